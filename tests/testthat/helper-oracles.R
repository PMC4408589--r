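# Shared fixtures and independent oracles for the test suite.

# small uniform genetic map on one chromosome
toy_map <- function(M, length_cm = 10, chrom = 1) {
  genetic_map(rep(chrom, M), seq_len(M) * 1000,
              seq(0, length_cm, length.out = M))
}

# Exhaustive-path enumeration oracle for the two-chain window HMM.
# Computes the forward-filter marginal at each window by enumerating all
# K^j prefix paths (and symmetrically for the reverse chain), then combines
# the two chains as the normalized elementwise product. Independent of the
# recursive implementation.
enum_fb_oracle <- function(emissions, d_cm, lambda, A) {
  J <- nrow(emissions); K <- ncol(emissions)
  pr <- recomb_prob(ifelse(is.na(d_cm), 0, d_cm), lambda)
  trans <- function(j) {             # T[k_prev, k] between windows j-1 and j
    outer(rep(1, K), A * pr[j]) + diag(K) * (1 - pr[j])
  }
  filter_marginal <- function(dir) {
    ord <- if (dir == "f") seq_len(J) else rev(seq_len(J))
    out <- matrix(0, J, K)
    npath <- 1
    weights <- A * emissions[ord[1], ]
    paths <- matrix(seq_len(K), ncol = 1)
    out[ord[1], ] <- tapply(weights, paths[, 1], sum)[as.character(seq_len(K))]
    out[ord[1], ] <- out[ord[1], ] / sum(out[ord[1], ])
    if (J == 1) return(out)
    for (step in 2:J) {
      j <- ord[step]
      jd <- if (dir == "f") j else j + 1   # distance index linking step-1 and step
      Tm <- trans(jd)
      newpaths <- matrix(0L, nrow(paths) * K, ncol(paths) + 1)
      newweights <- numeric(nrow(paths) * K)
      r <- 0
      for (pi in seq_len(nrow(paths))) for (k in seq_len(K)) {
        r <- r + 1
        newpaths[r, ] <- c(paths[pi, ], k)
        prevk <- paths[pi, ncol(paths)]
        newweights[r] <- weights[pi] * Tm[prevk, k] * emissions[j, k]
      }
      paths <- newpaths; weights <- newweights
      marg <- vapply(seq_len(K), function(k)
        sum(weights[paths[, ncol(paths)] == k]), numeric(1))
      out[j, ] <- marg / sum(marg)
      weights <- weights / sum(weights)   # keep numbers in range
    }
    out
  }
  gf <- filter_marginal("f")
  gr <- filter_marginal("r")
  g <- gf * gr
  g / rowSums(g)
}

# Kolmogorov-Smirnov distance between a sample and a numerically integrated
# target density on a grid (trapezoidal CDF).
ks_to_density <- function(x, dens, grid) {
  dy <- dens(grid)
  cdf <- cumsum(c(0, (dy[-1] + dy[-length(dy)]) / 2 * diff(grid)))
  cdf <- cdf / cdf[length(cdf)]
  Fx <- stats::approx(grid, cdf, xout = sort(x), rule = 2)$y
  n <- length(x)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  max(abs(Fx - emp_hi), abs(Fx - emp_lo))
}

# Run a frozen-parameter Metropolis chain by repeatedly calling `step`,
# a function current -> new scalar value.
run_frozen_chain <- function(step, init, n, burn = 1000) {
  x <- numeric(n)
  cur <- init
  for (i in seq_len(burn)) cur <- step(cur)
  for (i in seq_len(n)) { cur <- step(cur); x[i] <- cur }
  x
}

# Small two-population study set shared by several test files (cheap:
# ~300 markers). Built once per test run.
toy_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(42)
    map <- toy_map(300, length_cm = 15)
    panels <- simulate_panels(panel_spec(K = 2, n_hap = 80, map = map,
                                         divergence = 0.15, ld_decay_cm = 0.3))
    windows <- build_windows(map$chromosome, map$position_cm, 0.1)
    priors <- compute_priors(panels, windows, map$position_cm)
    sim <- simulate_admixed(panels, map, n_chrom = 40)
    cache <<- list(map = map, panels = panels, windows = windows,
                   priors = priors, sim = sim)
    cache
  }
})

# The desk-scale synthetic experiment shared by the acceptance tests:
# divergence 0.15, 2000 markers on one 100 cM chromosome, 50 individuals,
# surrogate PCR priors perturbed at one standard error, fixed seed.
desk_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(20150307)
    M <- 2000
    map <- genetic_map(rep(1, M), seq_len(M) * 5000,
                       seq(0, 100, length.out = M))
    panels <- simulate_panels(panel_spec(K = 2, n_hap = 120, map = map,
                                         divergence = 0.15, ld_decay_cm = 0.3))
    windows <- build_windows(map$chromosome, map$position_cm, 0.1)
    priors <- compute_priors(panels, windows, map$position_cm)
    priors <- perturb_priors(priors, scale = 1)
    sim <- simulate_admixed(panels, map, n_chrom = 100)
    fit <- ald_fit(sim$haplotypes, priors, n_burn = 100, n_iter = 200,
                   seed = 1)
    cache <<- list(map = map, panels = panels, windows = windows,
                   priors = priors, sim = sim, fit = fit)
    cache
  }
})

# Recurrence-based enumeration oracle for the exact HWE test: builds the
# full conditional distribution of heterozygote counts from the ratio
# P(h+2)/P(h) and sums configurations no more probable than the observed one.
hwe_enum_oracle <- function(h0, h1, h2) {
  n <- h0 + h1 + h2
  na <- 2 * h2 + h1; nb <- 2 * n - na
  minor <- min(na, nb)
  if (minor == 0) return(1)
  hs <- seq(minor %% 2, minor, by = 2)
  probs <- numeric(length(hs))
  probs[1] <- 1
  if (length(hs) > 1) for (i in 2:length(hs)) {
    h <- hs[i - 1]
    # P(h+2)/P(h) = 4 * hom_minor * hom_major / ((h+2)(h+1))
    hom_min <- (minor - h) / 2
    hom_maj <- n - h - hom_min
    probs[i] <- probs[i - 1] * 4 * hom_min * hom_maj / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  pobs <- probs[match(h1, hs)]
  sum(probs[probs <= pobs * (1 + 1e-12)])
}

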