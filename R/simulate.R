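# Synthetic ancestral panels and admixed chromosomes with known truth.

#' Specification of a synthetic ancestral panel set
#'
#' Describes K divergent populations over one or more chromosomes: marker
#' density comes from the map, allele-frequency divergence follows a
#' Balding-Nichols construction with parameter `divergence` (an F_ST-like
#' quantity), and within-population LD is induced by a haplotype-copying
#' process whose template-switch correlation length is `ld_decay_cm`.
#'
#' @param K number of populations (>= 2).
#' @param n_hap haplotypes per population.
#' @param map a [genetic_map()] giving marker positions.
#' @param divergence Balding-Nichols divergence parameter in (0, 1).
#' @param ld_decay_cm copying correlation length in cM (0 = linkage
#'   equilibrium).
#' @param maf_range ancestral allele-frequency range markers are drawn from.
#' @return list of class `panel_spec`.
#' @export
panel_spec <- function(K = 2, n_hap = 120, map, divergence = 0.15,
                       ld_decay_cm = 0.3, maf_range = c(0.1, 0.9)) {
  stopifnot(divergence > 0, divergence < 1, K >= 2, n_hap > 0)
  structure(list(K = K, n_hap = n_hap, map = map, divergence = divergence,
                 ld_decay_cm = ld_decay_cm, maf_range = maf_range),
            class = "panel_spec")
}

#' Simulate divergent ancestral haplotype panels
#'
#' Per marker, an ancestral frequency is drawn uniformly from `maf_range`;
#' each population's frequency is then drawn from the Balding-Nichols Beta
#' `Beta(q (1-F)/F, (1-q)(1-F)/F)` with `F = divergence`. Haplotypes are
#' generated from a latent Gaussian first-order autoregression along the
#' genetic map (correlation `exp(-d_cM / ld_decay_cm)` between adjacent
#' markers, restarting at chromosome boundaries) thresholded at each
#' marker's population frequency, so marginal frequencies are exactly
#' Balding-Nichols while within-population LD decays with cM distance.
#'
#' @param spec a [panel_spec()].
#' @return list of class `panel_set`: binary matrices (`n_hap` x markers), one
#'   per population, with attributes `freqs` (markers x K realized generating
#'   frequencies), `map`, and `spec`.
#' @export
simulate_panels <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  map <- spec$map
  M <- nrow(map)
  Fst <- spec$divergence
  q <- stats::runif(M, spec$maf_range[1], spec$maf_range[2])
  shp <- (1 - Fst) / Fst
  freqs <- sapply(seq_len(spec$K), function(k)
    stats::rbeta(M, q * shp, (1 - q) * shp))
  freqs <- pmin(pmax(freqs, 1e-4), 1 - 1e-4)
  # latent AR(1) correlation between adjacent markers, broken at chromosome starts
  dcm <- c(Inf, diff(map$position_cm))
  dcm[c(TRUE, map$chromosome[-1] != map$chromosome[-M])] <- Inf
  rho <- if (spec$ld_decay_cm > 0) exp(-dcm / spec$ld_decay_cm) else rep(0, M)
  panels <- vector("list", spec$K)
  for (k in seq_len(spec$K)) {
    Z <- matrix(0, spec$n_hap, M)
    Z[, 1] <- stats::rnorm(spec$n_hap)
    for (m in 2:M)
      Z[, m] <- rho[m] * Z[, m - 1] +
        sqrt(1 - rho[m]^2) * stats::rnorm(spec$n_hap)
    thr <- stats::qnorm(freqs[, k])
    H <- matrix(0L, spec$n_hap, M)
    H[sweep(Z, 2, thr, "<")] <- 1L
    panels[[k]] <- H
  }
  names(panels) <- paste0("pop", seq_len(spec$K))
  structure(panels, freqs = freqs, map = map, spec = spec,
            class = c("panel_set", "list"))
}

#' Hudson's F_ST estimator between two panels
#'
#' Ratio-of-averages estimator with the standard finite-sample correction:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`, both averaged over markers before taking the ratio.
#'
#' @param panel1,panel2 binary haplotype matrices over the same markers.
#' @return scalar F_ST estimate.
#' @export
fst_hudson <- function(panel1, panel2) {
  n1 <- nrow(panel1); n2 <- nrow(panel2)
  p1 <- colMeans(panel1); p2 <- colMeans(panel2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  mean(num[keep]) / mean(den[keep])
}

#' Simulate admixed chromosomes with known local ancestry
#'
#' Two-step construction: (1) per chromosome copy, draw the generations since
#' admixture `lambda` from a Gamma distribution (default mean 6, sd 2) and the
#' global ancestry vector from a Beta/Dirichlet (default mean 0.82, sd 0.1 for
#' the first population), then place recombination breakpoints as a Poisson
#' process of rate `lambda` per Morgan along the genetic map; (2) fill each
#' segment by selecting a source population with probability equal to the
#' global ancestry and copying the segment from a uniformly chosen panel
#' haplotype. The ground-truth ancestry label of every marker is recorded.
#'
#' @param panels a `panel_set` (or plain list of binary matrices with a `map`
#'   attribute / explicit `map`).
#' @param map a [genetic_map()] (defaults to the panel map).
#' @param n_chrom number of chromosome copies to simulate (default 400);
#'   consecutive pairs form diploid individuals.
#' @param lambda_mean,lambda_sd Gamma distribution of generations since
#'   admixture.
#' @param g_mean,g_sd Beta distribution of the first population's global
#'   ancestry proportion (remaining mass split evenly for K > 2).
#' @return list of class `admixed_sim` with `haplotypes` (n_chrom x markers),
#'   `truth` (n_chrom x markers population labels), `breakpoints` (list of cM
#'   positions), `lambda_true`, `G_true` (n_chrom x K), and `map`.
#' @export
simulate_admixed <- function(panels, map = attr(panels, "map"), n_chrom = 400,
                             lambda_mean = 6, lambda_sd = 2,
                             g_mean = 0.82, g_sd = 0.1) {
  K <- length(panels)
  M <- nrow(map)
  shape <- (lambda_mean / lambda_sd)^2
  rate <- lambda_mean / lambda_sd^2
  nu <- g_mean * (1 - g_mean) / g_sd^2 - 1
  stopifnot(nu > 0)
  a <- g_mean * nu; b <- (1 - g_mean) * nu
  hap <- matrix(0L, n_chrom, M)
  truth <- matrix(0L, n_chrom, M)
  lam <- stats::rgamma(n_chrom, shape, rate)
  G <- matrix(0, n_chrom, K)
  G[, 1] <- stats::rbeta(n_chrom, a, b)
  if (K > 1) G[, -1] <- (1 - G[, 1]) / (K - 1)
  bks <- vector("list", n_chrom)
  chroms <- unique(map$chromosome)
  for (i in seq_len(n_chrom)) {
    bk_all <- numeric(0)
    for (ch in chroms) {
      idx <- which(map$chromosome == ch)
      cm <- map$position_cm[idx]
      L <- max(cm) - min(cm)
      nb <- stats::rpois(1, lam[i] * L / 100)
      bk <- sort(stats::runif(nb, min(cm), max(cm)))
      seg_of <- findInterval(cm, bk) + 1L
      for (s in unique(seg_of)) {
        seg <- idx[seg_of == s]
        k <- sample.int(K, 1, prob = G[i, ])
        src <- sample.int(nrow(panels[[k]]), 1)
        hap[i, seg] <- panels[[k]][src, seg]
        truth[i, seg] <- k
      }
      bk_all <- c(bk_all, bk)
    }
    bks[[i]] <- bk_all
  }
  structure(list(haplotypes = hap, truth = truth, breakpoints = bks,
                 lambda_true = lam, G_true = G, map = map, K = K),
            class = "admixed_sim")
}

#' Perturb PCR coefficient priors to mimic imperfect surrogate panels
#'
#' Adds independent normal noise to every regression coefficient, with
#' standard deviation `scale` times the coefficient's standard error
#' `sqrt(Sigma_diag)`.
#'
#' @param priors an [compute_priors()] bundle.
#' @param scale noise scale relative to each coefficient's standard error
#'   (0 = no perturbation).
#' @return the bundle with perturbed `H` matrices.
#' @export
perturb_priors <- function(priors, scale) {
  if (scale == 0) return(priors)
  for (j in seq_along(priors$win)) {
    w <- priors$win[[j]]
    if (w$freq_only) next
    for (k in seq_len(priors$K)) {
      H <- w$pop[[k]]$H
      S <- w$pop[[k]]$Sigma
      priors$win[[j]]$pop[[k]]$H <- H +
        stats::rnorm(length(H), 0, scale * sqrt(S))
    }
  }
  priors
}

#' Simulate phenotypes tied to local ancestry at a risk window
#'
#' Disease liability increases with the diploid local-ancestry dosage of
#' population 1 at `risk_window` by `effect_size` on the link scale
#' (identity for `"quantitative"`, logit for `"case_control"`; `"case_only"`
#' keeps affected individuals only). `effect_size = 0` gives a null
#' phenotype independent of local ancestry.
#'
#' @param sim an `admixed_sim` (consecutive chromosome pairs = individuals).
#' @param windows a `window_set` over the simulated markers.
#' @param risk_window window index carrying the effect.
#' @param effect_size effect per dosage unit on the link scale.
#' @param model `"quantitative"`, `"case_control"` or `"case_only"`.
#' @param base_rate intercept on the link scale for binary models.
#' @return data frame with `id`, `phenotype`, and the risk-window `dosage`.
#' @export
simulate_phenotypes <- function(sim, windows, risk_window, effect_size = 0,
                                model = c("quantitative", "case_control",
                                          "case_only"),
                                base_rate = -0.5) {
  model <- match.arg(model)
  dos <- truth_dosage(sim, windows)[, risk_window]
  n <- length(dos)
  if (model == "quantitative") {
    y <- effect_size * dos + stats::rnorm(n)
  } else {
    pr <- stats::plogis(base_rate + effect_size * dos)
    y <- stats::rbinom(n, 1, pr)
    if (model == "case_only") {
      keep <- y == 1
      return(data.frame(id = which(keep), phenotype = y[keep],
                        dosage = dos[keep]))
    }
  }
  data.frame(id = seq_len(n), phenotype = y, dosage = dos)
}

#' True diploid ancestry dosage per window
#'
#' Pairs consecutive simulated chromosomes into individuals and counts, per
#' window, the copies whose majority ancestry is population 1 (0, 1 or 2).
#'
#' @param sim an `admixed_sim`.
#' @param windows a `window_set` over the simulated markers.
#' @param pop population whose dosage is counted (default 1).
#' @return matrix (individuals x windows).
#' @export
truth_dosage <- function(sim, windows, pop = 1) {
  lab <- truth_window_labels(sim, windows)
  n <- nrow(lab) %/% 2
  (lab[2 * seq_len(n) - 1, , drop = FALSE] == pop) +
    (lab[2 * seq_len(n), , drop = FALSE] == pop)
}

#' Majority true ancestry of each window per chromosome copy
#' @param sim an `admixed_sim`.
#' @param windows a `window_set`.
#' @return integer matrix (copies x windows).
#' @export
truth_window_labels <- function(sim, windows) {
  members <- window_members(windows)
  sapply(members, function(mem) {
    if (length(mem) == 1) return(sim$truth[, mem])
    apply(sim$truth[, mem, drop = FALSE], 1, function(r)
      as.integer(names(which.max(table(r)))))
  })
}
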