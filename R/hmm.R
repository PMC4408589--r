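#' Probability of an observed recombination event between window midpoints
#'
#' Over a genetic distance of `d` cM and `lambda` generations since admixture,
#' the probability that at least one ancestry-switching recombination is
#' observed is `1 - ((1 + exp(-2d/100))/2)^lambda`. At `lambda = 1` this
#' reduces exactly to the single-generation form `(1 - exp(-2d/100))/2`.
#'
#' @param d genetic distance in cM (>= 0).
#' @param lambda generations since admixture (> 0).
#' @return probability in `[0, 1)`.
#' @export
recomb_prob <- function(d, lambda) {
  if (any(d < 0, na.rm = TRUE)) stop("negative genetic distance")
  1 - ((1 + exp(-2 * d / 100)) / 2)^lambda
}

#' Probability of any crossover within a window since admixture
#'
#' Crossovers over a span of `w` cM accumulate as a Poisson process with rate
#' `lambda` per Morgan, so the probability of one or more crossovers is
#' `1 - exp(-lambda * w / 100)`. When a crossover has occurred inside the
#' support of a window's principal-component regression, the haplotype is no
#' longer representative of a single ancestral population and the emission
#' falls back to the allele frequency.
#'
#' @param w span in cM (>= 0).
#' @param lambda generations since admixture (> 0).
#' @return probability in `[0, 1)`.
#' @export
crossover_prob <- function(w, lambda) 1 - exp(-lambda * w / 100)

#' Transition prior for the ancestral state of a window
#'
#' Convex combination of the global ancestry and the previous window's state
#' probabilities: `P(g = k) = A_k * pr + gamma_prev_k * (1 - pr)`, where `pr`
#' is the recombination probability over the inter-midpoint distance. The
#' first window of a chromosome uses `pr = 1` (as if a recombination were
#' known to have occurred), so the prior is the global ancestry.
#'
#' @param gamma_prev K-vector summing to 1 (previous window posterior).
#' @param A K-vector summing to 1 (global ancestry of this haplotype copy).
#' @param pr recombination probability in `[0, 1]`.
#' @return K-vector summing to 1.
#' @export
transition_prior <- function(gamma_prev, A, pr) A * pr + gamma_prev * (1 - pr)

#' Window emission probability given an ancestral state
#'
#' Implements the mixture emission: with probability `crossover_prob(w,
#' lambda)` a crossover has disrupted the support haplotype and the member
#' allele is modeled by the population allele frequency `p` alone; otherwise
#' it is modeled by the inverse-logit of the member's principal-component
#' regression evaluated on the support haplotype. For frequency-only windows
#' (single member marker, no support, or degenerate support PCA) only `p` is
#' used. Missing member alleles contribute a factor of 1.
#'
#' @param x 0/1 member-marker alleles of the window (NA = missing).
#' @param support_hap 0/1 alleles of the support markers (ignored for
#'   frequency-only windows).
#' @param k population index.
#' @param win one window model from an [compute_priors()] bundle
#'   (`priors$win[[j]]`).
#' @param p variant-allele frequencies of the member markers in population
#'   `k`.
#' @param beta coefficient matrix (m x n_members) of the member PCRs for
#'   population `k` (defaults to the prior mean `H`).
#' @param lambda generations since admixture of this haplotype copy.
#' @param support_cm total support span in cM.
#' @return emission probability `P(observed window | g = k)`.
#' @export
emission_prob <- function(x, support_hap = NULL, k, win, p,
                          beta = NULL, lambda, support_cm = 2) {
  obs <- !is.na(x)
  if (!any(obs)) return(1)
  if (win$freq_only) {
    f <- p
  } else {
    if (is.null(beta)) beta <- win$pop[[k]]$H
    cp <- crossover_prob(support_cm, lambda)
    sc <- c(1, project_pcs(matrix(support_hap, nrow = 1), win$pop[[k]]$pca))
    q <- stats::plogis(as.numeric(sc %*% beta))
    f <- p * cp + q * (1 - cp)
  }
  if (any(f <= 0 | f >= 1)) {
    f <- pmin(pmax(f, 1e-12), 1 - 1e-12)
    if (any(!is.finite(f))) stop("emission probability outside [0,1]: corrupted beta/p")
  }
  prod(ifelse(obs, ifelse(x == 1, f, 1 - f), 1))
}

#' Forward-backward ancestral state probabilities for one haplotype copy
#'
#' Runs the scaled forward chain (emission times the convex transition prior,
#' renormalized at each window), the symmetric reverse chain from the
#' opposite end, and combines them as the normalized elementwise product.
#' Both chains start from the global ancestry (first-window rule `pr = 1`).
#'
#' @param emissions J x K matrix of window emission probabilities (rows may
#'   be unnormalized likelihoods).
#' @param d_cm inter-midpoint distances (length J, first element NA).
#' @param lambda generations since admixture for this copy.
#' @param A global ancestry K-vector for this copy.
#' @return list with `gamma` (J x K posterior, rows sum to 1), `forward` and
#'   `reverse` chain marginals.
#' @export
forward_backward <- function(emissions, d_cm, lambda, A) {
  J <- nrow(emissions); K <- ncol(emissions)
  stopifnot(length(d_cm) == J, length(A) == K)
  pr <- recomb_prob(ifelse(is.na(d_cm), 0, d_cm), lambda)
  gf <- matrix(0, J, K); gr <- matrix(0, J, K)
  v <- emissions[1, ] * A
  if (sum(v) <= 0) stop("all-zero posterior at window 1")
  gf[1, ] <- v / sum(v)
  if (J > 1) for (j in 2:J) {
    prior <- transition_prior(gf[j - 1, ], A, pr[j])
    v <- emissions[j, ] * prior
    if (sum(v) <= 0) stop("all-zero posterior at window ", j)
    gf[j, ] <- v / sum(v)
  }
  v <- emissions[J, ] * A
  gr[J, ] <- v / sum(v)
  if (J > 1) for (j in (J - 1):1) {
    prior <- transition_prior(gr[j + 1, ], A, pr[j + 1])
    v <- emissions[j, ] * prior
    if (sum(v) <= 0) stop("all-zero posterior at window ", j)
    gr[j, ] <- v / sum(v)
  }
  g <- gf * gr
  s <- rowSums(g)
  if (any(s <= 0)) stop("all-zero posterior after chain combination")
  list(gamma = g / s, forward = gf, reverse = gr)
}

#' Sample ancestral states from posterior probabilities
#'
#' Independent categorical draw per row of `gamma` (or per (copy, window) for
#' a 3-d array). Reproducible under a fixed R random seed.
#'
#' @param gamma matrix (rows x K) or array (copies x windows x K) of
#'   probabilities, each K-slice summing to 1.
#' @return integer vector (or matrix) of sampled states in `1..K`.
#' @export
sample_states <- function(gamma) {
  if (length(dim(gamma)) == 3) {
    dm <- dim(gamma)
    flat <- matrix(gamma, dm[1] * dm[2], dm[3])
    return(matrix(sample_states(flat), dm[1], dm[2]))
  }
  K <- ncol(gamma)
  u <- stats::runif(nrow(gamma))
  cum <- gamma %*% upper.tri(diag(K), diag = TRUE)
  as.integer(rowSums(u > cum) + 1L)
}

# ---- batched internals used by the MCMC driver ----------------------------

# Pre-projects the admixed haplotypes once: for each window and population,
# the fixed PCR design matrix (copies x m), plus member allele matrices.
# hap: copies x markers 0/1 matrix (NA = missing)
precompute_designs <- function(hap, priors) {
  J <- nrow(priors$windows); K <- priors$K
  design <- vector("list", J)
  memX <- vector("list", J)
  for (j in seq_len(J)) {
    w <- priors$win[[j]]
    memX[[j]] <- hap[, w$members, drop = FALSE]
    if (!w$freq_only) {
      sup <- hap[, w$support, drop = FALSE]
      sup[is.na(sup)] <- matrix(rep(colMeans(sup, na.rm = TRUE),
                                    each = nrow(sup)), nrow(sup))[is.na(sup)]
      design[[j]] <- lapply(seq_len(K), function(k)
        cbind(1, project_pcs(sup, w$pop[[k]]$pca)))
    }
  }
  list(design = design, memX = memX)
}

# Log emission array (copies x windows x K), computed in C++.
# p: markers x K; beta: list[[j]][[k]] m x n_members; lambda: per copy.
emission_loglik <- function(pre, priors, p, beta, lambda) {
  cp <- crossover_prob(priors$support_cm, lambda)  # per copy
  p_mem <- lapply(priors$win, function(w) p[w$members, , drop = FALSE])
  freq_only <- vapply(priors$win, function(w) w$freq_only, logical(1))
  cpp_emission_loglik(pre$design, pre$memX, p_mem, freq_only, beta, cp)
}

# Batched forward-backward over all copies; le is a (C x J x K) log-emission
# array; returns the gamma array of the same shape.
fb_batch <- function(le, windows, lambda, A) {
  dm <- dim(le); C <- dm[1]; J <- dm[2]; K <- dm[3]
  d <- windows$d_cm
  first <- is.na(d)
  # per copy, per window recombination probability
  pr <- vapply(ifelse(first, 0, d), function(dd) recomb_prob(dd, lambda),
               numeric(C))
  if (C == 1) pr <- matrix(pr, 1, J)
  gf <- array(0, dm); gr <- array(0, dm)
  Ej <- function(j) {
    m <- matrix(le[, j, ], C, K)
    exp(m - apply(m, 1, max))
  }
  E <- lapply(seq_len(J), Ej)
  prev <- NULL
  for (j in seq_len(J)) {
    prior <- if (first[j]) A else A * pr[, j] + prev * (1 - pr[, j])
    v <- E[[j]] * prior
    s <- rowSums(v)
    if (any(s <= 0)) stop("all-zero posterior at window ", j)
    prev <- v / s
    gf[, j, ] <- prev
  }
  nxt_first <- c(first[-1], TRUE)  # window j ends its chromosome if j+1 starts one
  for (j in rev(seq_len(J))) {
    prior <- if (nxt_first[j]) A else A * pr[, j + 1] + prev * (1 - pr[, j + 1])
    v <- E[[j]] * prior
    s <- rowSums(v)
    if (any(s <= 0)) stop("all-zero posterior at window ", j)
    prev <- v / s
    gr[, j, ] <- prev
  }
  g <- gf * gr
  sw <- matrix(0, C, J)
  for (k in seq_len(K)) sw <- sw + g[, , k]
  if (any(sw <= 0)) stop("all-zero posterior after chain combination")
  list(gamma = g / as.vector(sw),  # (C,J) sums recycle over the K slices
       forward = gf, pr = pr, first = first)
}

# Joint path sample of ancestral states from the forward filter (backward
# sampling with the convex transition kernel). Independent marginal draws
# overcount ancestry switches on dense window grids, which corrupts the
# crossover augmentation; a path sample keeps switch counts coherent with
# the chain's transition prior.
sample_paths <- function(fb, A) {
  gf <- fb$forward; pr <- fb$pr; first <- fb$first
  dm <- dim(gf); C <- dm[1]; J <- dm[2]; K <- dm[3]
  G <- matrix(0L, C, J)
  draw <- function(w) {
    w <- w / rowSums(w)
    cum <- w %*% upper.tri(diag(K), diag = TRUE)
    as.integer(rowSums(stats::runif(nrow(w)) > cum) + 1L)
  }
  nxt_first <- c(first[-1], TRUE)     # window j ends its chromosome
  for (j in rev(seq_len(J))) {
    gfj <- matrix(gf[, j, ], C, K)
    if (nxt_first[j]) {
      G[, j] <- draw(gfj)
    } else {
      gnext <- G[, j + 1]
      p <- pr[, j + 1]
      Ag <- A[cbind(seq_len(C), gnext)]
      w <- gfj * (p * Ag)                          # recombination branch
      idx <- cbind(seq_len(C), gnext)
      w[idx] <- w[idx] + gfj[idx] * (1 - p)        # no-recombination branch
      G[, j] <- draw(w)
    }
  }
  G
}
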