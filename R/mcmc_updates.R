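# Metropolis-within-Gibbs parameter updates.
#
# Every update follows the same pattern: a data-informed independence proposal
# is drawn, then accepted with min(1, w(proposal)/w(current)) where w is the
# prior kernel (A, A^X, lambda, p, beta) or the likelihood ratio under the
# proposed hyperparameter (P, B, tau, omega, alpha). The stationary density of
# each chain is therefore proportional to proposal-density * w, which the
# tests integrate numerically.

#' Dirichlet random deviates
#' @param n number of draws.
#' @param alpha concentration vector (or matrix, one row per draw).
#' @return matrix of draws, rows summing to 1.
#' @keywords internal
rdirichlet <- function(n, alpha) {
  if (is.matrix(alpha)) {
    g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow(alpha))
  } else {
    g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)), n)
  }
  g / rowSums(g)
}

#' Update global ancestry proportions A
#'
#' Per haplotype copy, proposes `A' ~ Dirichlet(omega + sum_j gamma)` (the
#' sums running over that copy's autosomal windows) and accepts with the
#' Dirichlet prior-kernel ratio `min(1, prod_k A'^(omega-1) / A^(omega-1))`.
#'
#' @param A current ancestry matrix (copies x K), rows on the simplex.
#' @param gamma_sum matrix (copies x K) of summed posterior state
#'   probabilities over autosomal windows.
#' @param omega Dirichlet concentration K-vector.
#' @return list with `value` (updated A), `accepted` (logical per copy) and
#'   `accept_prob`.
#' @export
update_global_ancestry <- function(A, gamma_sum, omega) {
  C <- nrow(A); K <- ncol(A)
  prop <- rdirichlet(C, sweep(gamma_sum, 2, omega, "+"))
  lr <- rowSums(sweep(log(pmax(prop, 1e-300)) - log(pmax(A, 1e-300)),
                      2, omega - 1, "*"))
  ap <- pmin(1, exp(lr))
  acc <- stats::runif(C) < ap
  A[acc, ] <- prop[acc, ]
  list(value = A, accepted = acc, accept_prob = ap)
}

#' Update X-chromosome ancestry proportions
#'
#' Proposes `AX' ~ Dirichlet(omega_X * A + sum_j gamma_X)` per copy and
#' accepts with the kernel ratio of `Dirichlet(omega_X * A)` evaluated at the
#' proposal vs the current value. With no X windows the proposal collapses to
#' the prior around the autosomal ancestry.
#'
#' @param AX current X ancestry (copies x K).
#' @param A autosomal ancestry (copies x K).
#' @param gamma_sum_x summed X-window posterior probabilities (copies x K),
#'   zeros when no X windows were sampled.
#' @param omega_x scalar concentration tying X to autosomal ancestry.
#' @return list with `value`, `accepted`, `accept_prob`.
#' @export
update_x_ancestry <- function(AX, A, gamma_sum_x, omega_x) {
  conc <- omega_x * A + gamma_sum_x
  prop <- rdirichlet(nrow(AX), conc)
  lr <- rowSums((omega_x * A - 1) *
                  (log(pmax(prop, 1e-300)) - log(pmax(AX, 1e-300))))
  ap <- pmin(1, exp(lr))
  acc <- stats::runif(nrow(AX)) < ap
  AX[acc, ] <- prop[acc, ]
  list(value = AX, accepted = acc, accept_prob = ap)
}

#' Sample per-window crossover counts by augmentation
#'
#' For each copy and each window with a defined inter-midpoint distance, draws
#' a uniform `q` on `(P(x = 0), 1)`, inverts the Poisson CDF (rate
#' `lambda * d / 100`) to a crossover count `nx >= 1`, computes the
#' probability of zero crossovers given the sampled states (0 when ancestry
#' switched between the windows; otherwise the posterior odds of a hidden
#' same-state crossover), and retains `nx` with probability `1 - px0`.
#'
#' @param G sampled states (copies x windows).
#' @param windows `window_set` providing `d_cm` (NA starts a chromosome).
#' @param lambda generations since admixture per copy.
#' @param A global ancestry (copies x K).
#' @return list with `nx` (copies x windows retained counts), `px0`,
#'   `n_crossovers` per copy, and `sum_d` (total distance in Morgans entering
#'   the Gamma rate update).
#' @export
sample_crossovers <- function(G, windows, lambda, A) {
  C <- nrow(G); J <- ncol(G)
  stopifnot(J == nrow(windows))
  dM <- windows$d_cm / 100
  use <- !is.na(dM)
  nx <- matrix(0L, C, J)
  px0 <- matrix(NA_real_, C, J)
  for (j in which(use)) {
    rate <- lambda * dM[j]
    p0 <- exp(-rate)
    q <- p0 + stats::runif(C) * (1 - p0)
    n <- stats::qpois(q, rate)
    n[n < 1L] <- 1L                       # q > P(0) guarantees >= 1 up to rounding
    same <- G[, j] == G[, j - 1]
    Ag <- A[cbind(seq_len(C), G[, j])]
    e <- exp(-rate)
    pgt0 <- ifelse(same, Ag * (1 - e) / (e + Ag * (1 - e)), 1)
    px0[, j] <- 1 - pgt0
    keep <- stats::runif(C) < pgt0
    nx[, j] <- ifelse(keep, n, 0L)
  }
  list(nx = nx, px0 = px0, n_crossovers = rowSums(nx),
       sum_d = sum(dM[use]))
}

#' Update generations since admixture
#'
#' Proposes `lambda' ~ Gamma(alpha1 + n_crossovers, alpha2 + sum_d)` per copy
#' (distances in Morgans, matching the Poisson crossover rate units) and
#' accepts with the Gamma prior-kernel ratio.
#'
#' @param lambda current values per copy.
#' @param n_crossovers retained crossover counts per copy.
#' @param sum_d summed inter-midpoint distance in Morgans.
#' @param alpha `c(shape, rate)` of the Gamma prior.
#' @return list with `value`, `accepted`, `accept_prob`.
#' @export
update_lambda <- function(lambda, n_crossovers, sum_d, alpha) {
  C <- length(lambda)
  prop <- stats::rgamma(C, shape = alpha[1] + n_crossovers,
                        rate = alpha[2] + sum_d)
  lr <- (alpha[1] - 1) * (log(prop) - log(lambda)) - alpha[2] * (prop - lambda)
  ap <- pmin(1, exp(lr))
  acc <- stats::runif(C) < ap
  lambda[acc] <- prop[acc]
  list(value = lambda, accepted = acc, accept_prob = ap)
}

#' Update ancestry-specific allele frequencies
#'
#' Per marker and population, proposes from the conjugate Beta built from the
#' prior weight `tau * P` and the variant/reference allele counts among
#' haplotypes currently assigned that ancestry, and accepts with the Beta
#' prior-kernel ratio. `p` and `P` are variant-allele frequencies.
#'
#' @param p current frequencies (markers x K).
#' @param n_var,n_ref variant/reference allele counts (markers x K) among
#'   assigned haplotypes.
#' @param tau per-population concentration K-vector.
#' @param P prior frequencies (markers x K).
#' @return list with `value`, `accepted`, `accept_prob` (markers x K).
#' @export
update_allele_freqs <- function(p, n_var, n_ref, tau, P) {
  tauP <- sweep(P, 2, tau, "*")
  tauQ <- sweep(1 - P, 2, tau, "*")
  prop <- matrix(stats::rbeta(length(p), tauP + n_var, tauQ + n_ref),
                 nrow(p), ncol(p))
  prop <- pmin(pmax(prop, 1e-12), 1 - 1e-12)
  lr <- (tauP - 1) * (log(prop) - log(p)) + (tauQ - 1) * (log1p(-prop) - log1p(-p))
  ap <- pmin(1, exp(lr))
  acc <- matrix(stats::runif(length(p)) < ap, nrow(p))
  p[acc] <- prop[acc]
  list(value = p, accepted = acc, accept_prob = ap)
}

#' Update one member-marker PCR coefficient vector
#'
#' Given the refit estimate `beta_hat` on the `n` haplotypes currently
#' assigned this ancestry, proposes
#' `beta' ~ N((n beta_hat + tau B) / (n + tau), diag(Sigma) / (n + tau)^2)`
#' and accepts with the shrunken normal prior-kernel ratio
#' `min(1, exp(-tau^2/2 [ (b'-B)' D^-1 (b'-B) - (b-B)' D^-1 (b-B) ]))`.
#'
#' @param beta current coefficient vector (length m).
#' @param beta_hat refit estimate from the currently assigned haplotypes.
#' @param n number of haplotypes in the refit.
#' @param tau population concentration (scalar).
#' @param B prior mean vector.
#' @param Sigma_diag prior variance vector.
#' @return list with `value`, `accepted`, `accept_prob`.
#' @export
update_beta <- function(beta, beta_hat, n, tau, B, Sigma_diag) {
  mu <- (n * beta_hat + tau * B) / (n + tau)
  prop <- stats::rnorm(length(beta), mu, sqrt(Sigma_diag) / (n + tau))
  qf <- function(b) sum((b - B)^2 / Sigma_diag)
  ap <- min(1, exp(-tau^2 / 2 * (qf(prop) - qf(beta))))
  acc <- stats::runif(1) < ap
  list(value = if (acc) prop else beta, accepted = acc, accept_prob = ap)
}

#' Update the allele-frequency hyperparameter P
#'
#' Proposes `P' ~ Beta(Omega)` from the surrogate-panel allele counts and
#' accepts with the likelihood ratio of the current `p` under the proposed vs
#' current hyperparameter, i.e. the ratio of full Beta densities
#' `Beta(p; tau P', tau(1-P')) / Beta(p; tau P, tau(1-P))`.
#'
#' @param P current hyperparameter (markers x K).
#' @param Omega_var,Omega_ref smoothed variant/reference panel counts.
#' @param tau K-vector.
#' @param p current frequencies (markers x K).
#' @return list with `value`, `accepted`, `accept_prob`.
#' @export
update_hyper_P <- function(P, Omega_var, Omega_ref, tau, p) {
  prop <- matrix(stats::rbeta(length(P), Omega_var, Omega_ref), nrow(P))
  prop <- pmin(pmax(prop, 1e-12), 1 - 1e-12)
  tl <- rep(tau, each = nrow(P))
  lr <- stats::dbeta(p, tl * prop, tl * (1 - prop), log = TRUE) -
    stats::dbeta(p, tl * P, tl * (1 - P), log = TRUE)
  ap <- pmin(1, exp(lr))
  acc <- matrix(stats::runif(length(P)) < ap, nrow(P))
  P[acc] <- prop[acc]
  list(value = P, accepted = acc, accept_prob = ap)
}

#' Update the PCR coefficient hyperparameter B
#'
#' Proposes `B' ~ N(H, diag(Sigma))` and accepts with the likelihood ratio of
#' the current `beta` under the proposed vs current prior mean,
#' `min(1, exp(-tau^2/2 [ (beta-B')' D^-1 (beta-B') - (beta-B)' D^-1 (beta-B) ]))`.
#'
#' @param B current prior mean vector.
#' @param H hyperprior mean vector (panel estimate).
#' @param Sigma_diag variance vector.
#' @param tau population concentration.
#' @param beta current coefficient vector.
#' @return list with `value`, `accepted`, `accept_prob`.
#' @export
update_hyper_B <- function(B, H, Sigma_diag, tau, beta) {
  prop <- stats::rnorm(length(B), H, sqrt(Sigma_diag))
  qf <- function(b0) sum((beta - b0)^2 / Sigma_diag)
  ap <- min(1, exp(-tau^2 / 2 * (qf(prop) - qf(B))))
  acc <- stats::runif(1) < ap
  list(value = if (acc) prop else B, accepted = acc, accept_prob = ap)
}

#' Update the surrogate-fit concentration tau
#'
#' Per population, proposes from the log-normal prior (`log10(tau) ~ N(2,
#' 0.5)`, prior median 100) and accepts with the product of two likelihood
#' ratios: the Beta likelihood of all `p` given `P`, and the normal likelihood
#' of all PCR coefficients `beta` given `B` (dimension `l` per coefficient
#' vector).
#'
#' @param tau current K-vector.
#' @param p,P allele frequencies and their hyperparameters (markers x K).
#' @param beta_list,B_list,Sigma_list per population, a list of current
#'   coefficient vectors, their prior means, and variances (may be empty).
#' @return list with `value`, `accepted`, `accept_prob` per population.
#' @export
update_tau <- function(tau, p, P, beta_list = NULL, B_list = NULL,
                       Sigma_list = NULL) {
  K <- length(tau)
  L <- numeric(K); Q <- numeric(K)
  for (k in seq_len(K)) {
    if (!is.null(beta_list) && length(beta_list[[k]])) {
      for (t in seq_along(beta_list[[k]])) {
        b <- beta_list[[k]][[t]]
        L[k] <- L[k] + length(b)
        Q[k] <- Q[k] + sum((b - B_list[[k]][[t]])^2 / Sigma_list[[k]][[t]])
      }
    }
  }
  update_tau_ss(tau, p, P, L, Q)
}

# tau update from sufficient statistics: total coefficient count L and total
# standardized quadratic form Q of (beta - B) per population.
update_tau_ss <- function(tau, p, P, L, Q) {
  K <- length(tau)
  ap <- numeric(K); acc <- logical(K)
  for (k in seq_len(K)) {
    prop <- 10^stats::rnorm(1, 2, 0.5)
    lr <- sum(stats::dbeta(p[, k], prop * P[, k], prop * (1 - P[, k]), log = TRUE) -
                stats::dbeta(p[, k], tau[k] * P[, k], tau[k] * (1 - P[, k]), log = TRUE))
    lr <- lr + L[k] * (log(prop) - log(tau[k])) + (tau[k]^2 - prop^2) / 2 * Q[k]
    ap[k] <- min(1, exp(lr))
    acc[k] <- stats::runif(1) < ap[k]
    if (acc[k]) tau[k] <- prop
  }
  list(value = tau, accepted = acc, accept_prob = ap)
}

#' Update the ancestry concentration hyperparameters omega
#'
#' Proposes each selected component from its log-normal prior
#' (`log10(omega) ~ N(1, 0.5)`, median 10) and accepts with the product over
#' haplotype copies of Dirichlet density ratios of `A` under the proposed vs
#' current concentration.
#'
#' @param omega current K-vector.
#' @param A ancestry matrix (copies x K).
#' @param which logical K-vector selecting components to propose (default all).
#' @return list with `value`, `accepted`, `accept_prob`.
#' @export
update_omega <- function(omega, A, which = rep(TRUE, length(omega))) {
  prop <- omega
  prop[which] <- 10^stats::rnorm(sum(which), 1, 0.5)
  lr <- sum(ddirichlet_log(A, prop) - ddirichlet_log(A, omega))
  ap <- min(1, exp(lr))
  acc <- stats::runif(1) < ap
  list(value = if (acc) prop else omega, accepted = acc, accept_prob = ap)
}

#' Update the X-ancestry concentration omega_X
#'
#' Scalar analogue of [update_omega()]: `AX ~ Dirichlet(omega_X * A)` per
#' copy, proposal from the log-normal prior, acceptance by the product of
#' Dirichlet density ratios.
#'
#' @param omega_x current scalar.
#' @param A autosomal ancestry (copies x K).
#' @param AX X ancestry (copies x K).
#' @return list with `value`, `accepted`, `accept_prob`.
#' @export
update_omega_x <- function(omega_x, A, AX) {
  prop <- 10^stats::rnorm(1, 1, 0.5)
  lr <- 0
  for (c in seq_len(nrow(A)))
    lr <- lr + ddirichlet_log(AX[c, , drop = FALSE], prop * A[c, ]) -
      ddirichlet_log(AX[c, , drop = FALSE], omega_x * A[c, ])
  ap <- min(1, exp(lr))
  acc <- stats::runif(1) < ap
  list(value = if (acc) prop else omega_x, accepted = acc, accept_prob = ap)
}

#' Update the Gamma hyperparameters of lambda
#'
#' The Gamma prior of lambda is reparameterized by its mean `m = a1/a2` and
#' variance `v = a1/a2^2`; each is proposed independently from its log-normal
#' prior (`log10 ~ N(1, 0.5)`) and accepted with the product over copies of
#' Gamma density ratios of the current lambda values.
#'
#' @param alpha current `c(shape, rate)`.
#' @param lambda per-copy values.
#' @param which which reparameterized components to update (`"m"`, `"v"`, or
#'   both in sequence).
#' @return list with `value` (`c(shape, rate)`), `accepted`, `accept_prob`
#'   (one entry per component updated), and `mv` (the mean/variance pair).
#' @export
update_alpha <- function(alpha, lambda, which = c("m", "v")) {
  m <- alpha[1] / alpha[2]
  v <- alpha[1] / alpha[2]^2
  ap <- numeric(0); acc <- logical(0)
  for (comp in which) {
    m_new <- m; v_new <- v
    if (comp == "m") m_new <- 10^stats::rnorm(1, 1, 0.5)
    else v_new <- 10^stats::rnorm(1, 1, 0.5)
    a_new <- c(m_new^2 / v_new, m_new / v_new)
    a_cur <- c(m^2 / v, m / v)
    lr <- sum(stats::dgamma(lambda, a_new[1], a_new[2], log = TRUE) -
                stats::dgamma(lambda, a_cur[1], a_cur[2], log = TRUE))
    p_acc <- min(1, exp(lr))
    a <- stats::runif(1) < p_acc
    if (a) { m <- m_new; v <- v_new }
    ap <- c(ap, p_acc); acc <- c(acc, a)
  }
  list(value = c(m^2 / v, m / v), accepted = acc, accept_prob = ap,
       mv = c(m = m, v = v))
}

# log Dirichlet density, rows of x on the simplex
ddirichlet_log <- function(x, alpha) {
  if (is.matrix(alpha)) {
    rowSums((alpha - 1) * log(pmax(x, 1e-300))) +
      lgamma(rowSums(alpha)) - rowSums(lgamma(alpha))
  } else {
    rowSums(sweep(log(pmax(x, 1e-300)), 2, alpha - 1, "*")) +
      lgamma(sum(alpha)) - sum(lgamma(alpha))
  }
}

#' Blend local and remote chain parameters during burn-in
#'
#' During a distributed burn-in, each chain updates its parameter space with
#' the weighted sum `(iter / n_burn) * local + (1 - iter / n_burn) * remote`,
#' where `remote` is the across-chain mean. Simplex-valued parameters (rows
#' of `A`, `AX`) are renormalized after blending and interval-valued ones
#' (`p`, `P`) are clamped to (0, 1). Applied only while `iter <= n_burn`.
#'
#' @param local parameter state (a named list; numeric entries and nested
#'   lists are blended recursively).
#' @param remote the across-chain mean state, structurally identical.
#' @param iter current iteration (0..n_burn).
#' @param n_burn total burn-in iterations.
#' @return blended state with the same structure.
#' @export
combine_chains <- function(local, remote, iter, n_burn) {
  stopifnot(iter >= 0, iter <= n_burn)
  w <- iter / n_burn
  blend <- function(l, r) {
    if (is.list(l)) {
      if (!is.list(r) || length(l) != length(r)) stop("chain structure mismatch")
      return(mapply(blend, l, r, SIMPLIFY = FALSE))
    }
    if (is.null(l)) return(l)
    if (!is.numeric(l)) return(l)
    if (is.null(r) || length(r) != length(l)) stop("chain structure mismatch")
    w * l + (1 - w) * r
  }
  out <- blend(local, remote)
  for (f in c("A", "AX")) if (!is.null(out[[f]]))
    out[[f]] <- out[[f]] / rowSums(out[[f]])
  for (f in c("p", "P")) if (!is.null(out[[f]]))
    out[[f]] <- pmin(pmax(out[[f]], 1e-12), 1 - 1e-12)
  out
}
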