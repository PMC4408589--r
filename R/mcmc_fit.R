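#' Fit the local-ancestry model by Metropolis-within-Gibbs MCMC
#'
#' Alternates (1) sampling ancestral states for every haplotype copy with the
#' window HMM ([forward_backward()] semantics, batched over copies) and (2)
#' the full set of parameter updates — global ancestry `A` (and `A^X` when X
#' windows exist), crossover augmentation and generations-since-admixture
#' `lambda`, ancestry-specific allele frequencies `p`, window PCR
#' coefficients `beta`, and the hyperparameters `P`, `B`, `tau`,
#' `omega`/`omega_X`, `alpha` — in a fixed order for reproducibility.
#' Multiple chains run in lockstep and, during burn-in only, blend their
#' parameters with the across-chain mean via [combine_chains()].
#'
#' @param haplotypes binary matrix (haplotype copies x markers; 0/1/NA),
#'   consecutive rows pairing into diploid individuals.
#' @param priors an [compute_priors()] bundle over the same markers.
#' @param n_burn burn-in iterations (default 100).
#' @param n_iter follow-on (kept) iterations (default 200).
#' @param chains number of lockstep chains (default 1; single-chain runs are
#'   bit-reproducible under a fixed seed).
#' @param seed optional RNG seed.
#' @param lambda_init,tau_init initial generations since admixture and
#'   surrogate concentration (defaults 6 and 300, tuned to African-American
#'   admixture).
#' @param refit_every refit the window PCRs every t-th iteration (default 1).
#' @param verbose print progress.
#' @return An object of class `ald_fit` with posterior means (`gamma`
#'   copies x windows x K, `A`, `AX`, `lambda`, `tau`, `p`), the per-iteration
#'   `trace` data frame, acceptance-rate summaries, and the window set.
#' @export
ald_fit <- function(haplotypes, priors, n_burn = 100, n_iter = 200,
                    chains = 1, seed = NULL, lambda_init = 6, tau_init = 300,
                    refit_every = 1, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(priors, "ald_priors"))
  hap <- haplotypes
  if (is.list(hap) && !is.null(hap$haplotypes)) hap <- hap$haplotypes
  C <- nrow(hap); M <- ncol(hap); K <- priors$K
  stopifnot(M == nrow(priors$P))
  windows <- priors$windows
  J <- nrow(windows)
  is_x <- normalize_chrom(windows$chromosome) %in% c("X", "23")
  aut <- which(!is_x); xw <- which(is_x)
  mw <- attr(windows, "marker_window")

  pre <- precompute_designs(hap, priors)
  init <- initialize_state(hap, pre, priors, lambda_init, tau_init)
  mk_state <- function() init
  states <- replicate(chains, mk_state(), simplify = FALSE)

  total <- n_burn + n_iter
  gamma_acc <- array(0, c(C, J, K))
  A_acc <- matrix(0, C, K); AX_acc <- if (length(xw)) matrix(0, C, K) else NULL
  lam_acc <- numeric(C); tau_acc <- numeric(K); p_acc <- matrix(0, M, K)
  kept <- 0L
  trace <- vector("list", total * chains)
  acc_tot <- c(A = 0, lambda = 0, p = 0, beta = 0, P = 0, B = 0,
               tau = 0, omega = 0, alpha = 0)
  acc_n <- acc_tot

  for (it in seq_len(total)) {
    for (ch in seq_len(chains)) {
      st <- states[[ch]]
      res <- mcmc_iteration(st, hap, pre, priors, windows, aut, xw, mw,
                            refit = (it %% refit_every) == 0)
      st <- res$state
      states[[ch]] <- st
      acc_tot <- acc_tot + res$acc
      acc_n <- acc_n + 1
      trace[[(it - 1) * chains + ch]] <- data.frame(
        iter = it, chain = ch, phase = if (it <= n_burn) "burnin" else "followon",
        t(stats::setNames(colMeans(st$A), paste0("mean_A_", priors$pops))),
        mean_lambda = mean(st$lambda),
        t(stats::setNames(st$tau, paste0("tau_", priors$pops))),
        t(stats::setNames(st$omega, paste0("omega_", priors$pops))),
        omega_x = st$omegaX, alpha1 = st$alpha[1], alpha2 = st$alpha[2])
      if (it > n_burn) {
        gamma_acc <- gamma_acc + res$gamma
        A_acc <- A_acc + st$A
        if (!is.null(AX_acc)) AX_acc <- AX_acc + st$AX
        lam_acc <- lam_acc + st$lambda
        tau_acc <- tau_acc + st$tau
        p_acc <- p_acc + st$p
        kept <- kept + 1L
      }
    }
    if (chains > 1 && it <= n_burn) {
      remote <- chain_mean_state(states)
      for (ch in seq_len(chains)) {
        blended <- combine_chains(states[[ch]][PARAM_FIELDS], remote, it, n_burn)
        states[[ch]][PARAM_FIELDS] <- blended
      }
    }
    if (verbose && it %% 10 == 0)
      message("iteration ", it, "/", total, " mean A1 = ",
              round(mean(states[[1]]$A[, 1]), 3))
  }

  out <- list(gamma = gamma_acc / kept,
              A = A_acc / kept,
              AX = if (!is.null(AX_acc)) AX_acc / kept,
              lambda = lam_acc / kept,
              tau = tau_acc / kept,
              p = p_acc / kept,
              trace = do.call(rbind, trace),
              windows = windows, pops = priors$pops, K = K,
              n_burn = n_burn, n_iter = n_iter, chains = chains,
              accept_rates = acc_tot / pmax(acc_n, 1),
              n_copies = C, n_markers = M,
              final_state = states[[1]],
              call = match.call())
  class(out) <- "ald_fit"
  out
}

# continuous parameter fields exchanged between chains during burn-in
PARAM_FIELDS <- c("A", "AX", "lambda", "tau", "p", "beta", "P", "B",
                  "omega", "omegaX", "alpha")

chain_mean_state <- function(states) {
  n <- length(states)
  avg <- function(field) {
    xs <- lapply(states, function(s) s[[field]])
    if (is.null(xs[[1]])) return(NULL)
    if (is.list(xs[[1]])) {
      return(lapply(seq_along(xs[[1]]), function(i)
        avg_list(lapply(xs, `[[`, i))))
    }
    Reduce(`+`, xs) / n
  }
  avg_list <- function(xs) {
    if (is.null(xs[[1]])) return(NULL)
    if (is.list(xs[[1]]))
      return(lapply(seq_along(xs[[1]]), function(i)
        avg_list(lapply(xs, `[[`, i))))
    Reduce(`+`, xs) / length(xs)
  }
  out <- lapply(PARAM_FIELDS, avg)
  names(out) <- PARAM_FIELDS
  out
}

# Quick frequentist initialization: window-wise maximum-likelihood
# classification under the fitted label PCR (uniform prior), frequency-based
# for windows without one; per-copy ancestry fractions, averaged within each
# diploid pair so both parental copies start equal.
initialize_state <- function(hap, pre, priors, lambda_init, tau_init) {
  C <- nrow(hap); K <- priors$K; J <- nrow(priors$windows); M <- ncol(hap)
  G0 <- matrix(1L, C, J)
  for (j in seq_len(J)) {
    w <- priors$win[[j]]
    if (!w$freq_only && !is.null(w$label)) {
      sup <- hap[, w$label$support, drop = FALSE]
      sup[is.na(sup)] <- 0
      pr <- w$label$pcr$predict(sup)
      G0[, j] <- max.col(pr, ties.method = "first")
    } else {
      X <- pre$memX[[j]]
      ll <- sapply(seq_len(K), function(k) {
        pk <- pmin(pmax(priors$P[w$members, k], 1e-6), 1 - 1e-6)
        lf <- matrix(log(pk), C, length(pk), byrow = TRUE)
        l0 <- matrix(log1p(-pk), C, length(pk), byrow = TRUE)
        rowSums(ifelse(is.na(X), 0, ifelse(X == 1, lf, l0)))
      })
      G0[, j] <- max.col(ll, ties.method = "first")
    }
  }
  A0 <- t(apply(G0, 1, function(g) tabulate(g, K) / length(g)))
  if (C %% 2 == 0) {     # both parental copies start with equal ancestry
    for (i in seq_len(C / 2)) {
      m <- colMeans(A0[c(2 * i - 1, 2 * i), , drop = FALSE])
      A0[2 * i - 1, ] <- m; A0[2 * i, ] <- m
    }
  }
  A0 <- pmin(pmax(A0, 0.01), 0.99)
  A0 <- A0 / rowSums(A0)
  beta <- lapply(priors$win, function(w) {
    if (w$freq_only) NULL else lapply(w$pop, function(pk) pk$H)
  })
  B <- beta
  list(A = A0, AX = A0, lambda = rep(lambda_init, C),
       tau = rep(tau_init, K), p = priors$P, beta = beta,
       P = priors$P, B = B, omega = rep(10, K), omegaX = 10,
       alpha = c(6^2 / 4, 6 / 4), G = G0)  # Gamma(mean 6, var 4) -> (9, 1.5)
}

# One full MCMC iteration for one chain. Returns updated state, the posterior
# gamma of this iteration, and per-family acceptance rates.
mcmc_iteration <- function(st, hap, pre, priors, windows, aut, xw, mw, refit = TRUE) {
  C <- nrow(hap); K <- priors$K; J <- nrow(windows); M <- ncol(hap)
  le <- emission_loglik(pre, priors, st$p, st$beta, st$lambda)
  gamma <- array(0, c(C, J, K))
  G <- matrix(0L, C, J)
  fbA <- fb_batch(le[, aut, , drop = FALSE],
                  windows[aut, , drop = FALSE], st$lambda, st$A)
  gamma[, aut, ] <- fbA$gamma
  G[, aut] <- sample_paths(fbA, st$A)
  if (length(xw)) {
    fbX <- fb_batch(le[, xw, , drop = FALSE],
                    windows[xw, , drop = FALSE], st$lambda, st$AX)
    gamma[, xw, ] <- fbX$gamma
    G[, xw] <- sample_paths(fbX, st$AX)
  }
  st$G <- G

  acc <- c(A = NA, lambda = NA, p = NA, beta = NA, P = NA, B = NA,
           tau = NA, omega = NA, alpha = NA)

  # --- A (and A^X) --------------------------------------------------------
  gs <- sapply(seq_len(K), function(k) rowSums(gamma[, aut, k, drop = FALSE]))
  if (C == 1) gs <- matrix(gs, 1, K)
  upA <- update_global_ancestry(st$A, gs, st$omega)
  st$A <- upA$value; acc["A"] <- mean(upA$accepted)
  if (length(xw)) {
    gsx <- sapply(seq_len(K), function(k) rowSums(gamma[, xw, k, drop = FALSE]))
    if (C == 1) gsx <- matrix(gsx, 1, K)
    upX <- update_x_ancestry(st$AX, st$A, gsx, st$omegaX)
    st$AX <- upX$value
  }

  # --- crossovers and lambda ---------------------------------------------
  cs <- sample_crossovers(G, windows, st$lambda, st$A)
  upL <- update_lambda(st$lambda, cs$n_crossovers, cs$sum_d, st$alpha)
  st$lambda <- upL$value; acc["lambda"] <- mean(upL$accepted)

  # --- allele frequencies p ----------------------------------------------
  Gm <- G[, mw, drop = FALSE]                  # state at each marker
  obs <- !is.na(hap)
  nv <- matrix(0, M, K); nr <- matrix(0, M, K)
  for (k in seq_len(K)) {
    mk <- (Gm == k) & obs
    nv[, k] <- colSums(mk & (hap == 1), na.rm = TRUE)
    nr[, k] <- colSums(mk & (hap == 0), na.rm = TRUE)
  }
  upP <- update_allele_freqs(st$p, nv, nr, st$tau, st$P)
  st$p <- upP$value; acc["p"] <- mean(upP$accepted)

  # --- beta (window PCR refits) ------------------------------------------
  if (refit) {
    nacc <- 0; ntry <- 0
    for (j in seq_len(J)) {
      w <- priors$win[[j]]
      if (w$freq_only) next
      for (k in seq_len(K)) {
        idx <- which(G[, j] == k)
        m <- nrow(st$beta[[j]][[k]])
        if (length(idx) < m + 5) next
        D <- pre$design[[j]][[k]][idx, , drop = FALSE]
        for (t in seq_along(w$members)) {
          y <- pre$memX[[j]][idx, t]
          ok <- !is.na(y)
          if (sum(ok) < m + 5 || length(unique(y[ok])) < 2) next
          # warm-started refit; a separated fit retains the current beta
          f <- irls_logit(D[ok, , drop = FALSE], y[ok], ridge = 0,
                          maxit = 12, tol = 1e-6,
                          init = st$beta[[j]][[k]][, t])
          if (isTRUE(f$separated)) next
          up <- update_beta(st$beta[[j]][[k]][, t], f$coef, sum(ok),
                            st$tau[k], st$B[[j]][[k]][, t], w$pop[[k]]$Sigma[, t])
          st$beta[[j]][[k]][, t] <- up$value
          ntry <- ntry + 1; nacc <- nacc + up$accepted
        }
      }
    }
    acc["beta"] <- if (ntry) nacc / ntry else NA
  }

  # --- hyperparameters P, B, tau -----------------------------------------
  upHP <- update_hyper_P(st$P, priors$Omega$var, priors$Omega$ref, st$tau, st$p)
  st$P <- upHP$value; acc["P"] <- mean(upHP$accepted)

  naccB <- 0; ntryB <- 0
  Lk <- numeric(K); Qk <- numeric(K)   # sufficient statistics for the tau update
  for (j in seq_len(J)) {
    w <- priors$win[[j]]
    if (w$freq_only) next
    for (k in seq_len(K)) {
      # all member columns of this (window, population) at once
      H <- w$pop[[k]]$H; S <- w$pop[[k]]$Sigma
      B <- st$B[[j]][[k]]; bt <- st$beta[[j]][[k]]
      prop <- H + stats::rnorm(length(H)) * sqrt(S)
      lr <- -st$tau[k]^2 / 2 *
        (colSums((bt - prop)^2 / S) - colSums((bt - B)^2 / S))
      accB <- stats::runif(ncol(H)) < pmin(1, exp(lr))
      if (any(accB)) B[, accB] <- prop[, accB]
      st$B[[j]][[k]] <- B
      ntryB <- ntryB + ncol(H); naccB <- naccB + sum(accB)
      Lk[k] <- Lk[k] + length(H)
      Qk[k] <- Qk[k] + sum((bt - B)^2 / S)
    }
  }
  acc["B"] <- if (ntryB) naccB / ntryB else NA

  upT <- update_tau_ss(st$tau, st$p, st$P, Lk, Qk)
  st$tau <- upT$value; acc["tau"] <- mean(upT$accepted)

  # --- omega, omega_X, alpha ---------------------------------------------
  upO <- update_omega(st$omega, st$A)
  st$omega <- upO$value; acc["omega"] <- mean(upO$accepted)
  if (length(xw)) {
    upOX <- update_omega_x(st$omegaX, st$A, st$AX)
    st$omegaX <- upOX$value
  }
  upAl <- update_alpha(st$alpha, st$lambda)
  st$alpha <- upAl$value; acc["alpha"] <- mean(upAl$accepted)

  list(state = st, gamma = gamma, acc = ifelse(is.na(acc), 0, acc))
}

#' @export
print.ald_fit <- function(x, ...) {
  cat("Local ancestry fit:", x$n_copies / 2, "individuals (",
      x$n_copies, "haplotype copies ),", x$n_markers, "markers,",
      nrow(x$windows), "windows, K =", x$K, "\n")
  cat("  MCMC:", x$n_burn, "burn-in +", x$n_iter, "kept iterations,",
      x$chains, "chain(s)\n")
  cat("  Posterior mean global ancestry:",
      paste(sprintf("%s = %.3f", x$pops, colMeans(x$A)), collapse = ", "), "\n")
  cat("  Posterior mean generations since admixture:",
      sprintf("%.2f", mean(x$lambda)), "\n")
  invisible(x)
}

#' @export
summary.ald_fit <- function(object, ...) {
  out <- list(
    A = colMeans(object$A),
    lambda = mean(object$lambda),
    tau = object$tau,
    accept = object$accept_rates,
    pops = object$pops,
    n_ind = object$n_copies / 2,
    n_windows = nrow(object$windows))
  class(out) <- "summary.ald_fit"
  out
}

#' @export
print.summary.ald_fit <- function(x, ...) {
  cat("Global ancestry (posterior mean over", x$n_ind, "individuals):\n")
  print(round(x$A, 4))
  cat("Generations since admixture:", round(x$lambda, 3), "\n")
  cat("Surrogate concentration tau:", paste(round(x$tau, 1), collapse = ", "),
      if (any(x$tau < 100)) " [warning: tau < 100 suggests poor surrogates]" else "",
      "\n")
  cat("Acceptance rates:\n"); print(round(x$accept, 3))
  invisible(x)
}

#' @export
coef.ald_fit <- function(object, ...) {
  A <- object$A
  colnames(A) <- object$pops
  rownames(A) <- paste0("ind", rep(seq_len(nrow(A) / 2), each = 2),
                        "_h", rep(1:2, nrow(A) / 2))
  A
}

#' @export
plot.ald_fit <- function(x, type = c("ancestry", "trace"), copy = 1,
                         param = "mean_lambda", ...) {
  type <- match.arg(type)
  if (type == "trace") {
    tr <- x$trace[x$trace$chain == 1, ]
    graphics::plot(tr$iter, tr[[param]], type = "l", xlab = "iteration",
                   ylab = param, main = paste("Trace of", param), ...)
    graphics::abline(v = x$n_burn + 0.5, lty = 2)
  } else {
    g <- x$gamma[copy, , 1]
    graphics::plot(x$windows$mid_cm, g, type = "h", ylim = c(0, 1),
                   xlab = "position (cM)",
                   ylab = paste("P(", x$pops[1], "ancestry )"),
                   main = paste("Local ancestry, haplotype copy", copy), ...)
  }
  invisible(x)
}

#' Hard local-ancestry calls from a fit
#'
#' @param fit an `ald_fit`.
#' @return integer matrix (copies x windows) of maximum-posterior states.
#' @export
ancestry_calls <- function(fit) {
  dm <- dim(fit$gamma)
  flat <- matrix(fit$gamma, dm[1] * dm[2], dm[3])
  matrix(max.col(flat, ties.method = "first"), dm[1], dm[2])
}
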