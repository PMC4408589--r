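#' Principal component analysis of a window of panel haplotypes
#'
#' Column-centered PCA of a binary haplotype matrix. The number of retained
#' components is the smallest count whose cumulative eigenvalue fraction
#' reaches `var_threshold` (default 0.8), so that with the intercept the
#' regression has `m` coefficients. Monomorphic markers have zero-variance
#' columns and contribute zero loadings; a panel in which every marker is
#' monomorphic is flagged degenerate (the window falls back to an
#' allele-frequency emission).
#'
#' @param panel binary haplotype matrix (haplotypes x markers), >= 2 rows.
#' @param var_threshold cumulative variance fraction to retain.
#' @return list with `loadings` (markers x q, orthonormal columns),
#'   `eigenvalues`, `center` (fit-time column means), `q` retained component
#'   count, `variance_fraction_retained`, and `degenerate`.
#' @export
fit_window_pca <- function(panel, var_threshold = 0.8) {
  stopifnot(is.matrix(panel), nrow(panel) >= 2)
  ctr <- colMeans(panel)
  X <- sweep(panel, 2, ctr)
  cv <- crossprod(X) / (nrow(panel) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  pos <- ev$values > max(ev$values[1], 0) * 1e-12
  if (!any(pos) || ev$values[1] <= 0) {
    return(list(loadings = matrix(0, ncol(panel), 0), eigenvalues = numeric(0),
                center = ctr, q = 0L, variance_fraction_retained = 0,
                degenerate = TRUE))
  }
  vals <- ev$values[pos]
  frac <- cumsum(vals) / sum(vals)
  q <- which(frac >= var_threshold - 1e-12)[1]
  list(loadings = ev$vectors[, seq_len(q), drop = FALSE],
       eigenvalues = vals,
       center = ctr, q = as.integer(q),
       variance_fraction_retained = frac[q],
       degenerate = FALSE)
}

#' Project haplotypes onto fitted PC loadings
#'
#' Applies the fit-time centering and multiplies by the eigenvector matrix:
#' the principal component score matrix of a window is the matrix product of
#' the (centered) phased haplotype matrix with the loadings.
#'
#' @param haplotypes binary matrix (haplotypes x markers); columns must match
#'   the markers the loadings were fitted on.
#' @param pca a fit from [fit_window_pca()].
#' @return numeric score matrix (haplotypes x q).
#' @export
project_pcs <- function(haplotypes, pca) {
  if (is.null(dim(haplotypes))) haplotypes <- matrix(haplotypes, nrow = 1)
  if (ncol(haplotypes) != length(pca$center))
    stop("haplotype columns do not match the markers the PCA was fitted on")
  sweep(haplotypes, 2, pca$center) %*% pca$loadings
}

# Binary logistic fit with automatic ridge fallback on separation.
# Returns coef, se2 (diag of inverse information), separated flag.
logit_fit <- function(X, y, ridge_scale = 1e-4) {
  fit <- irls_logit(X, as.numeric(y), ridge = 0)
  if (isTRUE(fit$separated) || !isTRUE(fit$converged)) {
    fit <- irls_logit(X, as.numeric(y), ridge = ridge_scale * nrow(X))
    fit$penalized <- TRUE
  } else fit$penalized <- FALSE
  fit
}

#' Ancestry-label principal component regression
#'
#' Logistic (K = 2) or multinomial (K > 2) regression of the population label
#' of panel haplotypes on their principal component scores, the scores being
#' computed with the reference (first) population's loadings. Used to obtain
#' starting values for the HMM and the quick frequentist initialization of
#' ancestry. An L2 penalty is applied only when the unpenalized fit separates.
#'
#' @param panels list of K >= 2 binary haplotype matrices over the same
#'   markers, one per population (first = reference).
#' @param pca loadings from [fit_window_pca()] on the reference panel.
#' @return list with `H` (coefficient matrix, (q+1) x (K-1), intercept first),
#'   `Sigma_diag` (matching estimated coefficient variances), `K`, `penalized`,
#'   and `predict(h)` returning class probabilities for new haplotypes.
#' @export
fit_pcr <- function(panels, pca) {
  K <- length(panels)
  stopifnot(K >= 2)
  scores <- lapply(panels, project_pcs, pca = pca)
  X <- cbind(1, do.call(rbind, scores))
  lab <- rep(seq_len(K), vapply(scores, nrow, 1L))
  penalized <- FALSE
  if (K == 2) {
    fit <- logit_fit(X, as.numeric(lab == 2))
    H <- matrix(fit$coef, ncol = 1)
    S <- matrix(fit$se2, ncol = 1)
    penalized <- isTRUE(fit$penalized)
  } else {
    df <- data.frame(lab = factor(lab), X[, -1, drop = FALSE])
    mfit <- nnet::multinom(lab ~ ., data = df, trace = FALSE, maxit = 200)
    cf <- stats::coef(mfit)                       # (K-1) x (q+1)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
    H <- t(cf)
    vc <- tryCatch(diag(stats::vcov(mfit)), error = function(e) rep(1, length(H)))
    S <- matrix(vc[seq_along(H)], nrow = nrow(H))
  }
  pred <- function(h) {
    sc <- cbind(1, project_pcs(h, pca))
    eta <- sc %*% H
    expeta <- exp(cbind(0, eta))
    expeta / rowSums(expeta)
  }
  list(H = H, Sigma_diag = S, K = K, penalized = penalized, predict = pred)
}

#' Build the prior bundle for ancestry inference
#'
#' From surrogate ancestral panels and a window tiling, assembles every prior
#' hyperparameter the HMM/MCMC needs:
#' * `Omega` — per marker, per population, Jeffreys-smoothed
#'   (variant + 0.5, reference + 0.5) allele counts;
#' * `P` — prior variant-allele frequencies `Omega_var / (Omega_var + Omega_ref)`,
#'   strictly inside (0,1);
#' * per window and population, PC loadings of the flanking support markers
#'   (all markers within `support_cm` total span centered on the window,
#'   excluding the window's own members), and for each member marker a
#'   logistic PCR of its allele on those PCs, giving coefficient prior means
#'   `H` and variances `Sigma_diag`;
#' * per window, the ancestry-label PCR of [fit_pcr()] (reference-population
#'   loadings over the full support including members), used for
#'   initialization.
#'
#' Windows with a single member marker, no usable support, or a degenerate
#' support PCA fall back to allele-frequency-only emissions.
#'
#' @param panels list of K >= 2 binary haplotype matrices (haplotypes x all
#'   markers), one per population; names are the population labels.
#' @param windows a [build_windows()] window set over the same markers.
#' @param marker_cm cM position of every marker.
#' @param support_cm total support span in cM (default 2).
#' @param var_threshold PCA variance fraction to retain (default 0.8).
#' @return An object of class `ald_priors`.
#' @export
compute_priors <- function(panels, windows, marker_cm, support_cm = 2,
                           var_threshold = 0.8) {
  stopifnot(length(panels) >= 2)
  K <- length(panels)
  pops <- names(panels)
  if (is.null(pops)) pops <- paste0("pop", seq_len(K))
  M <- ncol(panels[[1]])
  stopifnot(length(marker_cm) == M, sum(windows$n_markers) == M)

  var_ct <- sapply(panels, function(p) colSums(p, na.rm = TRUE))
  tot_ct <- sapply(panels, function(p) colSums(!is.na(p)))
  Omega_var <- var_ct + 0.5
  Omega_ref <- (tot_ct - var_ct) + 0.5
  P <- Omega_var / (Omega_var + Omega_ref)
  colnames(P) <- pops

  members <- window_members(windows)
  J <- nrow(windows)
  half <- support_cm / 2
  win_model <- vector("list", J)
  for (j in seq_len(J)) {
    mem <- members[[j]]
    # support: markers on the same chromosome within +/- half cM of midpoint
    chr_of_marker <- windows$chromosome[attr(windows, "marker_window")]
    cand <- which(chr_of_marker == windows$chromosome[j] &
                    abs(marker_cm - windows$mid_cm[j]) <= half)
    support <- setdiff(cand, mem)
    freq_only <- length(mem) == 1 || length(support) == 0
    pop_fit <- vector("list", K)
    label_fit <- NULL
    if (!freq_only) {
      ok <- TRUE
      for (k in seq_len(K)) {
        pca <- fit_window_pca(panels[[k]][, support, drop = FALSE], var_threshold)
        if (pca$degenerate) { ok <- FALSE; break }
        D <- cbind(1, project_pcs(panels[[k]][, support, drop = FALSE], pca))
        nm <- length(mem)
        H <- matrix(0, ncol(D), nm)
        S <- matrix(1, ncol(D), nm)
        for (t in seq_len(nm)) {
          y <- panels[[k]][, mem[t]]
          if (all(y == y[1])) {            # monomorphic member: intercept only
            pr <- P[mem[t], k]
            H[1, t] <- stats::qlogis(pr)
            S[1, t] <- 1 / (nrow(D) * pr * (1 - pr))
          } else {
            f <- logit_fit(D, y)
            H[, t] <- f$coef
            S[, t] <- ifelse(is.finite(f$se2) & f$se2 > 0, f$se2, 1)
          }
        }
        pop_fit[[k]] <- list(pca = pca, H = H, Sigma = S)
      }
      freq_only <- !ok
    }
    if (!freq_only) {
      # label PCR over the full support (members included), reference loadings
      full <- sort(c(support, mem))
      ref_pca <- fit_window_pca(panels[[1]][, full, drop = FALSE], var_threshold)
      label_fit <- if (ref_pca$degenerate) NULL else
        list(pca = ref_pca, support = full,
             pcr = fit_pcr(lapply(panels, function(p) p[, full, drop = FALSE]),
                           ref_pca))
    }
    win_model[[j]] <- list(freq_only = freq_only, support = support,
                           members = mem, pop = pop_fit, label = label_fit)
  }
  structure(list(K = K, pops = pops, P = P,
                 Omega = list(var = Omega_var, ref = Omega_ref),
                 windows = windows, marker_cm = marker_cm,
                 support_cm = support_cm, var_threshold = var_threshold,
                 win = win_model),
            class = "ald_priors")
}

#' @export
print.ald_priors <- function(x, ...) {
  nf <- sum(vapply(x$win, function(w) w$freq_only, logical(1)))
  cat("Ancestral prior bundle: K =", x$K, "populations (",
      paste(x$pops, collapse = ", "), ")\n")
  cat(" ", nrow(x$P), "markers,", nrow(x$windows), "windows;",
      nf, "frequency-only windows; support span", x$support_cm, "cM\n")
  invisible(x)
}
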