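# Admixture-mapping (MALD) association statistics over local-ancestry dosage.

#' Expected diploid local-ancestry dosage from a fit
#'
#' Sums the posterior ancestry probabilities of the two haplotype copies of
#' each individual, giving a continuous dosage in `[0, 2]` per window. Using
#' the posterior expectation rather than sampled states propagates inference
#' uncertainty into the association models; hard-call dosage is available
#' with `type = "sampled"`.
#'
#' @param fit an [ald_fit()] object.
#' @param pop population whose dosage is counted (default 1).
#' @param type `"expected"` (posterior mean) or `"sampled"` (maximum
#'   posterior hard calls).
#' @return matrix (individuals x windows).
#' @export
ancestry_dosage <- function(fit, pop = 1, type = c("expected", "sampled")) {
  type <- match.arg(type)
  C <- dim(fit$gamma)[1]; n <- C %/% 2
  if (type == "expected") {
    g <- fit$gamma[, , pop]
    if (is.null(dim(g))) g <- matrix(g, C)
  } else {
    g <- (ancestry_calls(fit) == pop) * 1
  }
  g[2 * seq_len(n) - 1, , drop = FALSE] + g[2 * seq_len(n), , drop = FALSE]
}

scan_result <- function(win_id, est, se, stat, p, n, model, flag = "") {
  out <- data.frame(window = win_id, estimate = est, se = se,
                    statistic = stat, p = p, n = n, model = model,
                    flag = flag, stringsAsFactors = FALSE)
  ok <- !is.na(out$p)
  out$p_bonferroni <- pmin(out$p * sum(ok), 1)
  out$q_bh <- NA_real_
  out$q_bh[ok] <- stats::p.adjust(out$p[ok], "BH")
  class(out) <- c("ald_scan", "data.frame")
  out
}

#' @export
print.ald_scan <- function(x, ...) {
  cat("Ancestry association scan:", nrow(x), "tests, model",
      x$model[1], "\n")
  top <- x[order(x$p), ][seq_len(min(5, nrow(x))), ]
  print.data.frame(top, digits = 3)
  invisible(x)
}

# build covariate matrix (or NULL)
cov_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  cv <- as.matrix(covariates)
  stopifnot(nrow(cv) == n)
  cv
}

#' Case-only admixture association scan
#'
#' In a sample of cases only, compares local ancestry at each window with the
#' ancestry expected from each individual's genome-wide (global) proportions.
#' The default `statistic = "difference"` tests, per window, whether the mean
#' of `local - 2 * global` (adjusted for covariates) departs from zero — the
#' calibrated case-only admixture statistic. `statistic = "regression"`
#' instead fits the literal regression `global ~ b0 + b1 local + covariates`
#' and tests `b1` (this direction is confounded by the within-sample
#' correlation between local and global ancestry under random sampling, so
#' its null rejection rate is not nominal; it is provided for compatibility
#' with the model as originally written).
#'
#' @param local dosage matrix (cases x windows), e.g. [ancestry_dosage()].
#' @param global_A global ancestry proportion per case (length n).
#' @param covariates optional numeric matrix/data frame of covariates.
#' @param statistic `"difference"` (calibrated deviation test, default) or
#'   `"regression"` (global-on-local regression coefficient).
#' @return an `ald_scan` data frame with one row per window.
#' @export
case_only_scan <- function(local, global_A, covariates = NULL,
                           statistic = c("difference", "regression")) {
  statistic <- match.arg(statistic)
  n <- length(global_A)
  stopifnot(nrow(local) == n)
  cv <- cov_matrix(covariates, n)
  J <- ncol(local)
  est <- se <- stat <- p <- rep(NA_real_, J)
  flag <- character(J)
  for (j in seq_len(J)) {
    x <- local[, j]
    if (stats::var(x) < 1e-12) { flag[j] <- "non-testable: constant dosage"; next }
    if (statistic == "difference") {
      X <- cbind(rep(1, n), cv); y <- x - 2 * global_A
      if (stats::var(y) < 1e-12) { flag[j] <- "non-testable: constant deviation"; next }
    } else {
      X <- cbind(1, x, cv); y <- global_A
    }
    idx <- if (statistic == "difference") 1 else 2
    ft <- stats::lm.fit(X, y)
    rdf <- ft$df.residual
    s2 <- sum(ft$residuals^2) / max(rdf, 1)
    XtXi <- chol2inv(chol(crossprod(X)))
    est[j] <- ft$coefficients[idx]
    se[j] <- sqrt(s2 * XtXi[idx, idx])
    stat[j] <- est[j] / se[j]
    p[j] <- 2 * stats::pt(-abs(stat[j]), rdf)
  }
  scan_result(seq_len(J), est, se, stat, p, n,
              paste0("case_only_", statistic), flag)
}

#' Admixture-mapping association scan
#'
#' Per window, fits the generalized linear model
#' `link(Y) ~ b0 + b1 local + b2 global + b3 covariates` and reports the Wald
#' test of the local-ancestry coefficient `b1`. Identity link for
#' quantitative phenotypes, logit for binary.
#'
#' @param phenotype response vector (0/1 for `link = "logit"`).
#' @param local dosage matrix (individuals x windows).
#' @param global_A global ancestry per individual.
#' @param covariates optional covariates.
#' @param link `"identity"` or `"logit"`.
#' @return an `ald_scan` data frame.
#' @export
mald_scan <- function(phenotype, local, global_A, covariates = NULL,
                      link = c("identity", "logit")) {
  link <- match.arg(link)
  n <- length(phenotype)
  stopifnot(nrow(local) == n, length(global_A) == n)
  if (link == "logit" && !all(phenotype %in% 0:1))
    stop("binary phenotype required for logit link")
  cv <- cov_matrix(covariates, n)
  J <- ncol(local)
  est <- se <- stat <- p <- rep(NA_real_, J)
  flag <- character(J)
  fam <- if (link == "identity") stats::gaussian() else stats::binomial()
  for (j in seq_len(J)) {
    x <- local[, j]
    if (stats::var(x) < 1e-12) { flag[j] <- "non-testable: constant dosage"; next }
    X <- cbind(`(Intercept)` = 1, local = x, global = global_A, cv)
    ft <- tryCatch(stats::glm.fit(X, phenotype, family = fam),
                   error = function(e) NULL, warning = function(w)
                     suppressWarnings(stats::glm.fit(X, phenotype, family = fam)))
    if (is.null(ft) || !ft$converged) { flag[j] <- "non-convergence"; next }
    sm <- glm_wald(ft, X, 2)
    est[j] <- sm[1]; se[j] <- sm[2]; stat[j] <- sm[3]; p[j] <- sm[4]
  }
  scan_result(seq_len(J), est, se, stat, p, n,
              paste0("mald_", link), flag)
}

# Wald statistic for coefficient `idx` of a glm.fit object
glm_wald <- function(ft, X, idx) {
  w <- ft$weights
  XtWX <- crossprod(X * sqrt(w))
  vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(vc)) return(rep(NA_real_, 4))
  disp <- if (ft$family$family == "gaussian")
    sum(ft$residuals^2 * w) / ft$df.residual else 1
  est <- ft$coefficients[idx]
  se <- sqrt(disp * vc[idx, idx])
  z <- est / se
  p <- if (ft$family$family == "gaussian")
    2 * stats::pt(-abs(z), ft$df.residual) else 2 * stats::pnorm(-abs(z))
  c(est, se, z, p)
}

#' Fine-mapping association of markers conditional on ancestry
#'
#' Per marker, fits `link(Y) ~ b0 + b1 genotype + b2 local + b3 global + b4
#' covariates` and reports the Wald test of the genotype coefficient, so that
#' a causal variant absorbs the admixture signal at its locus. Markers whose
#' genotype is (near-)collinear with local ancestry are flagged with a
#' condition-number note.
#'
#' @param phenotype response vector.
#' @param genotypes dosage matrix (individuals x markers).
#' @param local local-ancestry dosage per individual at the tested region
#'   (vector, or matrix with one column per marker).
#' @param global_A global ancestry per individual.
#' @param covariates optional covariates.
#' @param link `"identity"` or `"logit"`.
#' @return an `ald_scan` data frame with one row per marker.
#' @export
fine_map <- function(phenotype, genotypes, local, global_A, covariates = NULL,
                     link = c("identity", "logit")) {
  link <- match.arg(link)
  n <- length(phenotype)
  genotypes <- as.matrix(genotypes)
  if (is.null(dim(local))) local <- matrix(local, n, ncol(genotypes))
  cv <- cov_matrix(covariates, n)
  Mr <- ncol(genotypes)
  est <- se <- stat <- p <- rep(NA_real_, Mr)
  flag <- character(Mr)
  fam <- if (link == "identity") stats::gaussian() else stats::binomial()
  for (m in seq_len(Mr)) {
    g <- genotypes[, m]; la <- local[, m]
    X <- cbind(`(Intercept)` = 1, genotype = g, local = la,
               global = global_A, cv)
    d <- svd(scale(X[, -1], scale = FALSE))$d
    kappa <- if (min(d) < 1e-10) Inf else max(d) / min(d)
    if (!is.finite(kappa) || kappa > 1e6) {
      flag[m] <- sprintf("collinear genotype/ancestry (condition number %.3g)",
                         kappa)
      next
    }
    ft <- tryCatch(suppressWarnings(stats::glm.fit(X, phenotype, family = fam)),
                   error = function(e) NULL)
    if (is.null(ft) || !ft$converged) { flag[m] <- "non-convergence"; next }
    sm <- glm_wald(ft, X, 2)
    est[m] <- sm[1]; se[m] <- sm[2]; stat[m] <- sm[3]; p[m] <- sm[4]
  }
  scan_result(seq_len(Mr), est, se, stat, p, n,
              paste0("fine_map_", link), flag)
}
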