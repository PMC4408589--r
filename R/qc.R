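# Marker, individual and MCMC-chain quality control.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the heterozygote
#' count under HWE follows the standard hypergeometric-type distribution over
#' all configurations of the same parity; the p-value is the summed
#' probability of configurations no more probable than the observed one.
#'
#' @param genotype_counts integer vector `c(hom_ref, het, hom_alt)`.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact <- function(genotype_counts) {
  stopifnot(length(genotype_counts) == 3, all(genotype_counts >= 0))
  n <- sum(genotype_counts)
  if (n == 0) stop("zero individuals")
  het <- genotype_counts[2]
  na <- 2 * genotype_counts[3] + het          # alt allele count
  nb <- 2 * n - na
  minor <- min(na, nb)
  if (minor == 0) return(1)                   # monomorphic: single configuration
  hs <- seq(minor %% 2, minor, by = 2)        # attainable het counts (same parity)
  # log P(het = h | n, na) for each attainable h
  logp <- lgamma(n + 1) - lgamma((minor - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma(n - (minor + hs) / 2 + 1) + hs * log(2) +
    lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  pobs <- logp[match(het, hs)]
  if (is.na(pobs)) stop("inconsistent genotype counts")
  sum(exp(logp[logp <= pobs + 1e-12]))
}

qc_row <- function(scope, id, check, observed, threshold, action) {
  data.frame(scope = scope, id = as.character(id), check = check,
             observed = observed, threshold = threshold, action = action,
             stringsAsFactors = FALSE)
}

#' Marker quality control
#'
#' Flags markers with missingness above a threshold (default 5%), drops
#' strand-ambiguous A-T / G-C markers whose frequency cannot be reconciled
#' across data sources (near-0.5 frequencies are unresolvable; otherwise a
#' panel-vs-admixed frequency inconsistency marks a probable flip), and flags
#' markers whose admixed-sample frequency lies outside the convex hull of the
#' surrogate-panel frequencies by more than a margin.
#'
#' @param hap admixed haplotype matrix (copies x markers, 0/1/NA).
#' @param panels list of panel matrices for the frequency checks.
#' @param alleles optional data frame with `ref` and `alt` allele characters
#'   per marker for flip detection.
#' @param missing_threshold maximum missing-data rate (default 0.05).
#' @param hull_margin allowed excursion outside the panel frequency hull
#'   (default 0.1).
#' @param flip_band frequency half-width around 0.5 inside which an
#'   ambiguous-strand marker is unresolvable (default 0.1).
#' @return a `qc_report` data frame (possibly 0 rows).
#' @export
marker_qc <- function(hap, panels, alleles = NULL, missing_threshold = 0.05,
                      hull_margin = 0.1, flip_band = 0.1) {
  M <- ncol(hap)
  ids <- colnames(hap)
  if (is.null(ids)) ids <- paste0("m", seq_len(M))
  rows <- list()
  miss <- colMeans(is.na(hap))
  for (m in which(miss > missing_threshold))
    rows[[length(rows) + 1]] <- qc_row("marker", ids[m], "missingness",
                                       miss[m], missing_threshold, "flag")
  freq_adm <- colMeans(hap, na.rm = TRUE)
  pf <- sapply(panels, colMeans)
  if (!is.null(alleles)) {
    amb <- (toupper(alleles$ref) == "A" & toupper(alleles$alt) == "T") |
      (toupper(alleles$ref) == "T" & toupper(alleles$alt) == "A") |
      (toupper(alleles$ref) == "G" & toupper(alleles$alt) == "C") |
      (toupper(alleles$ref) == "C" & toupper(alleles$alt) == "G")
    for (m in which(amb)) {
      near_half <- abs(freq_adm[m] - 0.5) < flip_band
      # a flip shows as the admixed frequency tracking 1 - panel frequency
      mismatch <- all(abs(freq_adm[m] - pf[m, ]) >
                        abs(freq_adm[m] - (1 - pf[m, ])))
      if (near_half || mismatch)
        rows[[length(rows) + 1]] <- qc_row("marker", ids[m], "strand_ambiguous",
                                           freq_adm[m], 0.5, "drop")
    }
  }
  lo <- apply(pf, 1, min) - hull_margin
  hi <- apply(pf, 1, max) + hull_margin
  for (m in which(freq_adm < lo | freq_adm > hi))
    rows[[length(rows) + 1]] <- qc_row("marker", ids[m], "irregular_frequency",
                                       freq_adm[m], hull_margin, "flag")
  out <- if (length(rows)) do.call(rbind, rows) else empty_qc_report()
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Individual quality control
#'
#' Flags individuals with missingness above a threshold (default 5%),
#' compares reported sex with X-chromosome heterozygosity when X data exist
#' (heterozygosity below `male_het_threshold` calls a male), and flags pairs
#' of individuals whose genome-wide proportion of identical alleles exceeds a
#' relatedness threshold (default 0.9, catching duplicates and first-degree
#' relatives).
#'
#' @param hap haplotype matrix (copies x markers); consecutive row pairs form
#'   individuals.
#' @param missing_threshold maximum missing rate (default 0.05).
#' @param related_threshold allele-sharing proportion above which a pair is
#'   flagged (default 0.9).
#' @param sex optional reported sex per individual (`"M"`/`"F"`).
#' @param x_markers optional column indices of X-chromosome markers.
#' @param male_het_threshold X heterozygosity below which a male is called
#'   (default 0.02).
#' @return a `qc_report` data frame.
#' @export
individual_qc <- function(hap, missing_threshold = 0.05,
                          related_threshold = 0.9, sex = NULL,
                          x_markers = NULL, male_het_threshold = 0.02) {
  n <- nrow(hap) %/% 2
  rows <- list()
  ids <- paste0("ind", seq_len(n))
  geno <- hap[2 * seq_len(n) - 1, , drop = FALSE] +
    hap[2 * seq_len(n), , drop = FALSE]
  miss <- rowMeans(is.na(geno))
  for (i in which(miss > missing_threshold))
    rows[[length(rows) + 1]] <- qc_row("individual", ids[i], "missingness",
                                       miss[i], missing_threshold, "flag")
  if (!is.null(sex) && !is.null(x_markers)) {
    xh <- rowMeans(geno[, x_markers, drop = FALSE] == 1, na.rm = TRUE)
    called <- ifelse(xh < male_het_threshold, "M", "F")
    for (i in which(called != toupper(sex)))
      rows[[length(rows) + 1]] <- qc_row("individual", ids[i], "sex_mismatch",
                                         xh[i], male_het_threshold, "flag")
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ok <- !is.na(geno[i, ]) & !is.na(geno[j, ])
      if (!any(ok)) next
      share <- mean(1 - abs(geno[i, ok] - geno[j, ok]) / 2)
      if (share > related_threshold)
        rows[[length(rows) + 1]] <- qc_row("individual",
                                           paste(ids[i], ids[j], sep = "/"),
                                           "relatedness", share,
                                           related_threshold, "flag")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_qc_report()
  class(out) <- c("qc_report", "data.frame")
  out
}

empty_qc_report <- function() {
  data.frame(scope = character(0), id = character(0), check = character(0),
             observed = numeric(0), threshold = numeric(0),
             action = character(0), stringsAsFactors = FALSE)
}

#' MCMC trace diagnostics
#'
#' Per traced parameter: a mean-shift/drift check over the follow-on phase
#' (linear trend test; a significant slope indicates the burn-in was too
#' short), across-chain variability, and the surrogate-fit rule on `tau`
#' (posterior mean below 100 warns of poorly chosen surrogate panels or
#' allele flips; below 50 is a strong warning). Optionally writes one trace
#' plot per parameter.
#'
#' @param trace a trace data frame from [ald_fit()] (columns `iter`, `chain`,
#'   `phase`, parameters), or a list of such.
#' @param params parameter columns to check (default: all numeric except
#'   `iter`/`chain`).
#' @param drift_alpha significance level of the trend test (default 0.01).
#' @param plot_dir if non-NULL, a directory to write one PNG per parameter.
#' @return data frame with one row per parameter: follow-on mean, drift
#'   p-value and flag, across-chain SD, and tau warnings.
#' @export
trace_diagnostics <- function(trace, params = NULL, drift_alpha = 0.01,
                              plot_dir = NULL) {
  if (is.list(trace) && !is.data.frame(trace)) {
    for (i in seq_along(trace)) trace[[i]]$chain <- i
    trace <- do.call(rbind, trace)
  }
  if (is.null(trace$phase)) trace$phase <- "followon"
  if (is.null(trace$chain)) trace$chain <- 1
  if (is.null(params))
    params <- setdiff(names(trace)[vapply(trace, is.numeric, logical(1))],
                      c("iter", "chain"))
  fo <- trace[trace$phase == "followon", , drop = FALSE]
  if (!nrow(fo)) fo <- trace
  out <- lapply(params, function(pp) {
    y <- fo[[pp]]; x <- fo$iter
    pval <- if (stats::var(y) < 1e-16) 1 else
      summary(stats::lm(y ~ x))$coefficients[2, 4]
    chain_sd <- if (length(unique(fo$chain)) > 1)
      stats::sd(tapply(y, fo$chain, mean)) else NA_real_
    warn <- ""
    if (grepl("^tau", pp)) {
      mtau <- mean(y)
      if (mtau < 50) warn <- "strong warning: tau < 50"
      else if (mtau < 100) warn <- "warning: tau < 100"
    }
    if (!is.null(plot_dir)) {
      grDevices::png(file.path(plot_dir, paste0("trace_", pp, ".png")),
                     width = 600, height = 300)
      graphics::plot(trace$iter, trace[[pp]], type = "l", xlab = "iteration",
                     ylab = pp, col = trace$chain)
      grDevices::dev.off()
    }
    data.frame(parameter = pp, mean_followon = mean(y), drift_p = pval,
               drift_flag = pval < drift_alpha, across_chain_sd = chain_sd,
               warning = warn, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
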