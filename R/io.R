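# Readers and writers for phased data and result tables.

#' Read phased haplotypes
#'
#' Reads phased biallelic haplotypes from a VCF (GT entries with the `|`
#' phase separator) or an Oxford HAPS file. Unphased VCF entries are an
#' error unless `permissive = TRUE`, in which case both haplotypes of the
#' entry are set missing. Multi-allelic sites are dropped with a logged
#' count. Coordinates are 1-based.
#'
#' @param path file path.
#' @param format `"vcf"` or `"haps"` (guessed from the extension by default).
#' @param permissive mark unphased entries missing instead of failing.
#' @return An object of class `phased_dataset`: list with `samples`,
#'   `markers` (id, chromosome, position_bp, ref, alt), and `haplotypes`
#'   (2 x n_samples rows, markers columns, 0/1/NA).
#' @export
read_phased <- function(path, format = c("auto", "vcf", "haps"),
                        permissive = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "haps"
  if (format == "vcf") read_phased_vcf(path, permissive)
  else read_phased_haps(path)
}

read_phased_vcf <- function(path, permissive = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    message("read_phased: dropped ", sum(multi), " multi-allelic site(s)")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  samples <- colnames(gt)
  n <- length(samples); M <- nrow(fix)
  hapm <- matrix(NA_integer_, 2 * n, M)
  for (s in seq_len(n)) {
    g <- gt[, s]
    phased <- grepl("|", g, fixed = TRUE)
    missing <- is.na(g) | g %in% c(".", "./.", ".|.")
    bad <- !phased & !missing
    if (any(bad) && !permissive)
      stop("unphased genotype '", g[which(bad)[1]], "' at record ",
           which(bad)[1], " for sample ", samples[s],
           " (use permissive = TRUE to treat as missing)")
    al <- matrix(NA_character_, M, 2)
    sp <- strsplit(ifelse(phased, g, ".|."), "|", fixed = TRUE)
    al[, 1] <- vapply(sp, `[`, "", 1)
    al[, 2] <- vapply(sp, `[`, "", 2)
    al[al == "."] <- NA
    hapm[2 * s - 1, ] <- as.integer(al[, 1])
    hapm[2 * s, ] <- as.integer(al[, 2])
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("m", which(is.na(ids) | ids == "."))
  markers <- data.frame(id = ids, chromosome = normalize_chrom(fix[, "CHROM"]),
                        position_bp = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  colnames(hapm) <- markers$id
  structure(list(samples = samples, markers = markers, haplotypes = hapm,
                 phase = "phased input required; unphased entries missing"),
            class = "phased_dataset")
}

read_phased_haps <- function(path) {
  tab <- utils::read.table(path, stringsAsFactors = FALSE)
  meta <- tab[, 1:5]
  H <- t(as.matrix(tab[, -(1:5), drop = FALSE]))
  H[H == -1] <- NA
  n <- nrow(H) / 2
  markers <- data.frame(id = as.character(meta[, 2]),
                        chromosome = normalize_chrom(meta[, 1]),
                        position_bp = as.integer(meta[, 3]),
                        ref = as.character(meta[, 4]),
                        alt = as.character(meta[, 5]),
                        stringsAsFactors = FALSE)
  colnames(H) <- markers$id
  rownames(H) <- NULL
  structure(list(samples = paste0("sample", seq_len(n)), markers = markers,
                 haplotypes = H, phase = "Oxford HAPS (phased)"),
            class = "phased_dataset")
}

#' @export
print.phased_dataset <- function(x, ...) {
  cat("Phased dataset:", length(x$samples), "samples,",
      nrow(x$markers), "markers (", x$phase, ")\n")
  invisible(x)
}

#' Write a phased dataset as VCF text
#'
#' @param dataset a `phased_dataset` (or a bare haplotype matrix plus
#'   `markers`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_phased <- function(dataset, path) {
  mk <- dataset$markers
  hap <- dataset$haplotypes
  n <- length(dataset$samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", dataset$samples), collapse = "\t")),
             con)
  fmt_allele <- function(a) ifelse(is.na(a), ".", as.character(a))
  for (m in seq_len(nrow(mk))) {
    gts <- paste(fmt_allele(hap[2 * seq_len(n) - 1, m]),
                 fmt_allele(hap[2 * seq_len(n), m]), sep = "|")
    writeLines(paste(c(mk$chromosome[m], mk$position_bp[m], mk$id[m],
                       mk$ref[m], mk$alt[m], ".", "PASS", ".", "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Long-format local ancestry table
#'
#' One row per (individual, haplotype copy, window) with the window interval,
#' the posterior probability of each population, and the maximum-posterior
#' state.
#'
#' @param fit an [ald_fit()].
#' @return data frame.
#' @export
local_ancestry <- function(fit) {
  C <- dim(fit$gamma)[1]; J <- dim(fit$gamma)[2]; K <- dim(fit$gamma)[3]
  calls <- ancestry_calls(fit)
  out <- data.frame(
    individual = rep(rep(seq_len(C / 2), each = 2), J),
    haplotype = rep(rep(1:2, C / 2), J),
    chromosome = rep(fit$windows$chromosome, each = C),
    start_cm = rep(fit$windows$start_cm, each = C),
    end_cm = rep(fit$windows$end_cm, each = C),
    state = as.vector(calls))
  for (k in seq_len(K))
    out[[paste0("gamma_", fit$pops[k])]] <- as.vector(fit$gamma[, , k])
  out
}

#' Write a BED-like per-segment ancestry track
#'
#' Merges consecutive windows with the same maximum-posterior state into
#' segments, one row per (copy, segment): chromosome, start/end cM, state.
#'
#' @param fit an [ald_fit()].
#' @param path output path (tab-delimited).
#' @return the path, invisibly.
#' @export
write_ancestry_track <- function(fit, path) {
  calls <- ancestry_calls(fit)
  rows <- list()
  for (cc in seq_len(nrow(calls))) {
    r <- rle(paste(fit$windows$chromosome, calls[cc, ]))
    ends <- cumsum(r$lengths); starts <- c(1, utils::head(ends, -1) + 1)
    rows[[cc]] <- data.frame(
      copy = cc,
      chromosome = fit$windows$chromosome[starts],
      start_cm = fit$windows$start_cm[starts],
      end_cm = fit$windows$end_cm[ends],
      state = calls[cc, starts])
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records package version, seed, and configuration as JSON next to other
#' outputs, so a run can be reproduced.
#'
#' @param path output path.
#' @param seed seed used.
#' @param config named list of configuration values.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, seed = NA, config = list()) {
  jsonlite::write_json(
    list(package = "aldmix",
         version = as.character(utils::packageVersion("aldmix")),
         date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
         seed = seed, config = config),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
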