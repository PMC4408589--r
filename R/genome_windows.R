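#' Construct a genetic map
#'
#' A genetic map relates physical positions (bp, 1-based as in VCF) to genetic
#' positions (cM) per chromosome. Within a chromosome, cM must be non-decreasing
#' in bp and marker ids must be unique.
#'
#' @param chromosome character or integer vector of chromosome labels
#'   (normalized so that `"chr20"` and `"20"` are equivalent).
#' @param position_bp integer vector of physical positions (1-based, >= 0).
#' @param position_cm numeric vector of genetic positions in centimorgans.
#' @param id optional character vector of marker ids; generated if missing.
#' @return An object of class `genetic_map`: a data frame with columns
#'   `id`, `chromosome`, `position_bp`, `position_cm`, sorted by chromosome
#'   and bp.
#' @export
genetic_map <- function(chromosome, position_bp, position_cm, id = NULL) {
  chromosome <- normalize_chrom(chromosome)
  n <- length(position_bp)
  stopifnot(length(chromosome) == n, length(position_cm) == n)
  if (is.null(id)) id <- paste0("m", seq_len(n))
  if (any(position_bp < 0)) stop("position_bp must be >= 0")
  if (any(position_cm < 0)) stop("position_cm must be >= 0")
  m <- data.frame(id = as.character(id), chromosome = chromosome,
                  position_bp = as.integer(position_bp),
                  position_cm = as.numeric(position_cm),
                  stringsAsFactors = FALSE)
  m <- m[order(m$chromosome, m$position_bp), , drop = FALSE]
  rownames(m) <- NULL
  for (ch in unique(m$chromosome)) {
    sub <- m[m$chromosome == ch, ]
    if (is.unsorted(sub$position_cm))
      stop("position_cm must be non-decreasing in bp on chromosome ", ch)
    if (anyDuplicated(sub$id))
      stop("duplicate marker ids on chromosome ", ch)
  }
  class(m) <- c("genetic_map", "data.frame")
  m
}

# "chr20", "Chr20" and "20" all mean chromosome 20
normalize_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

#' Read a genetic map from text
#'
#' Accepts the common 3-column (chromosome, bp, cM) and 4-column
#' (chromosome, id, bp, cM) whitespace- or tab-delimited dialects, with or
#' without a header line.
#'
#' @param path file path.
#' @return A [genetic_map()] object.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "[ \t]+")[[1]]
  # header detected when the last two fields are not numeric
  has_header <- suppressWarnings(any(is.na(as.numeric(toks[length(toks) - 0:1]))))
  tab <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) == 3) {
    genetic_map(tab[[1]], tab[[2]], tab[[3]])
  } else if (ncol(tab) >= 4) {
    genetic_map(tab[[1]], tab[[3]], tab[[4]], id = tab[[2]])
  } else stop("genetic map must have 3 or 4 columns")
}

#' Interpolate physical positions onto the cM scale
#'
#' Piecewise-linear interpolation between flanking map points; positions
#' beyond the map ends are extrapolated at the nearest interval's cM/bp rate.
#' Output is non-decreasing for non-decreasing input.
#'
#' @param map a [genetic_map()].
#' @param positions_bp integer vector of positions to place.
#' @param chromosome single chromosome label.
#' @return numeric vector of cM positions.
#' @export
interpolate_cm <- function(map, positions_bp, chromosome) {
  chromosome <- normalize_chrom(chromosome)
  sub <- map[map$chromosome == chromosome, , drop = FALSE]
  if (nrow(sub) == 0L) stop("unknown chromosome label: ", chromosome)
  x <- sub$position_bp; y <- sub$position_cm
  if (nrow(sub) == 1L) return(rep(y, length(positions_bp)))
  # collapse duplicate bp knots (plateaus in cM keep the mean)
  if (anyDuplicated(x)) {
    y <- tapply(y, x, mean); x <- as.numeric(names(y)); y <- as.numeric(y)
  }
  out <- stats::approx(x, y, xout = positions_bp, rule = 1)$y
  lo <- positions_bp < x[1]
  hi <- positions_bp > x[length(x)]
  if (any(lo)) {
    rate <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- pmax(0, y[1] + (positions_bp[lo] - x[1]) * rate)
  }
  if (any(hi)) {
    n <- length(x)
    rate <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + (positions_bp[hi] - x[n]) * rate
  }
  out
}

#' Tile markers into fixed-width cM windows
#'
#' The genome is split into equally sized windows (default 0.1 cM). Tiling is
#' anchored at the first marker of each chromosome, windows are half-open
#' `[start, end)`, empty windows are dropped, and every marker belongs to
#' exactly one window. The window midpoint is the mean cM of member markers,
#' and `d_cm` is the genetic distance between consecutive window midpoints
#' (missing for the first window of each chromosome).
#'
#' @param chromosome chromosome label per marker.
#' @param marker_cm cM position per marker (sorted within chromosome).
#' @param window_cm window width in cM (> 0), default 0.1.
#' @return An object of class `window_set`: a data frame with one row per
#'   non-empty window (`chromosome`, `start_cm`, `end_cm`, `mid_cm`, `d_cm`,
#'   `n_markers`) carrying a list attribute `members` of marker index vectors,
#'   and `marker_window`, the window index of every marker.
#' @export
build_windows <- function(chromosome, marker_cm, window_cm = 0.1) {
  stopifnot(window_cm > 0)
  chromosome <- normalize_chrom(chromosome)
  n <- length(marker_cm)
  if (n == 0L) stop("no markers")
  stopifnot(length(chromosome) == n)
  rows <- list(); members <- list(); marker_window <- integer(n)
  wi <- 0L
  for (ch in unique(chromosome)) {
    idx <- which(chromosome == ch)
    cm <- marker_cm[idx]
    if (is.unsorted(cm)) stop("marker_cm must be sorted within chromosome ", ch)
    anchor <- cm[1]
    bin <- floor((cm - anchor) / window_cm + 1e-9)
    prev_mid <- NA_real_
    for (b in sort(unique(bin))) {
      wi <- wi + 1L
      mem <- idx[bin == b]
      mid <- mean(marker_cm[mem])
      rows[[wi]] <- data.frame(chromosome = ch,
                               start_cm = anchor + b * window_cm,
                               end_cm = anchor + (b + 1) * window_cm,
                               mid_cm = mid,
                               d_cm = if (is.na(prev_mid)) NA_real_ else mid - prev_mid,
                               n_markers = length(mem),
                               stringsAsFactors = FALSE)
      members[[wi]] <- mem
      marker_window[mem] <- wi
      prev_mid <- mid
    }
  }
  ws <- do.call(rbind, rows)
  rownames(ws) <- NULL
  attr(ws, "members") <- members
  attr(ws, "marker_window") <- marker_window
  attr(ws, "window_cm") <- window_cm
  class(ws) <- c("window_set", "data.frame")
  ws
}

#' @export
print.window_set <- function(x, ...) {
  cat("Window set:", nrow(x), "windows over",
      length(unique(x$chromosome)), "chromosome(s);",
      sum(x$n_markers), "markers; width",
      attr(x, "window_cm"), "cM\n")
  invisible(x)
}

#' Member markers of each window
#' @param windows a `window_set`.
#' @return list of integer marker-index vectors, one per window.
#' @export
window_members <- function(windows) attr(windows, "members")
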