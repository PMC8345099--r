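#' Genomic region sets
#'
#' A `region_set` is an ordered collection of genomic intervals in BED
#' convention: 0-based starts, exclusive ends, so a region `[s, e)` spans
#' exactly `e - s` bp. It is stored as a data frame with columns `chrom`,
#' `start`, `end`, `name`, `score` plus a class label attribute (e.g.
#' `"up"`, `"down"`, `"common"`). Strand is deliberately not carried:
#' histone-acetylation peaks are unstranded.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector of 0-based inclusive starts (`>= 0`).
#' @param end integer vector of exclusive ends (`> start`).
#' @param name optional character vector of region identifiers.
#' @param score optional numeric vector (free units; often a signal value).
#' @param label single string labelling the whole set (default `""`).
#'
#' @return An object of class `region_set` (a data frame).
#' @export
region_set <- function(chrom, start, end, name = NULL, score = NULL,
                       label = "") {
  n <- length(start)
  if (length(chrom) == 1L && n != 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (n > 0) {
    if (any(is.na(chrom)) || any(!nzchar(chrom)))
      stop("chrom must be non-empty strings")
    if (any(is.na(start)) || any(is.na(end)))
      stop("start/end must not be NA")
    if (any(start < 0))
      stop("start must be >= 0")
    bad <- which(end <= start)
    if (length(bad))
      stop(sprintf("invalid interval (end <= start) at record %d: %s:%s-%s",
                   bad[1], chrom[bad[1]], format(start[bad[1]], scientific = FALSE),
                   format(end[bad[1]], scientific = FALSE)))
  }
  if (is.null(name)) name <- rep(NA_character_, n)
  if (is.null(score)) score <- rep(NA_real_, n)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = as.character(name), score = as.numeric(score),
                   stringsAsFactors = FALSE)
  structure(df, class = c("region_set", "data.frame"), label = label)
}

#' @export
print.region_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("region_set with %d regions%s\n", nrow(x),
              if (nzchar(lab)) sprintf(" [label: %s]", lab) else ""))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6))
  invisible(x)
}

#' Region widths in bp
#' @param x a `region_set`.
#' @return integer vector of widths (`end - start`).
#' @export
region_width <- function(x) x$end - x$start

#' Region midpoints (0-based)
#'
#' The midpoint of `[s, e)` is `floor((s + e) / 2)`; for even-width regions
#' the tie resolves leftward.
#' @param x a `region_set`.
#' @return numeric vector of 0-based midpoint coordinates.
#' @export
region_midpoint <- function(x) (x$start + x$end) %/% 2

#' Sort a region set by (chrom, start, end)
#' @param x a `region_set`.
#' @param decreasing unused, for generic compatibility.
#' @param ... unused.
#' @export
sort.region_set <- function(x, decreasing = FALSE, ...) {
  o <- order(x$chrom, x$start, x$end)
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(x), label = attr(x, "label"))
}

# Centralized coordinate conversions: 0-based half-open (BED) regions vs
# 1-based point positions (VCF/TSS). All overlap ops go through these two
# helpers so the off-by-one lives in exactly one place.

# region_set -> GRanges (1-based closed): [s, e) becomes [s+1, e]
.rs_as_granges <- function(rs) {
  GenomicRanges::GRanges(
    seqnames = rs$chrom,
    ranges = IRanges::IRanges(start = rs$start + 1L, end = rs$end))
}

# 1-based point positions -> GRanges of width 1. A position p overlaps
# region [s, e) iff s < p <= e, which is exactly 1-based [s+1, e] overlap.
.pos_as_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos, width = 1L))
}
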