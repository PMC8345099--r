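#' Signal per peak for super-enhancer ranking
#'
#' ROSE-style constituent signal: mean track coverage over the peak times
#' its width (i.e. summed per-bp signal). No input subtraction is applied;
#' tracks may already be background-corrected.
#'
#' @param track a `coverage_track`.
#' @param peaks a [region_set()].
#' @return the peaks with the signal written into the score column.
#' @export
peak_signal <- function(track, peaks) {
  peaks$score <- track_region_mean(track, peaks) * region_width(peaks)
  peaks
}

#' Stitch peaks into enhancer clusters
#'
#' Merges same-chromosome peaks transitively whenever the gap to the next
#' peak (`next start - previous end`) is at most the stitching distance.
#' Optionally excludes peaks lying fully within a TSS exclusion zone before
#' stitching. The stitched region is the hull of its constituents and its
#' total signal the sum of the constituent scores.
#'
#' @param peaks a [region_set()] whose score column carries per-peak signal
#'   (see [peak_signal()]); `NA` scores count as 0.
#' @param stitch_bp stitching distance in bp (default 12500, the canonical
#'   ROSE default).
#' @param tss optional `tss_annotation` for promoter exclusion.
#' @param tss_exclusion_bp half-width of the exclusion zone around each TSS
#'   (default 0 = no exclusion).
#' @return a `stitched_enhancers` data frame: `chrom`, `start`, `end`,
#'   `n_constituents`, `total_signal`.
#' @export
stitch_peaks <- function(peaks, stitch_bp = 12500, tss = NULL,
                         tss_exclusion_bp = 0) {
  if (stitch_bp < 0) stop("stitch distance must be >= 0")
  if (!is.null(tss) && tss_exclusion_bp > 0 && nrow(peaks) > 0) {
    zone <- region_set(tss$chrom, pmax(tss$tss - 1 - tss_exclusion_bp, 0),
                       tss$tss - 1 + tss_exclusion_bp + 1)
    gp <- .rs_as_granges(peaks)
    gz <- .rs_as_granges(zone)
    within <- IRanges::overlapsAny(gp, gz, type = "within")
    peaks <- peaks[!within, , drop = FALSE]
  }
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    n_constituents = integer(), total_signal = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(peaks) > 0) {
    o <- order(peaks$chrom, peaks$start, peaks$end)
    p <- peaks[o, , drop = FALSE]
    sig <- ifelse(is.na(p$score), 0, p$score)
    new_cluster <- c(TRUE, p$chrom[-1] != p$chrom[-nrow(p)] |
                     p$start[-1] - cummax_by_chrom(p) > stitch_bp)
    cl <- cumsum(new_cluster)
    out <- data.frame(
      chrom = tapply(p$chrom, cl, `[`, 1),
      start = as.numeric(tapply(p$start, cl, min)),
      end = as.numeric(tapply(p$end, cl, max)),
      n_constituents = as.integer(tapply(sig, cl, length)),
      total_signal = as.numeric(tapply(sig, cl, sum)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(out, class = c("stitched_enhancers", "data.frame"),
            stitch_bp = stitch_bp)
}

# running max of 'end' within chromosome runs, lagged by one: the gap test
# must use the furthest end seen so far, not just the previous peak's end
cummax_by_chrom <- function(p) {
  ends <- numeric(nrow(p) - 1L)
  cm <- p$end[1]
  for (i in seq_len(nrow(p) - 1L)) {
    if (p$chrom[i + 1L] != p$chrom[i]) cm <- 0
    ends[i] <- cm
    cm <- max(cm, p$end[i + 1L])
  }
  ends
}

#' Call super-enhancers by the rank-curve tangent rule
#'
#' Sorts stitched enhancers ascending by total signal, scales rank and
#' signal to the unit square, and sets the cutoff at the signal of the
#' first rank where the discrete slope of the scaled curve exceeds 1 (the
#' point where the curve rises faster than the diagonal). Enhancers with
#' total signal above the cutoff are flagged super. With all-equal signals
#' the curve is flat and no super-enhancers are called.
#'
#' @param stitched a `stitched_enhancers` data frame (>= 3 rows).
#' @return an `se_call`: the table with `rank` (descending in signal,
#'   1 = strongest), `is_super`, plus attributes `cutoff` and `curve`
#'   (scaled coordinates).
#' @export
call_superenhancers <- function(stitched) {
  n <- nrow(stitched)
  if (n < 3) stop("need at least 3 stitched enhancers")
  s <- sort(stitched$total_signal)
  rng <- s[n] - s[1]
  if (rng == 0) {
    warning("all stitched signals equal; no super-enhancers called")
    cutoff <- Inf
    curve <- data.frame(x = (seq_len(n) - 1) / (n - 1), y = rep(0, n))
  } else {
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (s - s[1]) / rng
    slope <- diff(y) / diff(x)
    idx <- which(slope > 1)
    if (length(idx) == 0) {
      cutoff <- Inf
    } else {
      cutoff <- s[idx[1]]
    }
    curve <- data.frame(x = x, y = y)
  }
  out <- stitched
  out$is_super <- out$total_signal > cutoff
  out$rank <- rank(-out$total_signal, ties.method = "first")
  structure(out, class = c("se_call", "data.frame"),
            cutoff = cutoff, curve = curve)
}

#' @export
print.se_call <- function(x, ...) {
  cat(sprintf("se_call: %d / %d stitched enhancers super (cutoff %.4g)\n",
              sum(x$is_super), nrow(x), attr(x, "cutoff")))
  invisible(x)
}

#' Write super-enhancer calls as BED + ranking table
#' @param se an `se_call`.
#' @param prefix output path prefix; writes `<prefix>_super.bed`,
#'   `<prefix>_typical.bed`, `<prefix>_ranking.tsv`.
#' @return the three paths, invisibly.
#' @export
write_se_call <- function(se, prefix) {
  mk <- function(sel) region_set(se$chrom[sel], se$start[sel], se$end[sel],
                                 name = sprintf("SE_%d", se$rank[sel]),
                                 score = se$total_signal[sel])
  p1 <- paste0(prefix, "_super.bed")
  p2 <- paste0(prefix, "_typical.bed")
  p3 <- paste0(prefix, "_ranking.tsv")
  write_bed(mk(se$is_super), p1)
  write_bed(mk(!se$is_super), p2)
  tab <- as.data.frame(se)
  tab$scaled_rank <- attr(se, "curve")$x[rank(se$total_signal,
                                              ties.method = "first")]
  .write_tsv(tab[order(tab$rank), ], p3)
  invisible(c(p1, p2, p3))
}
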