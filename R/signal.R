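#' Build a peak-centered signal matrix
#'
#' For each region and sample, computes per-bin means of per-bp coverage
#' over a window centered on the region midpoint (`floor((start+end)/2)`,
#' even-width ties resolved leftward): the window is
#' `[center - window/2, center + window/2)`. Positions outside the
#' chromosome or the track contribute 0.
#'
#' @param tracks named list of `coverage_track` objects (one per sample).
#' @param peaks a [region_set()].
#' @param window_bp window size in bp (default 10000, i.e. a 10 kb window
#'   around the peak center).
#' @param bin_bp bin size in bp (default 100); must divide `window_bp`.
#' @return a `signal_matrix`: numeric array regions x bins x samples with
#'   attributes `regions`, `window_bp`, `bin_bp`.
#' @export
extract_signal_matrix <- function(tracks, peaks, window_bp = 10000,
                                  bin_bp = 100) {
  if (window_bp %% bin_bp != 0)
    stop("window must be an even multiple of bin size")
  nbins <- window_bp %/% bin_bp
  samples <- names(tracks)
  if (is.null(samples) || any(!nzchar(samples)))
    stop("tracks must be a named list")
  n <- nrow(peaks)
  arr <- array(0, dim = c(n, nbins, length(samples)),
               dimnames = list(peaks$name, NULL, samples))
  if (n > 0) {
    centers <- region_midpoint(peaks)
    w0 <- centers - window_bp %/% 2
    for (s in seq_along(samples)) {
      tr <- tracks[[s]]
      for (i in seq_len(n)) {
        qs <- w0[i]
        per_bp <- numeric(window_bp)
        lo <- max(qs, 0)
        if (lo < qs + window_bp) {
          v <- track_query(tr, peaks$chrom[i], lo, qs + window_bp)
          per_bp[(lo - qs + 1):window_bp] <- v
        }
        arr[i, , s] <- colMeans(matrix(per_bp, nrow = bin_bp))
      }
    }
  }
  structure(arr, class = "signal_matrix", regions = peaks,
            window_bp = window_bp, bin_bp = bin_bp)
}

#' @export
print.signal_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "signal_matrix: %d regions x %d bins x %d samples (%d bp window, %d bp bins)\n",
    d[1], d[2], d[3], attr(x, "window_bp"), attr(x, "bin_bp")))
  invisible(x)
}

# quantile-normalize the columns of a features x samples matrix:
# each sample's values are replaced by the cross-sample mean of sorted
# values at the same rank; ties receive the mean over their tied rank block
.qnorm_matrix <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  cm <- cumsum(ref)
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    rmin <- rank(x, ties.method = "min")
    rmax <- rank(x, ties.method = "max")
    out[, j] <- (cm[rmax] - c(0, cm)[rmin]) / (rmax - rmin + 1)
  }
  out
}

#' Quantile-normalize signal across samples
#'
#' Equalizes the marginal signal distribution of every sample: values are
#' replaced by the mean across samples of the sorted values at the same
#' rank, ties receiving the mean over their tied rank positions. For a
#' `signal_matrix` the normalization operates on the flattened region x bin
#' vector of each sample (whole-distribution normalization, not per-bin).
#'
#' @param x a `signal_matrix` (regions x bins x samples) or a plain numeric
#'   matrix (features x samples).
#' @return object of the same shape with normalized values; after the
#'   operation all per-sample sorted vectors are identical.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "signal_matrix")) {
    d <- dim(x)
    if (d[3] < 2) {
      warning("single sample: quantile normalization is the identity")
      return(x)
    }
    flat <- matrix(as.vector(x), nrow = d[1] * d[2], ncol = d[3])
    norm <- .qnorm_matrix(flat)
    out <- x
    out[] <- array(norm, dim = d)
    return(out)
  }
  m <- as.matrix(x)
  if (ncol(m) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(m)
  }
  .qnorm_matrix(m)
}

#' Per-region per-sample mean signal over the region body
#'
#' Averages the bins of a `signal_matrix` whose centers fall inside each
#' region (the window typically extends beyond the peak; background bins
#' outside the peak are excluded from the mean).
#'
#' @param smat a `signal_matrix`.
#' @return numeric matrix regions x samples.
#' @export
region_body_means <- function(smat) {
  peaks <- attr(smat, "regions")
  bin <- attr(smat, "bin_bp")
  window <- attr(smat, "window_bp")
  nbins <- window %/% bin
  centers <- region_midpoint(peaks)
  w0 <- centers - window %/% 2
  bin_centers <- (seq_len(nbins) - 1) * bin + bin / 2
  out <- matrix(0, nrow(peaks), dim(smat)[3],
                dimnames = list(peaks$name, dimnames(smat)[[3]]))
  for (i in seq_len(nrow(peaks))) {
    pos <- w0[i] + bin_centers
    sel <- pos >= peaks$start[i] & pos < peaks$end[i]
    if (!any(sel)) sel <- rep(TRUE, nbins)  # region narrower than one bin
    out[i, ] <- apply(smat[i, sel, , drop = FALSE], 3, mean)
  }
  out
}

#' Spike-in-normalized ChIP-qPCR fold enrichment
#'
#' Each record is normalized to its input and to the exogenous spike-in
#' chromatin recovery, then expressed relative to a reference condition:
#' `[(target/input) / (spike_target/spike_input)]` divided by the same
#' quantity for the reference. The reference maps to 1.
#'
#' @param record,reference lists (or one-row data frames) with fields
#'   `target`, `input`, `spike_target`, `spike_input`; all quantities, not
#'   Ct values.
#' @return fold enrichment relative to the reference (reference -> 1).
#' @export
normalize_chip_qpcr <- function(record, reference) {
  q <- function(r) {
    if (any(unlist(r[c("input", "spike_target", "spike_input")]) == 0))
      stop("zero denominator in qPCR record")
    (r$target / r$input) / (r$spike_target / r$spike_input)
  }
  qr <- q(reference)
  if (qr == 0) stop("reference record has zero normalized signal")
  q(record) / qr
}

#' Relative expression (ratio of ratios)
#'
#' Classic reference-gene normalization: `(target/ref)` in the sample
#' divided by `(target/ref)` in the control sample; the control maps to 1.
#'
#' @param target,ref target- and reference-gene quantities in the sample.
#' @param target_ctrl,ref_ctrl the same in the control sample.
#' @return relative expression (control -> 1).
#' @export
relative_expression <- function(target, ref, target_ctrl, ref_ctrl) {
  if (ref == 0 || ref_ctrl == 0 || target_ctrl == 0)
    stop("zero reference quantity")
  (target / ref) / (target_ctrl / ref_ctrl)
}

#' Relative expression from Ct values (2^-ddCt)
#'
#' Convenience wrapper mapping Ct values to quantities at fixed efficiency 2
#' and delegating to [relative_expression()].
#'
#' @param ct_target,ct_ref sample Ct values for target and reference gene.
#' @param ct_target_ctrl,ct_ref_ctrl control-sample Ct values.
#' @return relative expression (control -> 1).
#' @export
relative_expression_ct <- function(ct_target, ct_ref, ct_target_ctrl,
                                   ct_ref_ctrl) {
  relative_expression(2^-ct_target, 2^-ct_ref, 2^-ct_target_ctrl,
                      2^-ct_ref_ctrl)
}

#' Serialize a signal matrix as long-format TSV
#' @param smat a `signal_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(smat, path) {
  d <- dim(smat)
  df <- data.frame(
    region = rep(dimnames(smat)[[1]], times = d[2] * d[3]),
    bin = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    sample = rep(dimnames(smat)[[3]], each = d[1] * d[2]),
    value = as.vector(smat))
  .write_tsv(df, path)
}
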