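#' Per-region signal statistics for a two-condition comparison
#'
#' Computes per-condition mean signal over each region body and the
#' pseudocounted fold change `(mean2 + eps) / (mean1 + eps)`. Samples are
#' averaged within condition.
#'
#' @param smat a `signal_matrix` (normally quantile-normalized).
#' @param cond1,cond2 character vectors of sample names per condition.
#' @param eps fold-change pseudocount in normalized signal units
#'   (default 1).
#' @return a `region_stats` data frame: `name`, `chrom`, `start`, `end`,
#'   `width`, `mean1`, `mean2`, `fc`.
#' @export
region_stats <- function(smat, cond1, cond2, eps = 1) {
  bm <- region_body_means(smat)
  if (!all(c(cond1, cond2) %in% colnames(bm)))
    stop("condition sample names not all present in matrix")
  peaks <- attr(smat, "regions")
  m1 <- rowMeans(bm[, cond1, drop = FALSE])
  m2 <- rowMeans(bm[, cond2, drop = FALSE])
  structure(data.frame(
    name = peaks$name, chrom = peaks$chrom, start = peaks$start,
    end = peaks$end, width = region_width(peaks),
    mean1 = m1, mean2 = m2, fc = (m2 + eps) / (m1 + eps),
    row.names = NULL, stringsAsFactors = FALSE),
    class = c("region_stats", "data.frame"), eps = eps)
}

# per-region clustering features: per-bin log2 ratio profiles, either over
# the full window or over the region body rescaled to a fixed length
.cluster_features <- function(smat, cond1, cond2, eps, features, body_bins) {
  d <- dim(smat)
  s1 <- apply(smat[, , cond1, drop = FALSE], c(1, 2), mean)
  s2 <- apply(smat[, , cond2, drop = FALSE], c(1, 2), mean)
  lr <- log2((s2 + eps) / (s1 + eps))
  if (features == "window") return(lr)
  peaks <- attr(smat, "regions")
  bin <- attr(smat, "bin_bp")
  window <- attr(smat, "window_bp")
  centers <- region_midpoint(peaks)
  w0 <- centers - window %/% 2
  bin_centers <- (seq_len(d[2]) - 1) * bin + bin / 2
  t(vapply(seq_len(d[1]), function(i) {
    pos <- w0[i] + bin_centers
    sel <- which(pos >= peaks$start[i] & pos < peaks$end[i])
    if (length(sel) < 2) sel <- seq_len(d[2])
    stats::approx(seq_along(sel), lr[i, sel], n = body_bins)$y
  }, numeric(body_bins)))
}

#' K-means clustering of differential signal profiles
#'
#' Clusters regions on per-bin `log2((s2+eps)/(s1+eps))` profiles and labels
#' each cluster by its mean log-ratio: above `log2(1.3)` is `up`, below
#' `log2(0.75)` is `down`, otherwise `common`. By default the profile is
#' taken over the region body rescaled to a fixed bin count
#' (scale-regions), so that the feature distance reflects the differential
#' response rather than the peak width; `features = "window"` uses the raw
#' window profile instead.
#'
#' @param smat a `signal_matrix` covering both conditions.
#' @param cond1,cond2 sample names per condition.
#' @param K number of clusters (default 3: common plus two differential
#'   classes).
#' @param seed RNG seed for the K-means initialization.
#' @param eps log-ratio pseudocount (default 1).
#' @param features `"body"` (default) or `"window"`.
#' @param body_bins profile length for body rescaling (default 20).
#' @param nstart K-means restarts (fixed default 10 for determinism given
#'   the seed).
#' @return a `cluster_result`: data frame (`name`, `cluster`, `label`,
#'   `mean_log_ratio`) plus attributes `K`, `seed`, `inertia`,
#'   `cluster_labels`.
#' @export
cluster_regions <- function(smat, cond1, cond2, K = 3, seed = 1, eps = 1,
                            features = c("body", "window"), body_bins = 20,
                            nstart = 10) {
  features <- match.arg(features)
  if (K < 2) stop("K must be >= 2")
  n <- dim(smat)[1]
  if (K > n) stop("K exceeds the number of regions")
  X <- .cluster_features(smat, cond1, cond2, eps, features, body_bins)
  region_mlr <- rowMeans(X)
  if (stats::sd(as.vector(X)) == 0) {
    # degenerate: all profiles identical; a single effective cluster
    cl <- rep(1L, n)
    centers_mlr <- mean(X)
    inertia <- 0
  } else {
    set.seed(seed)
    km <- stats::kmeans(X, centers = K, nstart = nstart, iter.max = 100)
    cl <- km$cluster
    centers_mlr <- rowMeans(km$centers)
    inertia <- km$tot.withinss
  }
  lab_of <- function(m) if (m > log2(1.3)) "up"
           else if (m < log2(0.75)) "down" else "common"
  cluster_labels <- vapply(centers_mlr, lab_of, "")
  peaks <- attr(smat, "regions")
  structure(data.frame(
    name = peaks$name, cluster = cl, label = cluster_labels[cl],
    mean_log_ratio = region_mlr, row.names = NULL, stringsAsFactors = FALSE),
    class = c("cluster_result", "data.frame"),
    K = K, seed = seed, inertia = inertia, cluster_labels = cluster_labels)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d regions, K = %d (inertia %.4g)\n",
              nrow(x), attr(x, "K"), attr(x, "inertia")))
  print(table(x$label))
  invisible(x)
}

#' Threshold filter for differential acetylation peaks
#'
#' Applies the explicit differential-peak rule: a region is retained only if
#' its width exceeds `width_min` (default 2 kb) and its peak intensity
#' exceeds `intensity_min` (default 1000 normalized units); retained regions
#' with fold change above `fc_up` (default 1.3) are called up, below
#' `fc_down` (default 0.75) down. Intensity is by default the maximum of
#' the two condition means, so a peak silenced in one condition is still
#' callable; `intensity_mode = "mean"` uses the mean of means.
#'
#' @param stats a `region_stats` data frame (computed on quantile-normalized
#'   signal).
#' @param width_min minimum width in bp (exclusive).
#' @param intensity_min minimum intensity (exclusive).
#' @param fc_up,fc_down fold-change thresholds (exclusive).
#' @param intensity_mode `"max"` (default) or `"mean"`.
#' @return list with `up` and `down` [region_set()]s (fold change in the
#'   score column) and the annotated `stats` table (`call` column).
#' @export
filter_differential_peaks <- function(stats, width_min = 2000,
                                      intensity_min = 1000,
                                      fc_up = 1.3, fc_down = 0.75,
                                      intensity_mode = c("max", "mean")) {
  intensity_mode <- match.arg(intensity_mode)
  intensity <- if (intensity_mode == "max") pmax(stats$mean1, stats$mean2)
               else (stats$mean1 + stats$mean2) / 2
  pass <- stats$width > width_min & intensity > intensity_min
  call <- rep("none", nrow(stats))
  call[pass & stats$fc > fc_up] <- "up"
  call[pass & stats$fc < fc_down] <- "down"
  mk <- function(side) {
    sel <- call == side
    region_set(stats$chrom[sel], stats$start[sel], stats$end[sel],
               name = stats$name[sel], score = stats$fc[sel], label = side)
  }
  stats$call <- call
  list(up = mk("up"), down = mk("down"), stats = stats)
}

#' Annotate regions with their nearest TSS
#'
#' For each region, finds the TSS nearest to the region midpoint by
#' absolute distance and reports a signed distance: midpoint minus TSS,
#' sign flipped for minus-strand genes, so positive means downstream of the
#' TSS. Absolute-distance ties are broken by gene name (lexicographic).
#' Regions on chromosomes absent from the annotation get `NA` distance and
#' are flagged.
#'
#' @param regions a [region_set()].
#' @param tss a `tss_annotation`.
#' @return data frame: `name`, `gene`, `distance` (bp, signed), `flag`.
#' @export
annotate_nearest_tss <- function(regions, tss) {
  if (nrow(tss) == 0) stop("TSS annotation is empty")
  n <- nrow(regions)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  flag <- rep("", n)
  mids <- region_midpoint(regions)          # 0-based
  for (ch in unique(regions$chrom)) {
    ridx <- which(regions$chrom == ch)
    t <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(t) == 0) { flag[ridx] <- "no_tss_on_chrom"; next }
    o <- order(t$tss, t$gene)
    pos <- t$tss[o] - 1                      # to 0-based
    gn <- t$gene[o]
    st <- t$strand[o]
    for (i in ridx) {
      m <- mids[i]
      j <- findInterval(m, pos)
      cand <- unique(pmin(pmax(c(j, j + 1L), 1L), length(pos)))
      best_d <- min(abs(m - pos[cand]))
      # entries with |distance| <= best_d are contiguous in sorted order;
      # expand outward to catch duplicated positions, then keep exact ties
      lo <- min(cand); hi <- max(cand)
      while (lo > 1L && abs(m - pos[lo - 1L]) <= best_d) lo <- lo - 1L
      while (hi < length(pos) && abs(m - pos[hi + 1L]) <= best_d)
        hi <- hi + 1L
      ties <- (lo:hi)[abs(m - pos[lo:hi]) == best_d]
      pick <- ties[order(gn[ties])][1]
      raw <- m - pos[pick]
      gene[i] <- gn[pick]
      dist[i] <- if (st[pick] == "-") -raw else raw
    }
  }
  data.frame(name = regions$name, gene = gene, distance = dist, flag = flag,
             stringsAsFactors = FALSE)
}

#' Histogram of TSS distances
#' @param ann output of [annotate_nearest_tss()].
#' @param breaks histogram breaks in bp (passed to [hist()]).
#' @return a histogram object (counts of signed distances).
#' @export
tss_distance_histogram <- function(ann, breaks = seq(-50000, 50000, 5000)) {
  d <- ann$distance[!is.na(ann$distance)]
  d <- pmin(pmax(d, min(breaks)), max(breaks))
  graphics::hist(d, breaks = breaks, plot = FALSE)
}

#' Correlate two marks over the same regions
#'
#' Pearson and Spearman correlation of per-region mean signals of two
#' signal matrices over the same region universe (e.g. H3K9ac vs H3K27ac at
#' differential regions).
#'
#' @param smatA,smatB `signal_matrix` objects over identical regions.
#' @return list with `pearson`, `spearman`, `n` and the per-region
#'   `scatter` table.
#' @export
correlate_marks <- function(smatA, smatB) {
  ra <- attr(smatA, "regions"); rb <- attr(smatB, "regions")
  if (nrow(ra) != nrow(rb) || !all(ra$name == rb$name))
    stop("matrices must cover the same regions")
  if (nrow(ra) < 3) stop("need at least 3 regions to correlate")
  a <- rowMeans(region_body_means(smatA))
  b <- rowMeans(region_body_means(smatB))
  list(pearson = stats::cor(a, b, method = "pearson"),
       spearman = stats::cor(a, b, method = "spearman"),
       n = length(a),
       scatter = data.frame(name = ra$name, meanA = a, meanB = b,
                            stringsAsFactors = FALSE))
}

# overlap pairs between two region sets; min_frac = required reciprocal
# overlap fraction (0 = any overlap)
.overlap_pairs <- function(rsA, rsB, min_frac = 0) {
  if (nrow(rsA) == 0 || nrow(rsB) == 0)
    return(data.frame(a = integer(), b = integer()))
  ga <- .rs_as_granges(rsA)
  gb <- .rs_as_granges(rsB)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  a <- S4Vectors::queryHits(hits)
  b <- S4Vectors::subjectHits(hits)
  if (min_frac > 0 && length(a)) {
    ov <- GenomicRanges::width(GenomicRanges::pintersect(ga[a], gb[b]))
    keep <- ov / GenomicRanges::width(ga[a]) >= min_frac &
            ov / GenomicRanges::width(gb[b]) >= min_frac
    a <- a[keep]; b <- b[keep]
  }
  data.frame(a = a, b = b)
}

#' Regions with inverse differential response in two comparisons
#'
#' Given up/down calls from two independent comparisons (e.g. resistant vs
#' sensitive, and remodeler-knockdown vs control), finds set A = regions up
#' in comparison A that overlap a region down in comparison B, and set B =
#' the symmetric down-in-A / up-in-B set. Each matched pair carries both
#' fold changes (taken from the score columns). Default overlap semantics is
#' any overlap; `min_frac` switches to a reciprocal-fraction requirement.
#'
#' @param diffA,diffB lists with `up` and `down` [region_set()]s (as
#'   returned by [filter_differential_peaks()]).
#' @param min_frac reciprocal overlap fraction in `[0, 1]` (default 0 = any
#'   overlap).
#' @return an `inverse_regions` list: `A` and `B` data frames with the
#'   matched coordinates and both fold changes.
#' @export
find_inverse_regions <- function(diffA, diffB, min_frac = 0) {
  pair_table <- function(x, y) {
    p <- .overlap_pairs(x, y, min_frac)
    data.frame(name = x$name[p$a], chrom = x$chrom[p$a],
               start = x$start[p$a], end = x$end[p$a],
               fc_a = x$score[p$a],
               match_name = y$name[p$b], fc_b = y$score[p$b],
               stringsAsFactors = FALSE)
  }
  A <- pair_table(diffA$up, diffB$down)
  B <- pair_table(diffA$down, diffB$up)
  structure(list(A = A, B = B), class = "inverse_regions")
}

#' @export
print.inverse_regions <- function(x, ...) {
  cat(sprintf(
    "inverse_regions: %d up/down pairs (A), %d down/up pairs (B)\n",
    nrow(x$A), nrow(x$B)))
  invisible(x)
}
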