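#' Count variants per region
#'
#' A variant at 1-based position `p` counts for region `[s, e)` iff
#' `s < p <= e`; a variant may count in several overlapping regions.
#' Densities are per kb of region width.
#'
#' @param variants a `variant_set`.
#' @param regions a [region_set()].
#' @param condition label carried into the output (default the variant
#'   set's sample attribute).
#' @return data frame: `name`, `chrom`, `start`, `end`, `count`,
#'   `density` (variants per kb), `condition`.
#' @export
count_variants_per_region <- function(variants, regions,
                                      condition = attr(variants, "sample")) {
  n <- nrow(regions)
  counts <- integer(n)
  if (n > 0 && nrow(variants) > 0) {
    hits <- GenomicRanges::findOverlaps(
      .pos_as_granges(variants$chrom, variants$pos),
      .rs_as_granges(regions))
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = n)
    counts <- as.integer(tab)
  }
  w <- region_width(regions)
  data.frame(name = regions$name, chrom = regions$chrom,
             start = regions$start, end = regions$end,
             count = counts, density = counts / (w / 1000),
             condition = if (is.null(condition)) "" else condition,
             stringsAsFactors = FALSE)
}

# Mann-Whitney comparison used across the package: exact two-sided p when
# both groups have n <= 8 and no ties, otherwise the normal approximation
# with tie correction and no continuity correction (so identical groups
# give p = 1 exactly). All-tied input returns p = 1 with a warning.
.mw_test <- function(a, b) {
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied; p set to 1")
    return(list(U = length(a) * length(b) / 2, p = 1))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= 8 && length(b) <= 8
  ht <- suppressWarnings(stats::wilcox.test(
    a, b, exact = exact, correct = FALSE, alternative = "two.sided"))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Compare variant density between two region classes
#'
#' Two-sided Mann-Whitney U test on per-region densities (exact for small
#' tie-free groups, normal approximation with tie correction otherwise).
#'
#' @param densA,densB numeric vectors of per-region densities (or the
#'   data frames from [count_variants_per_region()], in which case the
#'   `density` column is used). Each group needs >= 3 regions.
#' @return list: `U`, `p` (two-sided), `median_a`, `median_b`, `n_a`,
#'   `n_b`.
#' @export
compare_density <- function(densA, densB) {
  a <- if (is.data.frame(densA)) densA$density else densA
  b <- if (is.data.frame(densB)) densB$density else densB
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 regions per group")
  r <- .mw_test(a, b)
  list(U = r$U, p = r$p, median_a = stats::median(a),
       median_b = stats::median(b), n_a = length(a), n_b = length(b))
}
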