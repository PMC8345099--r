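#' Cumulative region signal per gene
#'
#' Sums the signal of all regions assigned to each gene (assignments
#' typically come from [annotate_nearest_tss()]). Genes in `genes` without
#' any region get 0.
#'
#' @param gene per-region gene assignment (character).
#' @param signal per-region signal (numeric, same length).
#' @param genes optional universe of genes to report (default: the genes
#'   present in the assignment).
#' @return named numeric vector gene -> cumulative signal.
#' @export
cumulative_signal_per_gene <- function(gene, signal, genes = NULL) {
  keep <- !is.na(gene)
  sums <- tapply(signal[keep], gene[keep], sum)
  if (is.null(genes)) genes <- sort(unique(gene[keep]))
  out <- stats::setNames(rep(0, length(genes)), genes)
  common <- intersect(names(sums), genes)
  out[common] <- sums[common]
  out
}

#' Signature-based resistance index over an expression panel
#'
#' Each gene is z-scored across the panel; a sample's index is the mean z
#' of signature-up genes minus the mean z of signature-down genes. Samples
#' are grouped by GI50 at the threshold (above = resistant) and compared by
#' a two-sided Mann-Whitney test. Genes with zero variance contribute z = 0;
#' signature genes missing from the matrix are dropped with a warning.
#'
#' @param expr numeric matrix genes x samples (log2 expression).
#' @param sig_up,sig_down character vectors of signature genes.
#' @param gi50 named numeric vector, GI50 in micromolar per sample.
#' @param threshold_uM GI50 split point (default 20).
#' @return a `resistance_index` list: `index` (named per-sample), `group`
#'   (factor sensitive/resistant), `U`, `p`, group means and sizes.
#' @export
resistance_index <- function(expr, sig_up, sig_down, gi50,
                             threshold_uM = 20) {
  up <- intersect(toupper(sig_up), rownames(expr))
  down <- intersect(toupper(sig_down), rownames(expr))
  if (length(up) < length(sig_up) || length(down) < length(sig_down))
    warning("signature genes missing from expression matrix were dropped")
  if (length(up) == 0 && length(down) == 0)
    stop("empty signature after intersecting with the expression matrix")
  if (!all(colnames(expr) %in% names(gi50)))
    stop("GI50 missing for some samples")
  z <- t(apply(expr, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  colnames(z) <- colnames(expr)
  mz <- function(g) if (length(g)) colMeans(z[g, , drop = FALSE]) else 0
  idx <- mz(up) - mz(down)
  grp <- factor(ifelse(gi50[colnames(expr)] > threshold_uM,
                       "resistant", "sensitive"),
                levels = c("sensitive", "resistant"))
  if (min(table(grp)) < 2) stop("need >= 2 samples per GI50 group")
  r <- .mw_test(idx[grp == "resistant"], idx[grp == "sensitive"])
  structure(list(index = idx, group = grp, U = r$U, p = r$p,
                 mean_resistant = mean(idx[grp == "resistant"]),
                 mean_sensitive = mean(idx[grp == "sensitive"]),
                 n_resistant = sum(grp == "resistant"),
                 n_sensitive = sum(grp == "sensitive")),
            class = "resistance_index")
}

#' @export
print.resistance_index <- function(x, ...) {
  cat(sprintf(
    "resistance_index: %d resistant (mean %.3f) vs %d sensitive (mean %.3f), MW p = %.3g\n",
    x$n_resistant, x$mean_resistant, x$n_sensitive, x$mean_sensitive, x$p))
  invisible(x)
}

#' Combined gene ranking score
#'
#' Ranks genes by the product of three components: expression log2 fold
#' change, replicate reproducibility as `-log10(FDR)`, and cumulative
#' acetylation signal as `log10(1 + signal)`. The product form is a
#' reconstruction of a score that combines exactly these three named
#' ingredients; any component at its null value (log2FC 0, FDR 1, signal 0)
#' annihilates the score. FDR 0 is clamped to the machine floor with a
#' warning. Descending rank; ties broken by FDR then gene name.
#'
#' @param gene character vector of gene names.
#' @param log2fc expression log2 fold change (resistant / sensitive).
#' @param fdr false discovery rate in (0, 1].
#' @param signal cumulative region signal per gene (>= 0).
#' @return a `gene_score_table` data frame sorted by rank: `gene`,
#'   `log2fc`, `fdr`, `signal`, `score`, `rank`.
#' @export
combined_rank_score <- function(gene, log2fc, fdr, signal) {
  if (any(fdr < 0 | fdr > 1)) stop("FDR must be in (0, 1]")
  if (any(fdr == 0)) {
    warning("FDR of 0 clamped to machine floor")
    fdr[fdr == 0] <- .Machine$double.xmin
  }
  if (any(signal < 0)) stop("cumulative signal must be >= 0")
  score <- log2fc * (-log10(fdr)) * log10(1 + signal)
  o <- order(-score, fdr, gene)
  out <- data.frame(gene = gene, log2fc = log2fc, fdr = fdr,
                    signal = signal, score = score,
                    stringsAsFactors = FALSE)[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("gene_score_table", "data.frame"))
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test per gene set: with universe size `N`,
#' set size `m` (after intersecting with the universe), selection size `n`
#' and overlap `k`, `p = P(X >= k)`. Benjamini-Hochberg adjustment across
#' the tested sets. This is a simplified enrichment on nearest-TSS gene
#' assignments; it does not model locus length (see the package vignette
#' for the bias caveat). Sets disjoint from the universe are skipped with a
#' note.
#'
#' @param selected character vector of selected genes (must be a subset of
#'   `universe`).
#' @param universe character vector, the assayable gene universe.
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param alpha reporting threshold on the raw p-value (default 0.05).
#' @return data frame: `set`, `k`, `m`, `n`, `N`, `p`, `q`, `enriched`
#'   (p <= alpha), sorted by p.
#' @export
enrich_gene_sets <- function(selected, universe, collection, alpha = 0.05) {
  selected <- unique(toupper(selected))
  universe <- unique(toupper(universe))
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(toupper(collection[[nm]]), universe)
    m <- length(set)
    if (m == 0) {
      message("gene set '", nm, "' disjoint from universe; skipped")
      return(NULL)
    }
    k <- length(intersect(set, selected))
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, m = m, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(set = character(), k = integer(), m = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), enriched = logical()))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$p <= alpha
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
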