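#' Reads-per-million normalization of screen counts
#'
#' Within each (condition, replicate) library, `rpm = 1e6 * (count + pc) /
#' sum(count + pc)`. The pseudocount keeps later depletion ratios finite.
#'
#' @param counts a `screen_counts` table.
#' @param pseudocount added to every count before normalization (default 1).
#' @return the table with an `rpm` column.
#' @export
normalize_counts <- function(counts, pseudocount = 1) {
  dt <- data.table::as.data.table(counts)
  dt[, pc := count + pseudocount]
  dt[, lib := sum(pc), by = .(condition, replicate)]
  if (any(dt$lib <= 0)) stop("empty library in a (condition, replicate)")
  dt[, rpm := 1e6 * pc / lib]
  out <- as.data.frame(dt[, .(shRNA, gene, condition, replicate, count, rpm)])
  structure(out, class = c("screen_counts", "data.frame"))
}

#' Per-shRNA depletion ratios (day 14 / pool)
#'
#' Divides day-14 rpm by the pool rpm of the same shRNA. With per-replicate
#' pools the matching replicate's pool is used; with a single sequenced
#' pool it is broadcast to all replicates. shRNAs absent from the pool are
#' excluded with a warning.
#'
#' @param rpm output of [normalize_counts()].
#' @param pool_condition name of the pool condition (default `"pool"`).
#' @return data frame: `shRNA`, `gene`, `condition`, `replicate`, `ratio`
#'   for every non-pool condition.
#' @export
shrna_depletion <- function(rpm, pool_condition = "pool") {
  pool <- rpm[rpm$condition == pool_condition, , drop = FALSE]
  if (nrow(pool) == 0) stop("pool condition absent from table")
  rest <- rpm[rpm$condition != pool_condition, , drop = FALSE]
  per_rep <- length(unique(pool$replicate)) > 1
  key <- if (per_rep) paste(rest$shRNA, rest$replicate, sep = "\r")
         else rest$shRNA
  pkey <- if (per_rep) paste(pool$shRNA, pool$replicate, sep = "\r")
          else pool$shRNA
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    warning("shRNAs missing from the pool were excluded")
    rest <- rest[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  data.frame(shRNA = rest$shRNA, gene = rest$gene,
             condition = rest$condition, replicate = rest$replicate,
             ratio = rest$rpm / pool$rpm[idx], stringsAsFactors = FALSE)
}

#' Gene-level depletion: geometric mean of shRNA ratios
#'
#' Aggregates per-shRNA depletion ratios to one value per gene and
#' condition. The default pools all (shRNA x replicate) ratios of a gene
#' into a single geometric mean, which is order-invariant; `"nested"` first
#' takes the geometric mean per shRNA across replicates, then across
#' shRNAs.
#'
#' @param ratios output of [shrna_depletion()].
#' @param method `"pooled"` (default) or `"nested"`.
#' @return data frame: `gene`, `condition`, `depletion`, `n_shrnas`.
#' @export
gene_depletion <- function(ratios, method = c("pooled", "nested")) {
  method <- match.arg(method)
  if (any(ratios$ratio <= 0)) stop("nonpositive depletion ratio")
  dt <- data.table::as.data.table(ratios)
  if (method == "pooled") {
    out <- dt[, .(depletion = exp(mean(log(ratio))),
                  n_shrnas = data.table::uniqueN(shRNA)),
              by = .(gene, condition)]
  } else {
    per <- dt[, .(g = exp(mean(log(ratio)))),
              by = .(gene, condition, shRNA)]
    out <- per[, .(depletion = exp(mean(log(g))), n_shrnas = .N),
               by = .(gene, condition)]
  }
  as.data.frame(out[order(gene, condition)])
}

#' Differential depletion: cisplatin vs vehicle
#'
#' For each gene, `D = depletion_cpt / depletion_vehicle`; genes are ranked
#' ascending in `D` (rank 1 = most cisplatin-specifically depleted).
#' Optional permutation p-values shuffle the shRNA-to-gene assignment
#' (keeping gene sizes) and compare each gene's observed `D` against its
#' permutation distribution, one-sided for depletion:
#' `p = (1 + #{D_perm <= D_obs}) / (n_perm + 1)`. Hits are genes with
#' `D <= hit_threshold` supported by at least `min_shrnas` shRNAs.
#'
#' @param ratios output of [shrna_depletion()] (both day-14 conditions).
#' @param cpt,vehicle condition names (defaults `"cpt_d14"`,
#'   `"vehicle_d14"`).
#' @param n_perm number of label permutations for empirical p-values
#'   (default 1000; 0 skips them).
#' @param seed RNG seed for the permutations.
#' @param hit_threshold maximal differential depletion for a hit call
#'   (default 0.5; the significance rule is a reconstruction and fully
#'   exposed).
#' @param min_shrnas minimal supporting shRNAs for a hit (default 2).
#' @return a `depletion_result` data frame sorted by rank: `gene`,
#'   `depletion_cpt`, `depletion_vehicle`, `D`, `rank`, `n_shrnas`,
#'   `is_hit`, and `p`/`fdr` when permutations were run. The per-shRNA
#'   ratio table is attached as attribute `shrna_ratios`.
#' @export
differential_depletion <- function(ratios, cpt = "cpt_d14",
                                   vehicle = "vehicle_d14", n_perm = 1000,
                                   seed = 1, hit_threshold = 0.5,
                                   min_shrnas = 2) {
  gd <- gene_depletion(ratios)
  dc <- gd[gd$condition == cpt, , drop = FALSE]
  dv <- gd[gd$condition == vehicle, , drop = FALSE]
  common <- intersect(dc$gene, dv$gene)
  dropped <- setdiff(union(dc$gene, dv$gene), common)
  if (length(dropped))
    message(length(dropped), " gene(s) absent from one condition excluded")
  dc <- dc[match(common, dc$gene), ]
  dv <- dv[match(common, dv$gene), ]
  out <- data.frame(gene = common, depletion_cpt = dc$depletion,
                    depletion_vehicle = dv$depletion,
                    D = dc$depletion / dv$depletion,
                    n_shrnas = dc$n_shrnas, stringsAsFactors = FALSE)
  if (n_perm > 0) {
    # per-shRNA log differential (cpt minus vehicle, averaged over reps);
    # D(g) = exp(mean over the gene's shRNAs)
    dt <- data.table::as.data.table(ratios)
    per <- dt[, .(lr = mean(log(ratio[condition == cpt])) -
                    mean(log(ratio[condition == vehicle]))),
              by = .(shRNA, gene)]
    per <- per[gene %in% common]
    set.seed(seed)
    obs <- tapply(per$lr, per$gene, mean)[out$gene]
    hits_le <- numeric(nrow(out))
    glab <- per$gene
    for (b in seq_len(n_perm)) {
      perm <- sample(per$lr)
      Dp <- tapply(perm, glab, mean)[out$gene]
      hits_le <- hits_le + (Dp <= obs)
    }
    out$p <- (1 + hits_le) / (n_perm + 1)
    out$fdr <- stats::p.adjust(out$p, method = "BH")
  }
  out$rank <- rank(out$D, ties.method = "first")
  out$is_hit <- out$D <= hit_threshold & out$n_shrnas >= min_shrnas
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("depletion_result", "data.frame"),
            shrna_ratios = ratios, n_perm = n_perm)
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf("depletion_result: %d genes, %d hit(s)\n",
              nrow(x), sum(x$is_hit)))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Run the full screen analysis from a count table
#'
#' Convenience wrapper: rpm normalization, per-shRNA day14/pool ratios,
#' geometric-mean gene aggregation and differential depletion ranking.
#'
#' @param counts a `screen_counts` table (see [read_count_table()]).
#' @param pseudocount passed to [normalize_counts()].
#' @param ... passed to [differential_depletion()].
#' @return a `depletion_result`.
#' @export
run_screen <- function(counts, pseudocount = 1, ...) {
  differential_depletion(
    shrna_depletion(normalize_counts(counts, pseudocount = pseudocount)),
    ...)
}
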