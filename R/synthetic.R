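#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. Defaults
#' reproduce the study conditions the analysis is designed for: two-condition
#' H3K27ac signal with planted common/up/down region classes (fold changes
#' 2.0 and 0.5 against a base peak intensity of 2000 arbitrary coverage
#' units, multiplicative lognormal noise with CV 0.15, 10 kb windows at
#' 100 bp bins), a chromatin-focused dropout screen of 1139 genes covered by
#' 6485 shRNAs with 4 planted cisplatin-specific dropouts at effect 0.2 over
#' 3 replicates, variant calls at 0.5/kb background vs 1.5/kb inside
#' up-regions of the resistant condition, and an 18-cell-line expression
#' panel split 11 resistant / 7 sensitive at a 20 uM GI50 threshold.
#'
#' @param seed integer root seed; every generator derives its stream from it.
#' @param n_common,n_up,n_down planted region counts per class.
#' @param fc_up,fc_down planted fold changes (condition 2 / condition 1).
#' @param base_intensity mean in-peak coverage, arbitrary units.
#' @param noise_cv lognormal coefficient of variation of per-bin signal.
#' @param window_bp,bin_bp signal-matrix window and bin size (bp).
#' @param min_peak_bp,max_peak_bp planted peak width range (bp); the default
#'   1-6 kb range deliberately straddles the 2 kb differential-filter cutoff.
#' @param stitch_bp reference stitching distance used to space planted peaks.
#' @param close_fraction fraction of peaks placed within stitching distance
#'   of their neighbour (exercises super-enhancer stitching); default 0.
#' @param tss_max_offset_bp TSS of each planted region's gene is placed
#'   within this absolute distance of the region midpoint.
#' @param n_genes,n_shrnas,n_depleted,depletion_effect,n_replicates screen
#'   parameters: library size in genes and total guides, number of planted
#'   cisplatin-synergistic genes, their count-depletion multiplier, and
#'   replicates.
#' @param shrnas_per_gene optional fixed number of guides per gene; when
#'   `NULL` (default) `n_shrnas` guides are spread as evenly as possible.
#' @param screen_base_count mean pool representation per shRNA (reads).
#' @param screen_dispersion negative-binomial dispersion of counts.
#' @param screen_drift_cv lognormal CV of per-shRNA passage drift between
#'   pool and day 14.
#' @param pool_per_replicate if `TRUE` (default) each replicate has its own
#'   sequenced pool; otherwise a single shared pool is emitted.
#' @param snp_rate_bg,snp_rate_up variants per kb: genome-wide background,
#'   and inside up-class regions of condition 2.
#' @param n_cell_lines,n_resistant expression-panel size and number of
#'   resistant lines (GI50 above threshold).
#' @param gi50_threshold_uM GI50 split point in micromolar.
#' @param expr_shift planted log2 expression shift of signature genes in
#'   resistant lines.
#' @param n_expr_genes,signature_n expression-panel gene count and size of
#'   each signature half (up and down).
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_common = 200L, n_up = 50L, n_down = 50L,
                       fc_up = 2.0, fc_down = 0.5,
                       base_intensity = 2000, noise_cv = 0.15,
                       window_bp = 10000L, bin_bp = 100L,
                       min_peak_bp = 1000L, max_peak_bp = 6000L,
                       stitch_bp = 12500L, close_fraction = 0,
                       tss_max_offset_bp = 10000L,
                       n_genes = 1139L, n_shrnas = 6485L,
                       shrnas_per_gene = NULL,
                       n_depleted = 4L, depletion_effect = 0.2,
                       n_replicates = 3L,
                       screen_base_count = 500, screen_dispersion = 0.1,
                       screen_drift_cv = 0.1, pool_per_replicate = TRUE,
                       snp_rate_bg = 0.5, snp_rate_up = 1.5,
                       n_cell_lines = 18L, n_resistant = 11L,
                       gi50_threshold_uM = 20,
                       expr_shift = 1, n_expr_genes = 500L,
                       signature_n = 50L) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_common, cfg$n_up, cfg$n_down, cfg$n_genes, cfg$n_shrnas,
              cfg$n_depleted, cfg$n_replicates, cfg$n_cell_lines,
              cfg$n_expr_genes)
  if (any(counts < 0)) stop("config error: counts must be >= 0")
  if (!(cfg$fc_up > 1 && cfg$fc_down < 1 && cfg$fc_down > 0))
    stop("config error: need fc_up > 1 > fc_down > 0")
  if (cfg$noise_cv < 0) stop("config error: noise_cv must be >= 0")
  if (cfg$window_bp < cfg$bin_bp)
    stop("config error: window smaller than bin")
  if (cfg$window_bp %% cfg$bin_bp != 0)
    stop("config error: window must be a multiple of bin size")
  if (cfg$n_depleted > cfg$n_genes)
    stop("config error: n_depleted > n_genes")
  if (cfg$n_resistant > cfg$n_cell_lines)
    stop("config error: n_resistant > n_cell_lines")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d+%d+%d regions (fc %.2g/%.2g, cv %.2g),", x$n_common,
              x$n_up, x$n_down, x$fc_up, x$fc_down, x$noise_cv),
      sprintf("screen %d genes/%d shRNAs,", x$n_genes, x$n_shrnas),
      sprintf("panel %d lines (%d resistant), seed %d\n", x$n_cell_lines,
              x$n_resistant, x$seed))
  invisible(x)
}

# lognormal multiplicative noise with mean 1 and coefficient of variation cv
.lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

# sample from the elements of x even when length(x) == 1
.sample_from <- function(x, n, replace = TRUE) {
  x[sample.int(length(x), n, replace = replace)]
}

# derive an independent stream per generator from the root seed so results
# do not depend on generator call order
.seed_for <- function(cfg, offset) {
  set.seed((as.integer(cfg$seed) %% 1000000L) * 100L + offset)
}

#' Simulate two-condition ChIP-seq signal with planted region classes
#'
#' Lays planted peaks on one synthetic chromosome (`chrS`) with gaps of at
#' least twice the stitching distance (except an optional close-packed
#' fraction), assigns each peak a class (common / up / down), and emits
#' binned coverage for two conditions: condition 1 peaks at
#' `base_intensity`, condition 2 multiplied by the class fold change, both
#' under multiplicative lognormal per-bin noise. Background between peaks
#' sits at 5% of base intensity. A TSS annotation places one gene per
#' planted region at a known offset from its midpoint, so nearest-TSS
#' distances have planted truth.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, writes
#'   `cond1.bedGraph`, `cond2.bedGraph`, `peaks.bed`, `tss.tsv` and
#'   `truth.json`.
#' @return list with `tracks` (named list of `coverage_track`), `peaks`
#'   (a [region_set()] with class in `name`-indexed truth), `tss`
#'   (a `tss_annotation`), `truth` (data frame: name, class, offsets),
#'   `chrom_len`, and `paths` when `dir` was given.
#' @export
simulate_chip <- function(cfg, dir = NULL) {
  .seed_for(cfg, 1L)
  n <- cfg$n_common + cfg$n_up + cfg$n_down
  bin <- cfg$bin_bp
  classes <- sample(c(rep("common", cfg$n_common), rep("up", cfg$n_up),
                      rep("down", cfg$n_down)))
  widths <- .sample_from(seq(cfg$min_peak_bp, cfg$max_peak_bp, by = bin), n)
  far_gap <- 2L * cfg$stitch_bp
  gaps <- rep(far_gap, n)
  if (cfg$close_fraction > 0 && n > 1) {
    nn <- floor(cfg$close_fraction * n)
    close_idx <- sample(2:n, min(nn, n - 1))
    gaps[close_idx] <- .sample_from(seq(bin * 10, cfg$stitch_bp, by = bin),
                                    length(close_idx))
  }
  gaps[1] <- cfg$window_bp  # left margin
  starts <- cumsum(gaps) + c(0, cumsum(widths))[seq_len(n)]
  ends <- starts + widths
  chrom_len <- ends[n] + far_gap
  names <- sprintf("region_%04d", seq_len(n))
  peaks <- region_set(rep("chrS", n), starts, ends, name = names,
                      label = "planted")

  fc <- c(common = 1, up = cfg$fc_up, down = cfg$fc_down)[classes]
  nbins <- chrom_len %/% bin
  bin_start <- (seq_len(nbins) - 1L) * bin
  # per-bin class multiplier: background bins get 0.05x, peak bins 1x * fc
  mu1 <- rep(cfg$base_intensity * 0.05, nbins)
  mu2 <- mu1
  for (i in seq_len(n)) {
    b <- (starts[i] %/% bin + 1L):(ends[i] %/% bin)
    mu1[b] <- cfg$base_intensity
    mu2[b] <- cfg$base_intensity * fc[i]
  }
  v1 <- mu1 * .lnoise(nbins, cfg$noise_cv)
  v2 <- mu2 * .lnoise(nbins, cfg$noise_cv)
  tr <- function(v) coverage_track(list(chrS = data.frame(
    start = bin_start, end = bin_start + bin, value = round(v, 4))))
  tracks <- list(cond1 = tr(v1), cond2 = tr(v2))

  offs <- .sample_from(seq(-cfg$tss_max_offset_bp, cfg$tss_max_offset_bp,
                           by = bin), n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  mid <- region_midpoint(peaks)
  tss <- tss_annotation(gene = sprintf("GENE%04d", seq_len(n)),
                        chrom = "chrS",
                        tss = pmax(1, mid + offs + 1L), strand = strand)
  truth <- data.frame(name = names, class = classes, start = starts,
                      end = ends, width = widths, gene = tss$gene,
                      tss_offset = offs, strand = strand,
                      stringsAsFactors = FALSE)
  out <- list(tracks = tracks, peaks = peaks, tss = tss, truth = truth,
              chrom_len = chrom_len, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(cond1 = file.path(dir, "cond1.bedGraph"),
              cond2 = file.path(dir, "cond2.bedGraph"),
              peaks = file.path(dir, "peaks.bed"),
              tss = file.path(dir, "tss.tsv"),
              truth = file.path(dir, "truth_chip.json"))
    write_bedgraph(tracks$cond1, p$cond1)
    write_bedgraph(tracks$cond2, p$cond2)
    write_bed(peaks, p$peaks)
    .write_tsv(as.data.frame(tss), p$tss)
    jsonlite::write_json(truth, p$truth, digits = NA)
    out$paths <- p
  }
  out
}

#' Simulate variant calls with planted enrichment in up-regions
#'
#' Condition 1 receives homogeneous Poisson variants at `snp_rate_bg` per kb
#' along the whole synthetic chromosome. Condition 2 receives the same
#' background outside up-class regions, but `snp_rate_up` per kb inside
#' them, emulating SNP accumulation at gained enhancers of the resistant
#' line.
#'
#' @param cfg a [sim_config()].
#' @param chip output of [simulate_chip()] (provides region truth and
#'   chromosome length).
#' @param dir optional output directory (writes `cond1.vcf`, `cond2.vcf`).
#' @return list of two `variant_set`s (`cond1`, `cond2`), plus `paths` when
#'   written.
#' @export
simulate_variants <- function(cfg, chip, dir = NULL) {
  .seed_for(cfg, 2L)
  L <- chip$chrom_len
  draw_bg <- function(rate) {
    k <- stats::rpois(1, rate * L / 1000)
    sort(sample.int(L, k, replace = TRUE))
  }
  pos1 <- draw_bg(cfg$snp_rate_bg)
  pos2 <- draw_bg(cfg$snp_rate_bg)
  up <- chip$truth[chip$truth$class == "up", , drop = FALSE]
  if (nrow(up) > 0) {
    # 1-based position p lies in [start, end) iff start < p <= end
    inside <- function(p) {
      g <- .pos_as_granges(rep("chrS", length(p)), p)
      r <- .rs_as_granges(region_set(rep("chrS", nrow(up)), up$start, up$end))
      IRanges::overlapsAny(g, r)
    }
    pos2 <- pos2[!inside(pos2)]
    extra <- unlist(lapply(seq_len(nrow(up)), function(i) {
      w <- up$end[i] - up$start[i]
      k <- stats::rpois(1, cfg$snp_rate_up * w / 1000)
      if (k == 0) return(integer())
      up$start[i] + sample.int(w, k, replace = TRUE)
    }))
    pos2 <- sort(c(pos2, extra))
  }
  out <- list(cond1 = variant_set(rep("chrS", length(pos1)), pos1, "cond1"),
              cond2 = variant_set(rep("chrS", length(pos2)), pos2, "cond2"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(cond1 = file.path(dir, "cond1.vcf"),
              cond2 = file.path(dir, "cond2.vcf"))
    write_vcf(out$cond1, p$cond1)
    write_vcf(out$cond2, p$cond2)
    out$paths <- p
  }
  out
}

#' Simulate a pooled shRNA dropout screen
#'
#' Emulates a chromatin-focused library screened in a sensitive line under
#' vehicle vs cisplatin: guide representation in the sequenced pool follows
#' a negative binomial around a common mean; day-14 counts drift per guide
#' (lognormal passage effect shared between arms); guides of planted
#' synergistic genes are additionally multiplied by `depletion_effect` in
#' the cisplatin arm only.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory (writes `screen_counts.tsv`,
#'   `truth_screen.json`).
#' @return list with `counts` (a `screen_counts` table with conditions
#'   `pool`, `vehicle_d14`, `cpt_d14`), `depleted_genes`, and `paths` when
#'   written.
#' @export
simulate_screen <- function(cfg, dir = NULL) {
  .seed_for(cfg, 3L)
  genes <- sprintf("SG%04d", seq_len(cfg$n_genes))
  per_gene <- if (!is.null(cfg$shrnas_per_gene)) {
    rep(as.integer(cfg$shrnas_per_gene), cfg$n_genes)
  } else {
    base <- cfg$n_shrnas %/% cfg$n_genes
    extra <- cfg$n_shrnas %% cfg$n_genes
    k <- rep(base, cfg$n_genes)
    if (extra > 0) k[sample.int(cfg$n_genes, extra)] <- base + 1L
    k
  }
  gene_of <- rep(genes, per_gene)
  ns <- length(gene_of)
  shrnas <- sprintf("sh%05d", seq_len(ns))
  depleted <- .sample_from(genes, cfg$n_depleted, replace = FALSE)
  eff <- ifelse(gene_of %in% depleted, cfg$depletion_effect, 1)

  size <- 1 / cfg$screen_dispersion
  mu_pool <- cfg$screen_base_count
  drift <- .lnoise(ns, cfg$screen_drift_cv)
  nb <- function(mu) stats::rnbinom(ns, size = size, mu = mu)
  rows <- list()
  pool_reps <- if (cfg$pool_per_replicate) seq_len(cfg$n_replicates) else 1L
  for (r in pool_reps)
    rows[[length(rows) + 1L]] <- data.frame(
      shRNA = shrnas, gene = gene_of, condition = "pool", replicate = r,
      count = nb(mu_pool), stringsAsFactors = FALSE)
  for (r in seq_len(cfg$n_replicates)) {
    rows[[length(rows) + 1L]] <- data.frame(
      shRNA = shrnas, gene = gene_of, condition = "vehicle_d14",
      replicate = r, count = nb(mu_pool * drift), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      shRNA = shrnas, gene = gene_of, condition = "cpt_d14",
      replicate = r, count = nb(mu_pool * drift * eff),
      stringsAsFactors = FALSE)
  }
  counts <- screen_counts(do.call(rbind, rows), fill_missing = TRUE)
  out <- list(counts = counts, depleted_genes = sort(depleted), config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(counts = file.path(dir, "screen_counts.tsv"),
              truth = file.path(dir, "truth_screen.json"))
    .write_tsv(as.data.frame(counts), p$counts)
    jsonlite::write_json(list(depleted_genes = sort(depleted)), p$truth)
    out$paths <- p
  }
  out
}

#' Simulate an expression panel with a planted resistance signature
#'
#' Generates a log2 expression matrix over a panel of cell lines with
#' planted resistant / sensitive status: resistant lines have signature-up
#' genes shifted by `+expr_shift` log2 units and signature-down genes by
#' `-expr_shift`. GI50 values are drawn so that thresholding at
#' `gi50_threshold_uM` reproduces the planted status exactly (resistant
#' uniform on 25-60 uM, sensitive on 2-15 uM).
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory (writes `expression.tsv`,
#'   `gi50.tsv`, `truth_expression.json`).
#' @return list with `expr` (matrix genes x lines, log2 units), `gi50`
#'   (named vector, uM), `sig_up`, `sig_down`, `resistant` (line names),
#'   and `paths` when written.
#' @export
simulate_expression <- function(cfg, dir = NULL) {
  .seed_for(cfg, 4L)
  genes <- sprintf("EG%04d", seq_len(cfg$n_expr_genes))
  lines <- sprintf("line_%02d", seq_len(cfg$n_cell_lines))
  resistant <- .sample_from(lines, cfg$n_resistant, replace = FALSE)
  sig <- sample(genes, 2L * cfg$signature_n)
  sig_up <- sig[seq_len(cfg$signature_n)]
  sig_down <- sig[cfg$signature_n + seq_len(cfg$signature_n)]
  base <- stats::rnorm(cfg$n_expr_genes, mean = 8, sd = 1)
  m <- matrix(stats::rnorm(cfg$n_expr_genes * cfg$n_cell_lines,
                           mean = 0, sd = 0.5),
              nrow = cfg$n_expr_genes,
              dimnames = list(genes, lines)) + base
  is_res <- lines %in% resistant
  m[sig_up, is_res] <- m[sig_up, is_res] + cfg$expr_shift
  m[sig_down, is_res] <- m[sig_down, is_res] - cfg$expr_shift
  gi50 <- stats::setNames(ifelse(is_res, stats::runif(length(lines), 25, 60),
                                 stats::runif(length(lines), 2, 15)), lines)
  out <- list(expr = m, gi50 = gi50, sig_up = sig_up, sig_down = sig_down,
              resistant = sort(resistant), config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(expr = file.path(dir, "expression.tsv"),
              gi50 = file.path(dir, "gi50.tsv"),
              truth = file.path(dir, "truth_expression.json"))
    .write_tsv(data.frame(gene = rownames(m), m, check.names = FALSE), p$expr)
    .write_tsv(data.frame(sample = names(gi50), gi50_uM = unname(gi50)),
               p$gi50)
    jsonlite::write_json(list(sig_up = sig_up, sig_down = sig_down,
                              resistant = sort(resistant)), p$truth)
    out$paths <- p
  }
  out
}
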