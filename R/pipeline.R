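utils::globalVariables(c("count", "pc", "lib", "condition", "replicate",
                         "rpm", "shRNA", "gene", "ratio", "g", ".", ".N"))

.datatable.aware <- TRUE

# stage dependency graph of the analysis
.stage_deps <- list(
  simulate = character(),
  signal = "simulate",
  differential = "signal",
  superenhancer = "differential",
  snp = "differential",
  genes = "differential",
  screen = "simulate",
  inverse = "differential"
)

#' Default pipeline configuration
#'
#' All thresholds of the analysis in one declarative list: differential
#' filter (width 2000 bp, intensity 1000, fold change 1.3 / 0.75),
#' super-enhancer stitching (12500 bp), GI50 split (20 uM), signal window
#' (10 kb / 100 bp bins), K-means K (3), plus the root seed, output
#' directory, enabled stages and the simulation parameters.
#'
#' @param ... overrides of the default fields.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = tempfile("enhancerdiff_run_"),
    stages = c("simulate", "signal", "differential", "superenhancer",
               "snp", "genes", "screen"),
    width_min = 2000, intensity_min = 1000, fc_up = 1.3, fc_down = 0.75,
    stitch_bp = 12500, gi50_threshold_uM = 20,
    window_bp = 10000, bin_bp = 100, K = 3,
    sim = list()
  )
  over <- list(...)
  cfg[names(over)] <- over
  if (cfg$fc_down >= 1 || cfg$fc_up <= 1)
    stop("config error: need fc_down < 1 < fc_up")
  if (any(c(cfg$width_min, cfg$intensity_min, cfg$stitch_bp, cfg$window_bp,
            cfg$bin_bp) <= 0))
    stop("config error: thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path a YAML file whose keys are [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.check_stage_deps <- function(stages) {
  for (s in stages) {
    if (!s %in% names(.stage_deps)) stop("unknown stage: ", s)
    missing <- setdiff(.stage_deps[[s]], stages)
    if (length(missing))
      stop(sprintf("config error: stage '%s' requires disabled stage '%s'",
                   s, missing[1]))
  }
  intersect(names(.stage_deps), stages)  # dependency order
}

#' Run the analysis pipeline from a single configuration
#'
#' Executes the enabled stages in dependency order over synthetic inputs
#' generated from the config seed: signal extraction and quantile
#' normalization, differential clustering + threshold filtering with
#' nearest-TSS annotation, super-enhancer calling, variant-density
#' comparison, gene-level scoring, and the shRNA-screen depletion ranking.
#' Identical config and seed give byte-identical outputs; the returned
#' manifest records per-stage output files with MD5 checksums.
#'
#' @param config a `pipeline_config` (or YAML path).
#' @param dry_run if `TRUE`, validates the configuration and stage
#'   dependencies without touching inputs or producing outputs.
#' @return a `pipeline_manifest` list: `seed`, `parameters`, `stages`
#'   (per stage: output paths and MD5 checksums), written also to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = pipeline_config(), dry_run = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stages <- .check_stage_deps(config$stages)
  if (dry_run)
    return(structure(list(seed = config$seed, stages = stages,
                          dry_run = TRUE), class = "pipeline_manifest"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- do.call(sim_config, c(list(seed = config$seed,
                                     window_bp = config$window_bp,
                                     bin_bp = config$bin_bp,
                                     stitch_bp = config$stitch_bp,
                                     gi50_threshold_uM =
                                       config$gi50_threshold_uM),
                                config$sim))
  manifest <- list(seed = config$seed,
                   parameters = unclass(config)[setdiff(names(config),
                                                        "out_dir")],
                   stages = list())
  note <- function(stage, paths) {
    paths <- unlist(paths, use.names = FALSE)
    manifest$stages[[stage]] <<- list(
      outputs = basename(paths),
      md5 = unname(tools::md5sum(paths)))
  }
  env <- new.env(parent = emptyenv())

  if ("simulate" %in% stages) {
    env$chip <- simulate_chip(scfg, dir = out_dir)
    env$vars <- simulate_variants(scfg, env$chip, dir = out_dir)
    env$expr <- simulate_expression(scfg, dir = out_dir)
    note("simulate", c(env$chip$paths, env$vars$paths, env$expr$paths))
  }
  if ("signal" %in% stages) {
    smat <- extract_signal_matrix(env$chip$tracks, env$chip$peaks,
                                  config$window_bp, config$bin_bp)
    env$smat <- quantile_normalize(smat)
    p <- file.path(out_dir, "signal_matrix.tsv")
    write_signal_matrix(env$smat, p)
    note("signal", p)
  }
  if ("differential" %in% stages) {
    env$stats <- region_stats(env$smat, "cond1", "cond2")
    env$clu <- cluster_regions(env$smat, "cond1", "cond2", K = config$K,
                               seed = config$seed)
    env$diff <- filter_differential_peaks(
      env$stats, width_min = config$width_min,
      intensity_min = config$intensity_min,
      fc_up = config$fc_up, fc_down = config$fc_down)
    env$tss_ann <- annotate_nearest_tss(env$chip$peaks, env$chip$tss)
    p <- c(up = file.path(out_dir, "diff_up.bed"),
           down = file.path(out_dir, "diff_down.bed"),
           stats = file.path(out_dir, "region_stats.tsv"),
           clusters = file.path(out_dir, "clusters.tsv"),
           tss = file.path(out_dir, "nearest_tss.tsv"))
    write_bed(env$diff$up, p["up"])
    write_bed(env$diff$down, p["down"])
    .write_tsv(env$diff$stats, p["stats"])
    .write_tsv(as.data.frame(env$clu), p["clusters"])
    .write_tsv(env$tss_ann, p["tss"])
    note("differential", p)
  }
  if ("superenhancer" %in% stages) {
    pk <- peak_signal(env$chip$tracks$cond1, env$chip$peaks)
    se <- call_superenhancers(stitch_peaks(pk, stitch_bp = config$stitch_bp))
    p <- write_se_call(se, file.path(out_dir, "se"))
    note("superenhancer", p)
  }
  if ("snp" %in% stages) {
    counts <- rbind(
      count_variants_per_region(env$vars$cond1, env$chip$peaks, "cond1"),
      count_variants_per_region(env$vars$cond2, env$chip$peaks, "cond2"))
    cls <- env$chip$truth$class[match(counts$name, env$chip$truth$name)]
    counts$class <- cls
    cmp <- compare_density(
      counts[counts$condition == "cond2" & cls == "up", ],
      counts[counts$condition == "cond1" & cls == "up", ])
    p <- file.path(out_dir, "snp_density.tsv")
    .write_tsv(counts, p)
    env$snp_cmp <- cmp
    note("snp", p)
  }
  if ("genes" %in% stages) {
    sig <- rowMeans(region_body_means(env$smat))
    cum <- cumulative_signal_per_gene(env$tss_ann$gene, sig,
                                      genes = env$chip$tss$gene)
    ri <- resistance_index(env$expr$expr, env$expr$sig_up,
                           env$expr$sig_down, env$expr$gi50,
                           threshold_uM = config$gi50_threshold_uM)
    p <- c(cum = file.path(out_dir, "cumulative_signal.tsv"),
           ri = file.path(out_dir, "resistance_index.tsv"))
    .write_tsv(data.frame(gene = names(cum), cumulative_signal = cum),
               p["cum"])
    .write_tsv(data.frame(sample = names(ri$index), index = ri$index,
                          group = as.character(ri$group)), p["ri"])
    env$ri <- ri
    note("genes", p)
  }
  if ("screen" %in% stages) {
    scr <- simulate_screen(scfg, dir = out_dir)
    res <- run_screen(scr$counts, n_perm = 0, seed = config$seed)
    p <- file.path(out_dir, "screen_depletion.tsv")
    .write_tsv(as.data.frame(res), p)
    env$screen <- res
    note("screen", c(scr$paths, p))
  }
  manifest$results <- list(
    snp_p = if (!is.null(env$snp_cmp)) env$snp_cmp$p,
    resistance_index_p = if (!is.null(env$ri)) env$ri$p)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(c(manifest, list(out_dir = out_dir, env = env)),
            class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  if (isTRUE(x$dry_run)) {
    cat("pipeline_manifest (dry run): stages",
        paste(x$stages, collapse = " -> "), "\n")
    return(invisible(x))
  }
  cat(sprintf("pipeline_manifest: seed %d, %d stage(s) -> %s\n",
              x$seed, length(x$stages), x$out_dir))
  for (s in names(x$stages))
    cat(sprintf("  %-14s %d file(s)\n", s, length(x$stages[[s]]$outputs)))
  invisible(x)
}
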