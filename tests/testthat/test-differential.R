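make_smat <- function(cfg) {
  chip <- simulate_chip(cfg)
  smat <- quantile_normalize(extract_signal_matrix(chip$tracks, chip$peaks,
                                                   cfg$window_bp,
                                                   cfg$bin_bp))
  list(chip = chip, smat = smat)
}

test_that("noiseless equal-signal regions all cluster as common", {
  cfg <- tiny_sim_config(seed = 6, noise_cv = 0, n_up = 0, n_down = 0)
  x <- make_smat(cfg)
  cl <- cluster_regions(x$smat, "cond1", "cond2", K = 3, seed = 1)
  expect_true(all(cl$label == "common"))
})

test_that("clustering is deterministic given the seed", {
  cfg <- tiny_sim_config(seed = 10)
  x <- make_smat(cfg)
  c1 <- cluster_regions(x$smat, "cond1", "cond2", K = 3, seed = 4)
  c2 <- cluster_regions(x$smat, "cond1", "cond2", K = 3, seed = 4)
  expect_identical(c1$cluster, c2$cluster)
  expect_error(cluster_regions(x$smat, "cond1", "cond2", K = 1000, seed = 1),
               "K exceeds")
})

test_that("planted classes are recovered by clustering on a small panel", {
  skip_if_not_installed("mclust")
  cfg <- tiny_sim_config(seed = 19)
  x <- make_smat(cfg)
  cl <- cluster_regions(x$smat, "cond1", "cond2", K = 3, seed = 2)
  truth <- x$chip$truth$class[match(cl$name, x$chip$truth$name)]
  ari <- mclust::adjustedRandIndex(cl$label, truth)
  expect_gte(ari, 0.9)
})

test_that("differential filter applies the width/intensity/FC rule", {
  mk <- function(width, m1, m2) data.frame(
    name = "r", chrom = "chr1", start = 0, end = width, width = width,
    mean1 = m1, mean2 = m2, fc = (m2 + 1) / (m1 + 1),
    stringsAsFactors = FALSE)
  up <- filter_differential_peaks(mk(2500, 800, 1200))
  expect_equal(up$up$name, "r")          # FC ~ 1.4994 > 1.3
  narrow <- filter_differential_peaks(mk(1500, 5000, 10000))
  expect_equal(nrow(narrow$up) + nrow(narrow$down), 0)  # fails >2 kb
  down <- filter_differential_peaks(mk(3000, 2000, 1400))
  expect_equal(down$down$name, "r")      # FC ~ 0.700 < 0.75
  mid <- filter_differential_peaks(mk(3000, 1000, 1100))
  expect_equal(mid$stats$call, "none")   # FC within (0.75, 1.3)
})

test_that("filter equals the per-region oracle and is threshold-monotone", {
  stats <- random_region_stats(1000, seed = 77)
  got <- filter_differential_peaks(stats)
  expect_equal(got$stats$call, oracle_filter(stats))
  # monotonicity: raising the FC threshold never grows the up set
  sizes <- vapply(c(1.1, 1.3, 1.6, 2.0), function(t)
    nrow(filter_differential_peaks(stats, fc_up = t)$up), 0L)
  expect_true(all(diff(sizes) <= 0))
  sizes_w <- vapply(c(1000, 2000, 3000), function(w)
    nrow(filter_differential_peaks(stats, width_min = w)$up), 0L)
  expect_true(all(diff(sizes_w) <= 0))
  # intensity mode "mean" is never more permissive than "max"
  got_mean <- filter_differential_peaks(stats, intensity_mode = "mean")
  expect_true(all(got_mean$stats$call == "none" |
                  got_mean$stats$call == got$stats$call))
})

test_that("nearest-TSS annotation gets distances, signs and ties right", {
  tss <- tss_annotation(gene = c("geneA", "geneB", "geneC"),
                        chrom = "chr1",
                        tss = c(4001, 20001, 6001),
                        strand = c("+", "+", "-"))
  # midpoint 5000: geneA at +1000 (downstream of + strand TSS at 4000),
  # geneC at 6000 on minus strand is also 1000 away -> tie, geneA wins
  r <- region_set("chr1", 4000, 6000, name = "m5000")
  ann <- annotate_nearest_tss(r, tss)
  expect_equal(ann$gene, "geneA")
  expect_equal(ann$distance, 1000)

  # minus-strand sign: midpoint 5000 vs TSS 6000 on '-' is downstream
  only_c <- tss_annotation("geneC", "chr1", 6001, "-")
  expect_equal(annotate_nearest_tss(r, only_c)$distance, 1000)

  at_tss <- region_set("chr1", 3000, 5002, name = "z")  # midpoint 4001
  expect_equal(annotate_nearest_tss(at_tss, tss)$distance[1], 1)
  exact <- region_set("chr1", 3000, 5000, name = "z")   # midpoint 4000
  expect_equal(annotate_nearest_tss(exact, tss)$distance[1], 0)

  other <- region_set("chr9", 0, 100, name = "off")
  offann <- annotate_nearest_tss(other, tss)
  expect_true(is.na(offann$distance))
  expect_equal(offann$flag, "no_tss_on_chrom")
})

test_that("nearest-TSS annotation equals brute force on random instances", {
  set.seed(55)
  for (rep in 1:5) {
    regions <- random_region_set(40, seed = rep * 13)
    tss <- tss_annotation(
      gene = sprintf("G%03d", sample(999, 60)),
      chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
      tss = sample.int(1.2e5, 60), strand = sample(c("+", "-"), 60, TRUE))
    got <- annotate_nearest_tss(regions, tss)
    want <- oracle_nearest_tss(regions, tss)
    expect_equal(got$gene, want$gene)
    expect_equal(got$distance, want$distance)
  }
})

test_that("mark correlation hits the closed-form extremes and the formula", {
  cfg <- tiny_sim_config(seed = 25)
  chip <- simulate_chip(cfg)
  A <- extract_signal_matrix(chip$tracks, chip$peaks)
  same <- correlate_marks(A, A)
  expect_equal(same$pearson, 1)
  B <- A; B[] <- -as.vector(A) + 7
  expect_equal(correlate_marks(A, B)$pearson, -1)
  # direct formula evaluation on the per-region means
  a <- rowMeans(region_body_means(A))
  b <- rowMeans(region_body_means(B))
  r_manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlate_marks(A, B)$pearson, r_manual, tolerance = 1e-12)
  few <- extract_signal_matrix(chip$tracks, chip$peaks[1:2, ])
  expect_error(correlate_marks(few, few), "3 regions")
})

test_that("inverse-region identification matches set and oracle semantics", {
  rs <- function(names, starts, ends, fc) region_set(
    rep("chr1", length(starts)), starts, ends, name = names, score = fc)
  upA <- rs(c("r1", "r2"), c(0, 1000), c(100, 1100), c(2, 3))
  downB <- rs(c("r2", "r3"), c(1000, 5000), c(1100, 5100), c(0.5, 0.4))
  res <- find_inverse_regions(list(up = upA, down = rs(character(),
                                                       numeric(), numeric(),
                                                       numeric())),
                              list(up = rs(character(), numeric(),
                                           numeric(), numeric()),
                                   down = downB))
  expect_equal(res$A$name, "r2")
  expect_equal(res$A$fc_a, 3)
  expect_equal(res$A$fc_b, 0.5)
  expect_equal(nrow(res$B), 0)

  # disjoint coordinates everywhere -> empty
  none <- find_inverse_regions(list(up = upA, down = rs("x", 9e6, 9e6 + 10,
                                                        1.5)),
                               list(up = rs("w", 7e6, 7e6 + 10, 2),
                                    down = rs("y", 8e6, 8e6 + 10, 0.5)))
  expect_equal(nrow(none$A) + nrow(none$B), 0)
})

test_that("inverse regions equal an all-pairs overlap scan on random input", {
  a <- random_region_set(100, seed = 3)
  b <- random_region_set(100, seed = 4)
  res <- find_inverse_regions(list(up = a, down = b[0, ]),
                              list(up = a[0, ], down = b))
  want <- oracle_overlap_pairs(a, b)
  got <- data.frame(a = match(res$A$name, a$name),
                    b = match(res$A$match_name, b$name))
  expect_equal(got[order(got$a, got$b), ], want[order(want$a, want$b), ],
               ignore_attr = TRUE)
  # reciprocal-fraction mode only ever removes pairs
  strict <- find_inverse_regions(list(up = a, down = b[0, ]),
                                 list(up = a[0, ], down = b),
                                 min_frac = 0.5)
  expect_lte(nrow(strict$A), nrow(res$A))
})
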