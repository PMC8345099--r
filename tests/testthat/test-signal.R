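test_that("signal matrix bins average per-bp coverage around peak centers", {
  const <- coverage_track(list(chr1 = data.frame(start = 0, end = 1e5,
                                                 value = 3)))
  peaks <- region_set("chr1", 40000, 42000, name = "p1")
  m <- extract_signal_matrix(list(s1 = const), peaks)
  expect_equal(dim(m), c(1, 100, 1))   # 10 kb window at 100 bp bins
  expect_true(all(m == 3))

  # step track: 1 left of the peak center, 5 right of it
  center <- (40000 + 42000) %/% 2
  step <- coverage_track(list(chr1 = data.frame(
    start = c(0, center), end = c(center, 1e5), value = c(1, 5))))
  ms <- extract_signal_matrix(list(s1 = step), peaks)
  expect_equal(as.vector(ms[1, , 1]), rep(c(1, 5), each = 50))
})

test_that("out-of-chromosome bins are zero and empty input is allowed", {
  tr <- coverage_track(list(chr1 = data.frame(start = 0, end = 3000,
                                              value = 2)))
  peaks <- region_set("chr1", 0, 2000, name = "edge")  # window spans < 0
  m <- extract_signal_matrix(list(s1 = tr), peaks)
  expect_equal(as.vector(m[1, 1:40, 1]), rep(0, 40))   # before position 0
  expect_true(all(m[1, 41:70, 1] == 2))
  empty <- extract_signal_matrix(list(s1 = tr),
                                 region_set(character(), numeric(),
                                            numeric()))
  expect_equal(dim(empty)[1], 0)
  expect_error(extract_signal_matrix(list(s1 = tr), peaks, 1000, 300),
               "multiple")
})

test_that("matrix total signal equals the track integral over the window", {
  set.seed(8)
  for (rep in 1:5) {
    nb <- 40
    tr <- coverage_track(list(chr1 = data.frame(
      start = seq(0, by = 250, length.out = nb),
      end = seq(250, by = 250, length.out = nb),
      value = runif(nb, 0, 10))))
    start <- sample(2000:6000, 1)
    peaks <- region_set("chr1", start, start + 1000, name = "p")
    m <- extract_signal_matrix(list(s1 = tr), peaks, window_bp = 2000,
                               bin_bp = 100)
    center <- (2 * start + 1000) %/% 2
    integral <- sum(track_query(tr, "chr1", center - 1000, center + 1000))
    expect_equal(sum(m[1, , 1]) * 100, integral, tolerance = 1e-10)
  }
})

test_that("quantile normalization reproduces the hand-worked 4x3 example", {
  m <- matrix(c(5, 2, 3, 4,
                4, 1, 4, 2,
                3, 4, 6, 8), nrow = 4,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  # sorted-column row means: (2, 3, 4.667, 5.667)
  got <- quantile_normalize(m)
  ref <- c(2, 3, 14 / 3, 17 / 3)
  expect_equal(got[, "s1"], ref[c(4, 1, 2, 3)], ignore_attr = TRUE)
  # sample 2 has tied 4s at ranks 3 and 4 -> both get mean(ref[3:4])
  tie <- mean(ref[3:4])
  expect_equal(got[, "s2"], c(tie, ref[1], tie, ref[2]),
               ignore_attr = TRUE)
  expect_equal(got[, "s3"], ref, ignore_attr = TRUE)
})

test_that("quantile normalization equalizes marginals and is a fixed point", {
  set.seed(12)
  m <- matrix(rnorm(50), 10, 5)
  q <- quantile_normalize(m)
  for (j in 2:5)
    expect_equal(sort(q[, j]), sort(q[, 1]), tolerance = 1e-12)
  expect_equal(quantile_normalize(cbind(m[, 1], m[, 1]))[, 1], m[, 1])
  expect_warning(quantile_normalize(m[, 1, drop = FALSE]), "single sample")
})

test_that("quantile normalization matches the brute-force oracle", {
  set.seed(99)
  for (rep in 1:10) {
    m <- matrix(rnorm(50), 10, 5)
    if (rep %% 2 == 0) m[sample(50, 8)] <- 1  # inject ties
    expect_equal(quantile_normalize(m), oracle_qnorm(m), tolerance = 1e-12)
  }
})

test_that("quantile normalization preserves within-sample rank order", {
  set.seed(7)
  m <- matrix(rexp(60), 12, 5)
  q <- quantile_normalize(m)
  for (j in 1:5)
    expect_equal(order(q[, j]), order(m[, j]))
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(31)
  m <- matrix(rnorm(60), 12, 5)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("3D signal matrices are normalized on the flattened sample vectors", {
  set.seed(14)
  nb <- 200
  mk <- function() coverage_track(list(chr1 = data.frame(
    start = seq(0, by = 100, length.out = nb),
    end = seq(100, by = 100, length.out = nb),
    value = runif(nb, 0, 100))))
  tracks <- list(s1 = mk(), s2 = mk(), s3 = mk())
  peaks <- region_set(rep("chr1", 3), c(4000, 8000, 12000),
                      c(6000, 10000, 14000),
                      name = c("a", "b", "c"))
  smat <- extract_signal_matrix(tracks, peaks, window_bp = 4000)
  q <- quantile_normalize(smat)
  expect_s3_class(q, "signal_matrix")
  for (s in 2:3)
    expect_equal(sort(as.vector(q[, , s])), sort(as.vector(q[, , 1])),
                 tolerance = 1e-12)
  # flattened-path equivalence with the 2D implementation
  flat <- matrix(as.vector(smat), ncol = 3)
  expect_equal(as.vector(q), as.vector(quantile_normalize(flat)),
               tolerance = 1e-12)
})

test_that("spike-in ChIP-qPCR normalization follows the stated formula", {
  ref <- list(target = 50, input = 50, spike_target = 10, spike_input = 10)
  expect_equal(normalize_chip_qpcr(ref, ref), 1)
  rec <- list(target = 100, input = 50, spike_target = 20, spike_input = 10)
  expect_equal(normalize_chip_qpcr(rec, ref), 1)   # (2/2)/(1/1)
  rec2 <- rec; rec2$spike_target <- 40              # doubled spike recovery
  expect_equal(normalize_chip_qpcr(rec2, ref),
               normalize_chip_qpcr(rec, ref) / 2)
  expect_error(normalize_chip_qpcr(list(target = 1, input = 0,
                                        spike_target = 1, spike_input = 1),
                                   ref), "zero")
})

test_that("relative expression is a ratio of ratios anchored at control", {
  expect_equal(relative_expression(4, 2, 4, 2), 1)
  expect_equal(relative_expression(8, 2, 4, 2), 2)
  expect_error(relative_expression(1, 0, 1, 1), "zero")
  # Ct wrapper: one cycle earlier target = 2x expression
  expect_equal(relative_expression_ct(19, 20, 20, 20), 2)
})
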