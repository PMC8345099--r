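# Independent brute-force oracles used across the suite. Each is written
# naively (loops, enumeration) and never shares code with the package
# implementation it checks.

# quantile normalization: per sample, substitute the cross-sample mean of
# sorted values at each rank; tied values share the mean over their block
oracle_qnorm <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    o <- order(x)
    assigned <- numeric(length(x))
    i <- 1
    while (i <= length(x)) {
      k <- i
      while (k < length(x) && x[o[k + 1]] == x[o[i]]) k <- k + 1
      assigned[o[i:k]] <- mean(ref[i:k])
      i <- k + 1
    }
    out[, j] <- assigned
  }
  out
}

# nearest TSS by absolute midpoint distance, ties by gene name; signed
# distance = midpoint - tss, flipped on minus strand
oracle_nearest_tss <- function(regions, tss) {
  mids <- (regions$start + regions$end) %/% 2
  res <- data.frame(gene = character(nrow(regions)),
                    distance = numeric(nrow(regions)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(regions))) {
    cand <- tss[tss$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) { res$gene[i] <- NA; res$distance[i] <- NA; next }
    d <- mids[i] - (cand$tss - 1)
    best <- which(abs(d) == min(abs(d)))
    pick <- best[order(cand$gene[best])][1]
    res$gene[i] <- cand$gene[pick]
    res$distance[i] <- if (cand$strand[pick] == "-") -d[pick] else d[pick]
  }
  res
}

# quadratic variant-in-region counting with the s < p <= e rule
oracle_count_variants <- function(variants, regions) {
  counts <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(variants))) {
      if (variants$chrom[j] == regions$chrom[i] &&
          regions$start[i] < variants$pos[j] &&
          variants$pos[j] <= regions$end[i])
        counts[i] <- counts[i] + 1L
    }
  }
  counts
}

# union-find stitching: peaks are connected if on the same chromosome with
# gap (start2 - end1, for start2 >= end1; 0 if overlapping) <= dist
oracle_stitch <- function(peaks, dist) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || peaks$chrom[i] != peaks$chrom[j]) next
    gap <- max(peaks$start[i], peaks$start[j]) -
           min(peaks$end[i], peaks$end[j])
    if (gap <= dist) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comp <- split(seq_len(n), roots)
  do.call(rbind, lapply(comp, function(idx) data.frame(
    chrom = peaks$chrom[idx[1]],
    start = min(peaks$start[idx]), end = max(peaks$end[idx]),
    n_constituents = length(idx),
    total_signal = sum(ifelse(is.na(peaks$score[idx]), 0,
                              peaks$score[idx])),
    stringsAsFactors = FALSE)))
}

# upper-tail hypergeometric by direct combinatorial enumeration
oracle_hyper_p <- function(k, m, N, n) {
  num <- 0
  for (i in k:min(m, n)) num <- num + choose(m, i) * choose(N - m, n - i)
  num / choose(N, n)
}

# all-pairs interval overlap scan
oracle_overlap_pairs <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i])
      out <- rbind(out, data.frame(a = i, b = j))
  }
  if (is.null(out)) data.frame(a = integer(), b = integer()) else out
}

# differential filter applied one region at a time, straight off the rule
oracle_filter <- function(stats, width_min = 2000, intensity_min = 1000,
                          fc_up = 1.3, fc_down = 0.75) {
  call <- character(nrow(stats))
  for (i in seq_len(nrow(stats))) {
    ok <- stats$width[i] > width_min &&
      max(stats$mean1[i], stats$mean2[i]) > intensity_min
    call[i] <- if (ok && stats$fc[i] > fc_up) "up"
    else if (ok && stats$fc[i] < fc_down) "down" else "none"
  }
  call
}

# small helpers used by several test files ---------------------------------

tiny_sim_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_common = 30, n_up = 10, n_down = 10,
               n_genes = 40, n_shrnas = 200, n_expr_genes = 120,
               signature_n = 15)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

random_region_stats <- function(n, seed) {
  set.seed(seed)
  start <- sample.int(1e6, n)
  width <- sample(500:5000, n, replace = TRUE)
  m1 <- runif(n, 0, 3000)
  m2 <- runif(n, 0, 3000)
  data.frame(name = sprintf("r%04d", seq_len(n)), chrom = "chr1",
             start = start, end = start + width, width = width,
             mean1 = m1, mean2 = m2, fc = (m2 + 1) / (m1 + 1),
             stringsAsFactors = FALSE)
}

random_region_set <- function(n, seed, chroms = c("chr1", "chr2"),
                              max_pos = 1e5, max_width = 3000) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  region_set(sample(chroms, n, replace = TRUE), start,
             start + sample.int(max_width, n, replace = TRUE),
             name = sprintf("p%04d", seq_len(n)),
             score = runif(n, 0, 100))
}
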