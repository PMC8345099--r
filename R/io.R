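#' Read a BED file into a region_set
#'
#' Accepts 3-6 column BED. Coordinates are kept exactly as in the file
#' (0-based half-open). Columns 4 and 5 map to `name` and `score` when
#' present. Lines starting with `track`, `browser` or `#` are skipped.
#'
#' @param path path to a BED file.
#' @param label label to attach to the returned set.
#' @return a [region_set()].
#' @export
read_bed <- function(path, label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) return(region_set(character(), numeric(), numeric(),
                                          label = label))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3))
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated columns",
                 idx[which(ncol < 3)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("malformed BED line %d: non-numeric coordinate",
                 idx[which(is.na(start) | is.na(end))[1]]))
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("validation error at line %d: end <= start", idx[bad[1]]))
  name <- ifelse(ncol >= 4, vapply(fields, function(f)
    if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  score <- suppressWarnings(as.numeric(ifelse(ncol >= 5, vapply(
    fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, ""),
    NA_character_)))
  region_set(chrom, start, end, name = name, score = score, label = label)
}

#' Write a region_set as BED
#'
#' Emits as many columns as are populated: 3 if no names, 4 if names only,
#' 5 with scores. Round-trips byte-identically for canonical 4-column input.
#'
#' @param x a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom,
               format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (any(!is.na(x$name)) || any(!is.na(x$score)))
    cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
  if (any(!is.na(x$score)))
    cols <- c(cols, list(ifelse(is.na(x$score), ".",
                                format(x$score, scientific = FALSE,
                                       trim = TRUE))))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Parses a 4-column bedGraph (chrom, start, end, value; 0-based half-open)
#' into a queryable coverage object. Intervals on one chromosome must not
#' overlap. Negative values (background-subtracted tracks) are allowed with
#' a warning.
#'
#' @param path path to a bedGraph file.
#' @return a `coverage_track`; query it with [track_query()].
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) return(coverage_track(list()))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  if (any(lengths(fields) < 4))
    stop(sprintf("malformed bedGraph line %d: fewer than 4 columns",
                 idx[which(lengths(fields) < 4)[1]]))
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L)),
    value = as.numeric(vapply(fields, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value))
    stop("malformed bedGraph: non-numeric field")
  coverage_track(split(df[c("start", "end", "value")], df$chrom))
}

#' Construct a coverage track from per-chromosome interval tables
#'
#' @param by_chrom named list of data frames with columns `start`, `end`,
#'   `value` (0-based half-open, non-overlapping within a chromosome).
#' @return a `coverage_track` object.
#' @export
coverage_track <- function(by_chrom) {
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("validation error: overlapping bedGraph intervals on one chromosome")
    if (any(d$end <= d$start)) stop("validation error: end <= start in track")
    rownames(d) <- NULL
    d
  })
  if (length(by_chrom) && any(vapply(by_chrom,
                                     function(d) any(d$value < 0), FALSE)))
    warning("track contains negative values (background-subtracted signal?)")
  structure(list(chrom = by_chrom), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track over %d chromosome(s): %s\n",
              length(x$chrom), paste(names(x$chrom), collapse = ", ")))
  invisible(x)
}

#' Query per-bp coverage
#'
#' Returns one value per bp over `[start, end)` (0-based half-open);
#' uncovered positions, including negative coordinates and positions beyond
#' the track, are 0.
#'
#' @param track a `coverage_track`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open query interval.
#' @return numeric vector of length `end - start`.
#' @export
track_query <- function(track, chrom, start, end) {
  if (end <= start) stop("end must be > start")
  n <- end - start
  out <- numeric(n)
  d <- track$chrom[[chrom]]
  if (is.null(d) || nrow(d) == 0) return(out)
  pos <- seq.int(start, end - 1L)
  i <- findInterval(pos, d$start)
  hit <- i >= 1L & pos < d$end[pmax(i, 1L)]
  out[hit] <- d$value[i[hit]]
  out
}

#' Mean coverage over a set of regions
#'
#' Per-region mean of per-bp track values over the region body.
#'
#' @param track a `coverage_track`.
#' @param regions a [region_set()].
#' @return numeric vector, one mean per region.
#' @export
track_region_mean <- function(track, regions) {
  vapply(seq_len(nrow(regions)), function(i)
    mean(track_query(track, regions$chrom[i], regions$start[i],
                     regions$end[i])), 0)
}

#' Write a coverage track as bedGraph
#' @param track a `coverage_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  chunks <- lapply(names(track$chrom), function(ch) {
    d <- track$chrom[[ch]]
    paste(ch, format(d$start, scientific = FALSE, trim = TRUE),
          format(d$end, scientific = FALSE, trim = TRUE),
          format(d$value, scientific = FALSE, trim = TRUE), sep = "\t")
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

#' Read variant positions from a VCF
#'
#' Extracts one (chrom, POS) pair per record whose FILTER field is in
#' `keep_filters`; multi-allelic records count once. Only site positions are
#' used; genotypes are ignored.
#'
#' @param path path to a VCF 4.x file.
#' @param keep_filters FILTER values to retain (default `PASS` and `.`).
#' @param sample label attached to the returned set.
#' @return a `variant_set`: data frame with columns `chrom`, `pos`
#'   (1-based) and a `sample` attribute.
#' @export
read_vcf_positions <- function(path, keep_filters = c("PASS", "."),
                               sample = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  if (!any(grepl("^#CHROM\t", lines)))
    stop("parse error: missing #CHROM header line")
  body <- lines[!hdr & nzchar(lines)]
  if (length(body) == 0) return(variant_set(character(), integer(), sample))
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 7))
    stop("parse error: VCF record with fewer than 7 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  filt <- vapply(fields, `[[`, "", 7L)
  keep <- filt %in% keep_filters
  variant_set(chrom[keep], pos[keep], sample)
}

#' Construct a variant set
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions (`>= 1`).
#' @param sample sample label.
#' @return a `variant_set` data frame.
#' @export
variant_set <- function(chrom, pos, sample = "") {
  if (length(pos) && any(pos < 1)) stop("VCF POS must be >= 1")
  structure(data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                       stringsAsFactors = FALSE),
            class = c("variant_set", "data.frame"), sample = sample)
}

#' Write a minimal VCF of site positions
#' @param variants a `variant_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  o <- order(variants$chrom, variants$pos)
  body <- paste(variants$chrom[o], variants$pos[o], ".", "N", "A", "100",
                "PASS", ".", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a pooled-screen count table
#'
#' Expects a TSV with header columns `shRNA`, `gene`, `condition`,
#' `replicate`, `count`. The (shRNA, condition, replicate) index must be
#' complete and unique; each shRNA must map to exactly one gene.
#'
#' @param path path to the TSV.
#' @param fill_missing if `TRUE`, absent (shRNA, condition, replicate)
#'   cells are filled with count 0 instead of raising an error.
#' @return a `screen_counts` data frame.
#' @export
read_count_table <- function(path, fill_missing = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("shRNA", "gene", "condition", "replicate", "count")
  if (!all(need %in% names(df)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  screen_counts(df[need], fill_missing = fill_missing)
}

#' Validate and index screen counts
#' @param df data frame with columns shRNA, gene, condition, replicate, count.
#' @param fill_missing fill absent index cells with 0 instead of erroring.
#' @return a `screen_counts` data frame.
#' @export
screen_counts <- function(df, fill_missing = FALSE) {
  if (any(df$count < 0))
    stop("validation error: negative count")
  if (any(df$count != floor(df$count)))
    stop("validation error: non-integer count")
  key <- paste(df$shRNA, df$condition, df$replicate, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate key (shRNA, condition, replicate): ",
         gsub("\r", "/", key[which(dup)[1]]))
  g <- unique(df[c("shRNA", "gene")])
  if (anyDuplicated(g$shRNA))
    stop("shRNA mapped to more than one gene: ",
         g$shRNA[which(duplicated(g$shRNA))[1]])
  full <- expand.grid(shRNA = unique(df$shRNA),
                      condition = unique(df$condition),
                      replicate = unique(df$replicate),
                      stringsAsFactors = FALSE)
  if (nrow(full) > nrow(df)) {
    if (!fill_missing)
      stop(sprintf("incomplete index: %d of %d cells present",
                   nrow(df), nrow(full)))
    miss <- !(paste(full$shRNA, full$condition, full$replicate,
                    sep = "\r") %in% key)
    add <- full[miss, , drop = FALSE]
    add$gene <- g$gene[match(add$shRNA, g$shRNA)]
    add$count <- 0L
    df <- rbind(df, add[names(df)])
  }
  df <- df[order(df$condition, df$replicate, df$shRNA), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("screen_counts", "data.frame"))
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, then member genes. Gene symbols
#' are upper-cased on load; empty sets are rejected.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3))
    stop("malformed GMT: a set has no genes")
  sets <- lapply(fields, function(f) toupper(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Read a TSS annotation table
#'
#' TSV with header columns `gene`, `chrom`, `tss` (1-based), `strand`
#' (`+` or `-`). Multiple TSS per gene are allowed.
#'
#' @param path path to the TSV.
#' @return a `tss_annotation` data frame.
#' @export
read_tss <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  tss_annotation(df$gene, df$chrom, df$tss, df$strand)
}

#' Construct a TSS annotation
#' @param gene,chrom,tss,strand parallel vectors; `tss` 1-based, strand
#'   `+`/`-`.
#' @return a `tss_annotation` data frame.
#' @export
tss_annotation <- function(gene, chrom, tss, strand) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(tss < 1)) stop("tss positions are 1-based (>= 1)")
  structure(data.frame(gene = as.character(gene), chrom = as.character(chrom),
                       tss = as.numeric(tss), strand = as.character(strand),
                       stringsAsFactors = FALSE),
            class = c("tss_annotation", "data.frame"))
}

# deterministic TSV writer used by generators and the pipeline
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read an expression matrix (genes x samples TSV)
#' @param path TSV with first column `gene`, remaining columns samples.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- toupper(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a GI50 table
#' @param path TSV with columns `sample` and `gi50_uM`.
#' @return named numeric vector of GI50 values (micromolar).
#' @export
read_gi50 <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "gi50_uM") %in% names(df)))
    stop("GI50 table must have columns sample, gi50_uM")
  stats::setNames(df$gi50_uM, df$sample)
}
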