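#' Read a BED-family interval file
#'
#' Parses BED3, BED6, ENCODE narrowPeak (10 columns) or ChromHMM-style
#' dense-segmentation BED into a `GRanges`. File coordinates are 0-based
#' half-open (the BED convention); the returned `GRanges` uses the usual
#' 1-based closed convention, and [write_bed()] converts back, so round trips
#' are bit-exact. The dialect is always explicit: 1-based formats are never
#' auto-detected.
#'
#' narrowPeak columns 7-10 are signalValue, pValue (-log10), qValue (-log10)
#' and the summit offset from the peak start. The returned `GRanges` carries
#' `name`, `score`, `pvalue` (back-transformed to a linear p-value) and
#' `summit` (absolute 1-based position, or `NA` when the offset is -1).
#' Segmentation files carry the state label (column 4) in `state`.
#'
#' @param path Path to the file. Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowPeak"`, `"segmentation"`.
#' @return A `GRanges`; metadata columns depend on the dialect.
#' @export
read_bed <- function(path,
                     dialect = c("bed3", "bed6", "narrowPeak", "segmentation")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_bed_granges(dialect))

  need <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L, segmentation = 4L)[[dialect]]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < need)
  if (length(bad))
    stop("malformed ", dialect, " line ", lineno[bad[1]], " in ", path,
         ": expected >= ", need, " fields, got ", nf[bad[1]])
  m <- matrix(unlist(lapply(fields, `[`, seq_len(need))), ncol = need,
              byrow = TRUE)

  chrom <- m[, 1]
  start0 <- suppressWarnings(as.numeric(m[, 2]))
  end0 <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("malformed ", dialect, " line ", lineno[bad[1]], " in ", path,
         ": non-numeric coordinates")
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad))
    stop("invalid interval at line ", lineno[bad[1]], " in ", path,
         ": need 0 <= start < end, got [", start0[bad[1]], ",",
         end0[bad[1]], ")")

  gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  if (dialect == "bed6") {
    mcols(gr)$name <- m[, 4]
    mcols(gr)$score <- suppressWarnings(as.numeric(m[, 5]))
    strand(gr) <- ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*")
  } else if (dialect == "segmentation") {
    mcols(gr)$state <- m[, 4]
  } else if (dialect == "narrowPeak") {
    mcols(gr)$name <- m[, 4]
    strand(gr) <- ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*")
    mcols(gr)$score <- suppressWarnings(as.numeric(m[, 7]))
    logp <- suppressWarnings(as.numeric(m[, 8]))
    mcols(gr)$pvalue <- ifelse(logp < 0, NA_real_, 10^(-logp))
    off <- suppressWarnings(as.numeric(m[, 10]))
    bad <- which(!is.na(off) & off >= 0 & (start0 + off >= end0))
    if (length(bad))
      stop("summit offset outside peak at line ", lineno[bad[1]], " in ", path)
    mcols(gr)$summit <- ifelse(is.na(off) | off < 0, NA_real_, start0 + off + 1)
  }
  gr
}

empty_bed_granges <- function(dialect) {
  gr <- GRanges()
  if (dialect == "segmentation") mcols(gr)$state <- character(0)
  if (dialect == "bed6") {
    mcols(gr)$name <- character(0); mcols(gr)$score <- numeric(0)
  }
  if (dialect == "narrowPeak") {
    mcols(gr)$name <- character(0); mcols(gr)$score <- numeric(0)
    mcols(gr)$pvalue <- numeric(0); mcols(gr)$summit <- numeric(0)
  }
  gr
}

#' Write a `GRanges` as a BED-family file
#'
#' Inverse of [read_bed()]: emits tab-separated, newline-terminated records
#' with 0-based half-open coordinates. For `"narrowPeak"` the summit column
#' is recomputed as the offset from the peak start (-1 when absent) and the
#' p-value column as -log10(p).
#'
#' @param gr A `GRanges` with the metadata columns the dialect needs.
#' @param path Output path.
#' @param dialect As in [read_bed()].
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path,
                      dialect = c("bed3", "bed6", "narrowPeak", "segmentation")) {
  dialect <- match.arg(dialect)
  chrom <- as.character(seqnames(gr))
  s0 <- format_bp(start(gr) - 1)
  e0 <- format_bp(end(gr))
  mc <- mcols(gr)
  grab <- function(col, default) {
    if (col %in% names(mc)) mc[[col]] else rep(default, length(gr))
  }
  lines <- switch(dialect,
    bed3 = paste(chrom, s0, e0, sep = "\t"),
    segmentation = paste(chrom, s0, e0, grab("state", "."), sep = "\t"),
    bed6 = paste(chrom, s0, e0, grab("name", "."),
                 ifelse(is.na(grab("score", 0)), 0, grab("score", 0)),
                 as.character(strand(gr)), sep = "\t"),
    narrowPeak = {
      p <- grab("pvalue", NA_real_)
      logp <- ifelse(is.na(p), -1, -log10(p))
      summit <- grab("summit", NA_real_)
      off <- ifelse(is.na(summit), -1, summit - start(gr))
      paste(chrom, s0, e0, grab("name", "."),
            0, as.character(strand(gr)),
            ifelse(is.na(grab("score", 0)), 0, grab("score", 0)),
            format_bp(logp), -1, format_bp(off), sep = "\t")
    })
  writeLines(lines, path)
  invisible(path)
}

# plain decimal formatting for coordinates (avoids 1e+06-style output)
format_bp <- function(x) {
  ifelse(x == floor(x), format(x, scientific = FALSE, trim = TRUE),
         format(round(x, 6), scientific = FALSE, trim = TRUE))
}

#' Merge intervals into a sorted disjoint union
#'
#' Returns sorted, pairwise-disjoint intervals covering exactly the union of
#' the input. Bookended intervals (`[0,10)` + `[10,20)`) are joined, so
#' nucleotide counts over the result never double-count. Strand is ignored:
#' no analysis in this package is strand-aware.
#'
#' @param x A `GRanges` (metadata columns are dropped).
#' @return A reduced `GRanges`.
#' @export
gi_merge <- function(x) {
  reduce(granges(x), ignore.strand = TRUE)
}

#' Intersect two interval sets
#'
#' Nucleotide-level intersection of the unions of `a` and `b`.
#'
#' @param a,b `GRanges` objects.
#' @return A merged `GRanges` covering exactly the positions present in both.
#' @export
gi_intersect <- function(a, b) {
  a <- gi_merge(a)
  b <- gi_merge(b)
  suppressWarnings(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
}

#' Total nucleotides covered by an interval set
#'
#' The number of distinct base pairs covered by the union of `x` — "number of
#' nucleotides within peaks" in contingency-table language.
#'
#' @param x A `GRanges`.
#' @return A non-negative number of base pairs.
#' @export
total_nt <- function(x) {
  sum(as.numeric(width(gi_merge(x))))
}

#' Per-interval covered fraction
#'
#' For each interval in `x`, the fraction of its bases covered by the union
#' of `by`. Used to classify ATAC peaks by H3K4ox overlap.
#'
#' @param x Query `GRanges`.
#' @param by Covering `GRanges` (merged internally).
#' @return Numeric vector in `[0, 1]`, one value per interval of `x`.
#' @export
covered_fraction <- function(x, by) {
  if (any(width(x) <= 0)) stop("zero-length interval in query")
  red <- gi_merge(by)
  hits <- findOverlaps(x, red, ignore.strand = TRUE)
  ov <- width(pintersect(granges(x)[queryHits(hits)], red[subjectHits(hits)]))
  covered <- rep(0, length(x))
  if (length(hits)) {
    agg <- tapply(ov, queryHits(hits), sum)
    covered[as.integer(names(agg))] <- agg
  }
  covered / width(x)
}
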