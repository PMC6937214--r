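#' Read a differential-gene table
#'
#' Tab-delimited table with columns `gene_id`, `chrom`, `start`, `end`
#' (BED-style 0-based half-open), `logfc`, `fdr`.
#'
#' @param path TSV file.
#' @return `GRanges` with metadata columns `gene_id`, `logfc`, `fdr`.
#' @export
read_gene_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "logfc", "fdr")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("gene table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(df$end <= df$start)) stop("gene with end <= start in ", path)
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE))
    stop("fdr outside [0, 1] in ", path)
  gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end))
  mcols(gr)$gene_id <- df$gene_id
  mcols(gr)$logfc <- df$logfc
  mcols(gr)$fdr <- df$fdr
  gr
}

#' Link differential genes to accessible peaks by distance
#'
#' Pairs every gene with every peak lying within `threshold` bp of it,
#' direction-agnostic (up- or downstream). The gap distance is 0 when the
#' intervals intersect, otherwise the number of bases strictly between their
#' nearest ends; the threshold is inclusive (`gap <= threshold` links).
#' Genes and peaks on different chromosomes never link. Each (gene, peak)
#' pair appears at most once.
#'
#' By default distance is measured to the whole gene span;
#' `anchor = "tss"` collapses each gene to its 5' end first (the leftmost
#' base for unstranded or `+` genes, the rightmost for `-`).
#'
#' @param genes `GRanges` with a `gene_id` metadata column.
#' @param peaks `GRanges` of (typically H3K4ox-overlapping, significant
#'   ATAC) peaks.
#' @param threshold Maximum gap in bp (e.g. 5e5 or 1e6).
#' @param anchor `"span"` (default) or `"tss"`.
#' @return `data.frame`: `gene_id`, `peak` (name or index), `distance`,
#'   `threshold`.
#' @export
link_genes <- function(genes, peaks, threshold, anchor = c("span", "tss")) {
  anchor <- match.arg(anchor)
  stopifnot(threshold > 0)
  q <- genes
  if (anchor == "tss") {
    neg <- as.character(strand(genes)) == "-"
    pos <- ifelse(neg, end(genes), start(genes))
    q <- GRanges(seqnames(genes), IRanges(pos, pos), strand = strand(genes))
    mcols(q) <- mcols(genes)
  }
  # cross-chromosome pairs are legitimately absent; silence seqlevel-merge
  # warnings when the two sets have disjoint chromosomes
  hits <- suppressWarnings(
    findOverlaps(q, peaks, maxgap = threshold, ignore.strand = TRUE))
  if (!length(hits))
    return(data.frame(gene_id = character(0), peak = character(0),
                      distance = numeric(0), threshold = numeric(0)))
  d <- suppressWarnings(distance(q[queryHits(hits)], peaks[subjectHits(hits)],
                                 ignore.strand = TRUE))
  peak_id <- if ("name" %in% names(mcols(peaks)))
    mcols(peaks)$name[subjectHits(hits)] else as.character(subjectHits(hits))
  gene_id <- if ("gene_id" %in% names(mcols(genes)))
    mcols(genes)$gene_id[queryHits(hits)] else as.character(queryHits(hits))
  out <- data.frame(gene_id = gene_id, peak = peak_id, distance = d,
                    threshold = threshold, stringsAsFactors = FALSE)
  out <- out[out$distance <= threshold, , drop = FALSE]  # guard maxgap edge
  out <- unique(out)
  rownames(out) <- NULL
  out
}
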