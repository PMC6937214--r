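#' Construct a genome description
#'
#' A genome is a named vector of chromosome sizes plus an effective
#' (mappable) size. The effective size is the universe for nucleotide-level
#' contingency tables: the "remaining genome" cell is computed as the
#' difference from it, mirroring the effective genome size used for ChIP-seq
#' peak calling (2,700,000,000 bp is the usual hg19 value).
#'
#' @param chrom_sizes Named numeric vector, chromosome name -> length in bp.
#' @param effective_size Effective genome size in bp. Defaults to the sum of
#'   the chromosome sizes (appropriate for fully mappable synthetic genomes);
#'   for real mammalian genomes pass the peak-caller's effective size.
#' @return An object of class `oxi_genome`: a list with elements
#'   `chrom_sizes` and `effective_size`.
#' @export
#' @examples
#' oxi_genome(c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6))
oxi_genome <- function(chrom_sizes, effective_size = sum(chrom_sizes)) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("all chromosome lengths must be positive")
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicated chromosome names")
  effective_size <- as.numeric(effective_size)
  if (length(effective_size) != 1 || effective_size <= 0)
    stop("effective_size must be a single positive number")
  if (effective_size > sum(chrom_sizes))
    stop("effective_size cannot exceed the summed chromosome sizes")
  structure(
    list(chrom_sizes = chrom_sizes, effective_size = effective_size),
    class = "oxi_genome"
  )
}

#' @export
print.oxi_genome <- function(x, ...) {
  cat("<oxi_genome> ", length(x$chrom_sizes), " chromosomes, ",
      format(sum(x$chrom_sizes), big.mark = ","), " bp (effective ",
      format(x$effective_size, big.mark = ","), " bp)\n", sep = "")
  invisible(x)
}

# seqlengths vector for building GRanges/coverage against this genome
genome_seqlengths <- function(genome) {
  stopifnot(inherits(genome, "oxi_genome"))
  genome$chrom_sizes
}

#' Normalize chromosome-name style
#'
#' Files from different sources disagree on the "chr" prefix ("chr1" vs "1").
#' Mixing styles in one analysis is an error elsewhere in the package; this
#' helper converts a `GRanges` to a chosen style up front.
#'
#' @param gr A `GRanges`.
#' @param style `"chr"` to add the prefix, `"plain"` to strip it.
#' @return The `GRanges` with renamed seqlevels.
#' @export
normalize_chroms <- function(gr, style = c("chr", "plain")) {
  style <- match.arg(style)
  lv <- GenomeInfoDb::seqlevels(gr)
  new <- if (style == "chr") ifelse(grepl("^chr", lv), lv, paste0("chr", lv))
         else sub("^chr", "", lv)
  GenomeInfoDb::renameSeqlevels(gr, setNames(new, lv))
}

# error unless two GRanges share at least one chromosome name, and warn on
# a chr/plain style clash, which silently produces empty intersections
check_chrom_compat <- function(a, b, what = c("first", "second")) {
  la <- unique(as.character(seqnames(a)))
  lb <- unique(as.character(seqnames(b)))
  if (length(la) && length(lb) && !length(intersect(la, lb))) {
    if (any(grepl("^chr", la)) != any(grepl("^chr", lb)))
      stop("chromosome naming styles differ between inputs ",
           "(e.g. 'chr1' vs '1'); use normalize_chroms() on one of them")
    stop("inputs share no chromosome names (",
         paste(utils::head(la, 3), collapse = ","), " vs ",
         paste(utils::head(lb, 3), collapse = ","), ")")
  }
  invisible(TRUE)
}
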