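#' Filter peaks by calling significance
#'
#' Retains exactly the peaks with `pvalue < alpha`, strictly: a peak at the
#' threshold (p = 1e-5 with the default alpha) is excluded. Peak calling with
#' no FDR restriction leaves this threshold as the sole significance gate.
#'
#' @param peaks `GRanges` with a `pvalue` metadata column (linear scale).
#' @param alpha Significance threshold; default `1e-5`.
#' @return The subset of `peaks` passing the filter.
#' @export
filter_significant <- function(peaks, alpha = 1e-5) {
  if (!"pvalue" %in% names(mcols(peaks)))
    stop("peaks carry no 'pvalue' column")
  p <- mcols(peaks)$pvalue
  if (anyNA(p)) stop("missing p-value on ", sum(is.na(p)), " peak(s)")
  peaks[p < alpha]
}

#' Classify ATAC peaks by H3K4ox coverage
#'
#' Computes, for each ATAC peak, the fraction of its bases covered by the
#' union of the H3K4ox peaks, and labels the peak `"overlapping"` when the
#' fraction strictly exceeds `min_frac` (default 0.95: only intersections
#' involving more than 95% of the ATAC peak sequence count) and `"orphan"`
#' otherwise. The two labels partition the input.
#'
#' @param atac_peaks Significance-filtered ATAC peak `GRanges`.
#' @param chip_peaks H3K4ox peak `GRanges` (merged internally).
#' @param min_frac Strict lower bound on the covered fraction; default 0.95.
#' @return `atac_peaks` with added metadata columns `covered_fraction` and
#'   `label` (factor, levels `overlapping`, `orphan`).
#' @export
classify_peaks <- function(atac_peaks, chip_peaks, min_frac = 0.95) {
  if (length(atac_peaks) && length(chip_peaks))
    check_chrom_compat(atac_peaks, chip_peaks)
  frac <- covered_fraction(atac_peaks, chip_peaks)
  mcols(atac_peaks)$covered_fraction <- frac
  mcols(atac_peaks)$label <- factor(
    ifelse(frac > min_frac, "overlapping", "orphan"),
    levels = c("overlapping", "orphan"))
  atac_peaks
}

#' Read a bedGraph coverage track
#'
#' Loads 4-column bedGraph (chrom, start0, end0, value) into a run-length
#' encoded per-base track (`RleList`) over the full genome; positions not
#' covered by any record are 0.
#'
#' @param path bedGraph file.
#' @param genome An [oxi_genome()] supplying chromosome lengths.
#' @return An `RleList`, one `Rle` of length `chrom size` per chromosome.
#' @export
read_bedgraph <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start0", "end0", "value"),
                          colClasses = list(character = 1, numeric = 2:4),
                          skip = 0, blank.lines.skip = TRUE,
                          data.table = FALSE)
  df <- df[!grepl("^(#|track|browser)", df$chrom), , drop = FALSE]
  if (anyNA(df$start0) || anyNA(df$end0) || anyNA(df$value))
    stop("malformed bedGraph record in ", path)
  if (any(df$end0 <= df$start0)) stop("bedGraph record with end <= start in ", path)
  if (any(df$value < 0)) stop("negative coverage value in ", path)
  sl <- genome_seqlengths(genome)
  missing <- setdiff(unique(df$chrom), names(sl))
  if (length(missing))
    stop("bedGraph chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "))
  gr <- GRanges(df$chrom, IRanges(df$start0 + 1, df$end0), seqlengths = sl)
  coverage(gr, weight = df$value)
}

#' Write a coverage track as bedGraph
#'
#' Emits one record per maximal run of equal nonzero coverage (run-length
#' compression); zero runs are omitted, as [read_bedgraph()] restores them.
#'
#' @param track An `RleList` coverage track.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  per_chrom <- lapply(names(track), function(chrom) {
    r <- track[[chrom]]
    ends <- cumsum(runLength(r))
    starts0 <- ends - runLength(r)   # 0-based starts
    v <- runValue(r)
    keep <- v != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start = starts0[keep], end = ends[keep],
               value = v[keep])
  })
  df <- do.call(rbind, per_chrom)
  if (is.null(df)) {
    file.create(path)
    return(invisible(path))
  }
  # tracks hold millions of runs; fwrite keeps this near-instant
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE,
                     scipen = 50)
  invisible(path)
}

# all tracks defined on identical chromosome sets and lengths
check_same_genome <- function(tracks) {
  nm <- lapply(tracks, names)
  ln <- lapply(tracks, lengths)
  if (!all(vapply(nm[-1], identical, TRUE, nm[[1]])) ||
      !all(vapply(ln[-1], function(l) all(l == ln[[1]]), TRUE)))
    stop("coverage tracks are not defined on the same genome")
  invisible(TRUE)
}

#' Average replicate coverage tracks
#'
#' Per-position arithmetic mean of the tracks; a position absent (zero) in
#' one track contributes 0 for that track.
#'
#' @param tracks List of `RleList` tracks on the same genome.
#' @return An `RleList` of per-position means.
#' @export
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  check_same_genome(tracks)
  Reduce(`+`, tracks) / length(tracks)
}

# per-peak summit: narrowPeak summit when present, else interval midpoint
peak_summits <- function(peaks) {
  s <- if ("summit" %in% names(mcols(peaks))) mcols(peaks)$summit
       else rep(NA_real_, length(peaks))
  mid <- floor((start(peaks) + end(peaks)) / 2)
  ifelse(is.na(s), mid, s)
}

#' Summit-aligned signal matrix
#'
#' Extracts per-base coverage in a window of `flank` bp on each side of every
#' peak summit: row i, column j holds the track value at
#' `summit_i + offset_j`, offsets running `-flank..+flank` in 1-bp bins.
#' Rows keep the input peak order. Offsets falling outside the chromosome
#' contribute 0, and such rows are flagged in the `truncated` attribute.
#'
#' @param peaks Peak `GRanges`; summit from the `summit` column when present,
#'   otherwise the interval midpoint.
#' @param track An `RleList` coverage track.
#' @param flank Half-window in bp (default 2000).
#' @return Numeric matrix `length(peaks) x (2*flank+1)` with attributes
#'   `offsets` (integer vector) and `truncated` (logical per row).
#' @export
summit_matrix <- function(peaks, track, flank = 2000) {
  offs <- -flank:flank
  n <- length(peaks)
  m <- matrix(0, nrow = n, ncol = length(offs))
  truncated <- logical(n)
  summits <- peak_summits(peaks)
  chroms <- as.character(seqnames(peaks))
  for (i in seq_len(n)) {
    r <- track[[chroms[i]]]
    if (is.null(r)) stop("peak chromosome '", chroms[i], "' not in track")
    L <- length(r)
    lo <- summits[i] - flank; hi <- summits[i] + flank
    clo <- max(1, lo); chi <- min(L, hi)
    if (clo > lo || chi < hi) truncated[i] <- TRUE
    if (clo <= chi)
      m[i, (clo - lo + 1):(chi - lo + 1)] <- as.numeric(window(r, clo, chi))
  }
  structure(m, offsets = offs, truncated = truncated)
}

#' Control-summit-normalized metaprofiles
#'
#' Sums each signal matrix over peaks at every offset, then divides both
#' position-wise sums by the control sum at offset 0, making all values
#' relative to the maximum control value: the control profile is exactly 1
#' at the summit, and a knockdown/control ratio can be read off directly.
#'
#' @param kd_matrix,ctrl_matrix Matrices from [summit_matrix()] over the same
#'   peaks and offsets.
#' @return `data.frame` with columns `offset`, `ctrl`, `kd`.
#' @export
linear_profile <- function(kd_matrix, ctrl_matrix) {
  if (!identical(dim(kd_matrix), dim(ctrl_matrix)))
    stop("matrices differ in shape")
  offs <- attr(ctrl_matrix, "offsets")
  if (is.null(offs)) offs <- seq_len(ncol(ctrl_matrix)) -
      (ncol(ctrl_matrix) + 1) / 2
  s_ctrl <- colSums(ctrl_matrix)
  s_kd <- colSums(kd_matrix)
  denom <- s_ctrl[offs == 0]
  if (length(denom) != 1 || denom == 0)
    stop("control summit column-sum is zero; profile undefined")
  data.frame(offset = offs, ctrl = s_ctrl / denom, kd = s_kd / denom)
}
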