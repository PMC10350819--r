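#' A per-position crosslink track over a genomic window
#'
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`; antisense positions are never mixed in.
#' @param start 0-based start of the window (half-open interval
#'   `[start, start + length(counts))`).
#' @param counts Non-negative integer crosslink counts, one per position.
#' @param library_size Total crosslinks in the library; must be at least
#'   the window sum.
#' @return An object of class `crosslink_track`.
#' @export
crosslink_track <- function(chrom, strand, start, counts, library_size) {
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  assert_scalar_number(library_size, "library_size", lower = 0)
  if (library_size < sum(counts))
    stopf("library_size (%s) below window sum (%s)",
          format(library_size), format(sum(counts)))
  structure(list(chrom = chrom, strand = strand, start = as.integer(start),
                 counts = as.numeric(counts),
                 library_size = library_size),
            class = "crosslink_track")
}

#' Read a crosslink track from a bedGraph file
#'
#' Positions inside the requested window without a record are zero.
#' bedGraph intervals are 0-based half-open, matching the track
#' convention.
#'
#' @param path bedGraph file path.
#' @param chrom,start,end Window (0-based half-open).
#' @param strand Track strand (bedGraph itself is strandless; the caller
#'   asserts which strand the file holds).
#' @param library_size Total crosslinks in the library; defaults to the
#'   file-wide sum of `count * width`.
#' @return A [crosslink_track()].
#' @export
read_bedgraph_track <- function(path, chrom, start, end, strand = "+",
                                library_size = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (is.null(library_size))
    library_size <- sum(gr$score * BiocGenerics::width(gr))
  win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- IRanges::subsetByOverlaps(gr, win)
  counts <- numeric(end - start)
  for (i in seq_along(hits)) {
    s <- max(BiocGenerics::start(hits)[i] - 1L, start)   # back to 0-based
    e <- min(BiocGenerics::end(hits)[i], end)
    if (e > s) counts[(s - start + 1L):(e - start)] <- hits$score[i]
  }
  crosslink_track(chrom, strand, start, counts, library_size)
}

#' Write track values as bedGraph
#'
#' @param track A [crosslink_track()].
#' @param path Output path.
#' @param values Values to write (defaults to the raw counts; pass the
#'   normalized/smoothed vector to export those).
#' @return Invisibly, `path`.
#' @export
write_bedgraph_track <- function(track, path, values = track$counts) {
  stopifnot(inherits(track, "crosslink_track"),
            length(values) == length(track$counts))
  gr <- GenomicRanges::GRanges(
    track$chrom,
    IRanges::IRanges(track$start + seq_along(values), width = 1L),
    score = values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Library-size normalization of a crosslink track
#'
#' Crosslinks per million: `counts * 1e6 / library_size`. Zero positions
#' and relative ratios are preserved exactly.
#'
#' @param track A [crosslink_track()].
#' @return Numeric vector of per-position crosslinks per million.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "crosslink_track"))
  if (track$library_size <= 0) stopf("library_size must be > 0")
  track$counts * 1e6 / track$library_size
}

#' Centered rolling-mean smoothing
#'
#' Centered rolling mean of odd width; edges use the truncated (shrinking)
#' window, so a constant vector is unchanged and the output maximum never
#' exceeds the input maximum. A window larger than the vector returns the
#' global mean everywhere.
#'
#' @param values Numeric vector.
#' @param window Odd window width, at least 1 (default 5).
#' @return Smoothed vector of the same length.
#' @export
smooth_track <- function(values, window = 5L) {
  assert_scalar_number(window, "window", lower = 1, integer = TRUE)
  if (window %% 2L == 0L) stopf("window must be odd")
  if (window > length(values))
    return(rep(mean(values), length(values)))
  as.numeric(zoo::rollapply(values, window, mean, partial = TRUE,
                            align = "center"))
}
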