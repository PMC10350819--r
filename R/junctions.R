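#' Define a skipped-exon (cassette) event
#'
#' Coordinates are 0-based half-open on the genomic axis, ordered
#' upstream < cassette < downstream with no overlap. A junction is the
#' half-open gap between the last base of the left exon and the first base
#' of the right exon.
#'
#' @param chrom Reference sequence name.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded).
#' @param upstream,cassette,downstream Length-2 integer vectors
#'   `c(start, end)`, 0-based half-open.
#' @param variant Free-text tag (e.g. `"3a-L"`).
#' @param one_based Set `TRUE` if the supplied intervals are 1-based
#'   closed (converted at this boundary).
#' @return An object of class `skipped_exon_event`.
#' @export
skipped_exon_event <- function(chrom, strand = "*", upstream, cassette,
                               downstream, variant = "PE",
                               one_based = FALSE) {
  conv <- function(x, name) {
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
      stopf("`%s` must be a length-2 numeric interval", name)
    x <- as.integer(x)
    if (one_based) x <- c(x[1] - 1L, x[2])
    if (x[1] >= x[2]) stopf("`%s` must satisfy start < end", name)
    x
  }
  upstream <- conv(upstream, "upstream")
  cassette <- conv(cassette, "cassette")
  downstream <- conv(downstream, "downstream")
  if (!(upstream[2] <= cassette[1] && cassette[2] <= downstream[1]))
    stopf("exons must be ordered and non-overlapping: upstream < cassette < downstream")
  if (!strand %in% c("+", "-", "*")) stopf("invalid strand: %s", strand)
  structure(list(chrom = as.character(chrom), strand = strand,
                 upstream = upstream, cassette = cassette,
                 downstream = downstream, variant = variant),
            class = "skipped_exon_event")
}

#' Junction read counts for a cassette event
#'
#' Container for the three junction categories with the effective lengths
#' used for isoform-length normalization. With anchor `m` and read length
#' `L`, a single junction offers `L - 2 (m - 1)` distinct spanning positions;
#' the included isoform has two junctions and so twice that effective length.
#'
#' @param I_up,I_down Reads spanning the upstream-cassette and
#'   cassette-downstream junctions.
#' @param S Reads spanning the skipping (upstream-downstream) junction.
#' @param read_length,min_anchor Used to derive default effective lengths.
#' @param eff_len_inc,eff_len_skip Override the derived effective lengths.
#' @return An object of class `junction_counts`.
#' @export
junction_counts <- function(I_up, I_down, S, read_length = 50L,
                            min_anchor = 6L,
                            eff_len_inc = NULL, eff_len_skip = NULL) {
  for (nm in c("I_up", "I_down", "S"))
    assert_scalar_number(get(nm), nm, lower = 0, integer = TRUE)
  if (is.null(eff_len_skip)) {
    assert_scalar_number(min_anchor, "min_anchor", lower = 1, integer = TRUE)
    ell <- read_length - 2L * (min_anchor - 1L)
    if (ell <= 0) stopf("read_length too short for min_anchor %d", min_anchor)
    eff_len_skip <- ell
  }
  if (is.null(eff_len_inc)) eff_len_inc <- 2L * eff_len_skip
  assert_scalar_number(eff_len_inc, "eff_len_inc", lower = 1e-9)
  assert_scalar_number(eff_len_skip, "eff_len_skip", lower = 1e-9)
  structure(list(I_up = as.integer(I_up), I_down = as.integer(I_down),
                 S = as.integer(S), eff_len_inc = eff_len_inc,
                 eff_len_skip = eff_len_skip),
            class = "junction_counts")
}

#' A percent-spliced-in value
#'
#' @param psi Estimate in `[0, 1]`, or `NA` when undefined (no informative
#'   signal); `undefined` is then `TRUE` so an absent value is never silently
#'   reported as 0.
#' @param method One of `"gel"`, `"junction"`, `"qpcr"`.
#' @param components Named list of the raw inputs used.
#' @return An object of class `psi_value`.
#' @export
psi_value <- function(psi, method, components = list()) {
  undefined <- is.na(psi)
  if (!undefined) assert_scalar_number(psi, "psi", 0, 1)
  if (!method %in% c("gel", "junction", "qpcr"))
    stopf("unknown PSI method: %s", method)
  structure(list(psi = psi, method = method, undefined = undefined,
                 components = components),
            class = "psi_value")
}

#' @export
print.psi_value <- function(x, ...) {
  cat(sprintf("<psi_value[%s]> %s\n", x$method,
              if (x$undefined) "undefined (no informative signal)"
              else format(x$psi, digits = 4)))
  invisible(x)
}

# per-alignment gap table: reference coords of each N gap plus the number of
# aligned (M/=/X) query bases immediately flanking it
.alignment_gaps <- function(cigars, starts) {
  ops <- GenomicAlignments::explodeCigarOps(cigars)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigars)
  out <- vector("list", length(cigars))
  for (i in seq_along(cigars)) {
    op <- ops[[i]]; ln <- lens[[i]]
    n_idx <- which(op == "N")
    if (!length(n_idx)) { out[[i]] <- NULL; next }
    ref_consumes <- op %in% c("M", "=", "X", "D", "N")
    aligned <- op %in% c("M", "=", "X")
    ref_off <- cumsum(ifelse(ref_consumes, ln, 0L))
    res <- matrix(0L, nrow = length(n_idx), ncol = 4L)
    seg_bounds <- c(0L, n_idx, length(op) + 1L)
    for (k in seq_along(n_idx)) {
      j <- n_idx[k]
      gap_end0 <- starts[i] - 1L + ref_off[j]            # 0-based half-open
      gap_start0 <- gap_end0 - ln[j]
      left_rng <- (seg_bounds[k] + 1L):(j - 1L)
      right_rng <- (j + 1L):(seg_bounds[k + 2L] - 1L)
      res[k, ] <- c(gap_start0, gap_end0,
                    sum(ln[left_rng][aligned[left_rng]]),
                    sum(ln[right_rng][aligned[right_rng]]))
    }
    out[[i]] <- res
  }
  out
}

#' Count junction-supporting reads for a cassette event
#'
#' A read supports a junction iff its alignment contains a gap (CIGAR `N`)
#' whose donor/acceptor coordinates match the event's junction exactly and it
#' aligns at least `min_anchor` nt on both sides of that gap. Each read is
#' counted at most once per junction; secondary and supplementary records are
#' ignored. Order of records is irrelevant.
#'
#' @param alignments Path to a SAM or BAM file (SAM is converted via
#'   [Rsamtools::asBam()]), or a `GAlignments` object.
#' @param event A [skipped_exon_event()] on the alignments' reference.
#' @param min_anchor Minimum aligned nt on each side of the gap (default 6).
#' @param strand Optional strand filter (`"+"`/`"-"`); default unstranded.
#' @param read_length Read length used for the effective lengths; inferred
#'   from the modal query width when `NULL`.
#' @return A [junction_counts()] object.
#' @export
extract_junction_counts <- function(alignments, event, min_anchor = 6L,
                                    strand = NULL, read_length = NULL) {
  stopifnot(inherits(event, "skipped_exon_event"))
  assert_scalar_number(min_anchor, "min_anchor", lower = 1, integer = TRUE)
  ga <- .load_alignments(alignments)
  refs <- GenomeInfoDb::seqlevels(ga)
  if (!event$chrom %in% refs)
    stopf("event reference '%s' not among alignment references: %s",
          event$chrom, paste(refs, collapse = ", "))
  ga <- ga[as.character(GenomicAlignments::seqnames(ga)) == event$chrom]
  if (!is.null(strand))
    ga <- ga[as.character(BiocGenerics::strand(ga)) == strand]
  if (is.null(read_length)) {
    qw <- GenomicAlignments::qwidth(ga)
    read_length <- if (length(qw)) as.integer(names(sort(table(qw),
                                                         decreasing = TRUE))[1])
                   else 50L
  }
  targets <- rbind(up   = c(event$upstream[2], event$cassette[1]),
                   down = c(event$cassette[2], event$downstream[1]),
                   skip = c(event$upstream[2], event$downstream[1]))
  tallies <- c(up = 0L, down = 0L, skip = 0L)
  if (length(ga)) {
    gaps <- .alignment_gaps(as.character(GenomicAlignments::cigar(ga)),
                            BiocGenerics::start(ga))
    for (g in gaps) {
      if (is.null(g)) next
      ok <- g[, 3] >= min_anchor & g[, 4] >= min_anchor
      for (jn in rownames(targets)) {
        hit <- ok & g[, 1] == targets[jn, 1] & g[, 2] == targets[jn, 2]
        if (any(hit)) tallies[jn] <- tallies[jn] + 1L   # once per read
      }
    }
  }
  junction_counts(I_up = tallies[["up"]], I_down = tallies[["down"]],
                  S = tallies[["skip"]], read_length = read_length,
                  min_anchor = min_anchor)
}

.load_alignments <- function(alignments) {
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags)
  if (is(alignments, "GAlignments")) return(alignments)
  if (!is.character(alignments) || length(alignments) != 1L)
    stopf("`alignments` must be a file path or GAlignments object")
  if (!file.exists(alignments)) stopf("no such file: %s", alignments)
  path <- alignments
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  GenomicAlignments::readGAlignments(path, param = param)
}

#' Junction-read PSI with isoform-length normalization
#'
#' \deqn{\Psi = \frac{(I_{up}+I_{down})/\ell_{inc}}
#'   {(I_{up}+I_{down})/\ell_{inc} + S/\ell_{skip}}}
#' where by default \eqn{\ell_{inc} = 2\ell} and \eqn{\ell_{skip} = \ell}
#' with \eqn{\ell = L - 2(m-1)} for read length \eqn{L} and minimum anchor
#' \eqn{m}. All counts zero yields an undefined (flagged) PSI.
#'
#' @param counts A [junction_counts()] object.
#' @return A [psi_value()] with `method = "junction"`.
#' @export
junction_psi <- function(counts) {
  stopifnot(inherits(counts, "junction_counts"))
  inc <- (counts$I_up + counts$I_down) / counts$eff_len_inc
  skp <- counts$S / counts$eff_len_skip
  psi <- if (inc + skp == 0) NA_real_ else inc / (inc + skp)
  psi_value(psi, "junction", components = unclass(counts))
}

#' Group difference in PSI with a permutation p-value
#'
#' Effect is `mean(group_a) - mean(group_b)`. The two-sided p-value comes
#' from label permutations with the add-one correction
#' `p = (b + 1) / (m + 1)`, where `b` counts assignments (the observed one
#' included) whose absolute effect reaches the observed one. All
#' `choose(n, n_a)` assignments are enumerated when that number does not
#' exceed `n_perm`; otherwise `n_perm` random assignments are drawn.
#'
#' @param group_a,group_b Numeric vectors of replicate PSI values.
#' @param n_perm Permutation budget (default `10000`).
#' @param seed Seed for the random-assignment fallback.
#' @return List with `effect`, `p_value` (`NA` with fewer than 2 replicates
#'   per group), `n_perm_used` and `exhaustive`.
#' @export
delta_psi <- function(group_a, group_b, n_perm = 10000L, seed = 1L) {
  stopifnot(is.numeric(group_a), is.numeric(group_b),
            length(group_a) >= 1, length(group_b) >= 1)
  effect <- mean(group_a) - mean(group_b)
  if (length(group_a) < 2 || length(group_b) < 2)
    return(list(effect = effect, p_value = NA_real_, n_perm_used = 0L,
                exhaustive = FALSE))
  pool <- c(group_a, group_b)
  na <- length(group_a); n <- length(pool)
  tol <- 1e-12
  total <- choose(n, na)
  if (total <= n_perm) {
    idx <- utils::combn(n, na, simplify = FALSE)
    effs <- vapply(idx, function(i) mean(pool[i]) - mean(pool[-i]),
                   numeric(1))
    b <- sum(abs(effs) >= abs(effect) - tol)
    m <- length(effs)
    exhaustive <- TRUE
  } else {
    effs <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      i <- sample.int(n, na)
      mean(pool[i]) - mean(pool[-i])
    }, numeric(1)))
    b <- sum(abs(effs) >= abs(effect) - tol)
    m <- n_perm
    exhaustive <- FALSE
  }
  list(effect = effect, p_value = (b + 1) / (m + 1), n_perm_used = m,
       exhaustive = exhaustive)
}
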