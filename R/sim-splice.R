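#' Parameters for the cassette-exon read simulator
#'
#' Bundles the ground truth for a three-exon skipped-exon (poison exon, PE)
#' event: the synthesis-level inclusion fraction `psi_true`, the fraction of
#' PE-containing molecules that survive nonsense-mediated decay
#' (`nmd_survival`), sequencing depth and read geometry.
#'
#' @param psi_true Fraction of transcripts that include the cassette exon at
#'   synthesis, in `[0, 1]`.
#' @param n_reads Number of junction-spanning reads to draw (non-negative
#'   integer).
#' @param nmd_survival Fraction of PE-included molecules that escape decay,
#'   in `(0, 1]`. `1` models an NMD-blocked (e.g. SMG1-inhibited) condition.
#' @param read_length Read length in nt. Must not exceed the cassette exon
#'   length so that each read spans exactly one junction.
#' @param event A [skipped_exon_event()] giving the exon coordinates.
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical output.
#'
#' @return An object of class `splice_sim_params`.
#' @seealso [sim_junction_counts()], [sim_junction_reads()]
#' @export
splice_sim_params <- function(psi_true, n_reads, nmd_survival = 1,
                              read_length = 50L,
                              event = synthetic_pe_event(),
                              seed = 1L) {
  assert_scalar_number(psi_true, "psi_true", 0, 1)
  assert_scalar_number(n_reads, "n_reads", lower = 0, integer = TRUE)
  assert_scalar_number(nmd_survival, "nmd_survival", upper = 1)
  if (nmd_survival <= 0) stopf("`nmd_survival` must be in (0, 1]")
  assert_scalar_number(read_length, "read_length", lower = 2, integer = TRUE)
  stopifnot(inherits(event, "skipped_exon_event"))
  pe_len <- event$cassette[2] - event$cassette[1]
  if (read_length > pe_len)
    stopf("read_length (%d) exceeds cassette exon length (%d)",
          read_length, pe_len)
  structure(list(psi_true = psi_true, n_reads = as.integer(n_reads),
                 nmd_survival = nmd_survival,
                 read_length = as.integer(read_length),
                 event = event, seed = as.integer(seed)),
            class = "splice_sim_params")
}

#' Post-decay inclusion fraction
#'
#' Closed-form molar fraction of PE-included molecules after NMD: starting
#' from synthesis inclusion `p` and survival `nu` of included molecules,
#' the surviving pool contains `p * nu / (p * nu + 1 - p)` included molecules.
#'
#' @param psi Synthesis-level inclusion fraction in `[0, 1]`.
#' @param nmd_survival Survival fraction of included molecules in `(0, 1]`.
#' @return The post-decay inclusion fraction.
#' @export
post_decay_inclusion <- function(psi, nmd_survival) {
  psi * nmd_survival / (psi * nmd_survival + 1 - psi)
}

#' A synthetic poison-exon cassette event
#'
#' Default three-exon geometry on a synthetic reference used by the
#' simulators: upstream exon, an 80-nt cassette (PE) and downstream exon on
#' a 2 kb contig. Coordinates are 0-based half-open.
#'
#' @param chrom Reference name.
#' @param variant Free-text tag for the cassette variant.
#' @return A [skipped_exon_event()].
#' @export
synthetic_pe_event <- function(chrom = "synth1", variant = "PE") {
  skipped_exon_event(chrom = chrom, strand = "+",
                     upstream = c(100L, 400L),
                     cassette = c(500L, 580L),
                     downstream = c(700L, 1000L),
                     variant = variant)
}

# read-level category probabilities: an included molecule exposes two
# junctions (twice the effective length) versus one for a skipped molecule,
# so P(inclusion-junction read) = 2 p' / (1 + p') with p' the post-decay
# molar inclusion fraction. This makes the effective-length PSI estimator
# unbiased for p'.
.junction_read_probs <- function(psi_true, nmd_survival) {
  p_post <- post_decay_inclusion(psi_true, nmd_survival)
  c(up = p_post, down = p_post, skip = 1 - p_post) / (1 + p_post)
}

#' Simulate junction read counts for a cassette event
#'
#' Count-level fast path of [sim_junction_reads()]: draws the three junction
#' categories (upstream-PE, PE-downstream, skipping) from a multinomial whose
#' weights combine the post-decay molar inclusion fraction with the 2:1
#' effective-length exposure of the included isoform.
#'
#' @param params A [splice_sim_params()].
#' @param min_anchor Minimum anchor used to compute the effective lengths
#'   attached to the returned counts (see [junction_psi()]).
#' @return A [junction_counts()] object with a `truth` attribute carrying
#'   `psi_true`, `nmd_survival` and the post-decay inclusion fraction.
#' @export
sim_junction_counts <- function(params, min_anchor = 6L) {
  stopifnot(inherits(params, "splice_sim_params"))
  probs <- .junction_read_probs(params$psi_true, params$nmd_survival)
  draw <- with_seed(params$seed,
                    as.vector(rmultinom(1, params$n_reads, probs)))
  counts <- junction_counts(
    I_up = draw[1], I_down = draw[2], S = draw[3],
    read_length = params$read_length, min_anchor = min_anchor)
  attr(counts, "truth") <- list(
    psi_true = params$psi_true, nmd_survival = params$nmd_survival,
    psi_post_decay = post_decay_inclusion(params$psi_true,
                                          params$nmd_survival))
  counts
}

#' Simulate junction-spanning spliced alignments in SAM format
#'
#' Draws reads as in [sim_junction_counts()], places each one across its
#' junction with a uniformly sampled left-anchor length, and writes a headered
#' SAM file with N-operation CIGARs readable by [extract_junction_counts()].
#' A ground-truth label table (one row per read) is written alongside.
#'
#' @param params A [splice_sim_params()].
#' @param sam_file,truth_file Output paths; default into `tempdir()`.
#' @return Invisibly, a list with `sam`, `truth` (path) and `labels`
#'   (the in-memory data frame: `read_id`, `junction`, `included`).
#' @export
sim_junction_reads <- function(params,
                               sam_file = tempfile(fileext = ".sam"),
                               truth_file = tempfile(fileext = ".tsv")) {
  stopifnot(inherits(params, "splice_sim_params"))
  ev <- params$event
  L <- params$read_length
  probs <- .junction_read_probs(params$psi_true, params$nmd_survival)
  dat <- with_seed(params$seed, {
    cat_idx <- if (params$n_reads > 0)
      sample.int(3L, params$n_reads, replace = TRUE, prob = probs)
    else integer(0)
    anchors <- if (params$n_reads > 0)
      sample.int(L - 1L, params$n_reads, replace = TRUE) else integer(0)
    seqs <- random_dna(params$n_reads, L)
    list(cat = cat_idx, anchor = anchors, seq = seqs)
  })
  # junction (donor, acceptor) in 0-based half-open gap coordinates
  gaps <- rbind(up   = c(ev$upstream[2], ev$cassette[1]),
                down = c(ev$cassette[2], ev$downstream[1]),
                skip = c(ev$upstream[2], ev$downstream[1]))
  recs <- character(params$n_reads)
  for (i in seq_len(params$n_reads)) {
    a <- dat$anchor[i]
    gap <- gaps[dat$cat[i], ]
    pos1 <- gap[1] - a + 1L                      # 1-based leftmost
    cigar <- sprintf("%dM%dN%dM", a, gap[2] - gap[1], L - a)
    recs[i] <- paste(sprintf("read%06d", i), 0L, ev$chrom, pos1, 60L, cigar,
                     "*", 0L, 0L, dat$seq[i], strrep("I", L),
                     sep = "\t")
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", ev$chrom,
                      max(2000L, ev$downstream[2] + 1000L)),
              "@PG\tID:coldsplice\tPN:coldsplice")
  writeLines(c(header, recs), sam_file)
  labels <- data.frame(
    read_id = sprintf("read%06d", seq_len(params$n_reads)),
    junction = c("up", "down", "skip")[dat$cat],
    included = dat$cat != 3L)
  write.table(labels, truth_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(sam = sam_file, truth = truth_file, labels = labels))
}
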