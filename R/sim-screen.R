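#' Simulate an sgRNA library
#'
#' Random unique 20-nt guides over `n_genes` genes plus non-targeting
#' controls, mirroring the scale (not the sequences) of genome-wide
#' knockout libraries.
#'
#' @param n_genes Number of targeted genes.
#' @param guides_per_gene Guides per gene (default 4).
#' @param n_nontargeting Non-targeting control guides.
#' @param seed Integer seed.
#' @return A [guide_library()].
#' @export
sim_guide_library <- function(n_genes, guides_per_gene = 4L,
                              n_nontargeting = 100L, seed = 1L) {
  n <- n_genes * guides_per_gene + n_nontargeting
  seqs <- with_seed(seed, {
    s <- unique(random_dna(ceiling(n * 1.2), 20L))
    while (length(s) < n) s <- unique(c(s, random_dna(n, 20L)))
    s[seq_len(n)]
  })
  genes <- c(rep(sprintf("GENE%04d", seq_len(n_genes)),
                 each = guides_per_gene),
             rep("NON_TARGETING", n_nontargeting))
  guide_library(data.frame(
    guide_id = sprintf("sg%05d", seq_len(n)),
    gene = genes, sequence = seqs))
}

#' Simulation parameters for a sorted-pool screen
#'
#' @param library A [guide_library()].
#' @param enriched_guides Guide ids receiving the effect multiplier in the
#'   enriched pool (must be library ids).
#' @param effect Multiplier (> 0) applied to enriched guides' expected
#'   counts in `enriched_pool` samples.
#' @param enriched_pool `"low"` or `"high"` fluorescence pool.
#' @param n_reads Expected matched reads per sample.
#' @param dispersion Negative-binomial dispersion (counts are NB with
#'   `size = 1/dispersion`; 0 gives Poisson).
#' @param read_length Read length in nt (default 21, guide plus one base).
#' @param guide_offset 0-based guide position within the read.
#' @param mutation_fraction Fraction of reads carrying one random
#'   substitution inside the 20-mer (exercises the exact-match discard
#'   rule).
#' @param seed Integer seed.
#' @return An object of class `screen_sim_params`.
#' @export
screen_sim_params <- function(library, enriched_guides = character(),
                              effect = 8, enriched_pool = c("low", "high"),
                              n_reads = 1e5, dispersion = 0.1,
                              read_length = 21L, guide_offset = 0L,
                              mutation_fraction = 0, seed = 1L) {
  stopifnot(inherits(library, "guide_library"))
  enriched_pool <- match.arg(enriched_pool)
  if (!all(enriched_guides %in% library$guide_id))
    stopf("enriched_guides not in library: %s",
          paste(setdiff(enriched_guides, library$guide_id), collapse = ", "))
  assert_scalar_number(effect, "effect", lower = 1e-12)
  assert_scalar_number(n_reads, "n_reads", lower = 1)
  assert_scalar_number(dispersion, "dispersion", lower = 0)
  assert_scalar_number(mutation_fraction, "mutation_fraction", 0, 1)
  assert_scalar_number(guide_offset, "guide_offset", lower = 0,
                       integer = TRUE)
  assert_scalar_number(read_length, "read_length", lower = 1,
                       integer = TRUE)
  if (guide_offset + 20L > read_length)
    stopf("guide_offset + 20 (%d) exceeds read length (%d)",
          guide_offset + 20L, read_length)
  structure(list(library = library, enriched_guides = enriched_guides,
                 effect = effect, enriched_pool = enriched_pool,
                 n_reads = n_reads, dispersion = dispersion,
                 read_length = as.integer(read_length),
                 guide_offset = as.integer(guide_offset),
                 mutation_fraction = mutation_fraction,
                 seed = as.integer(seed)),
            class = "screen_sim_params")
}

# draw one sample's guide counts: NB around library-proportional means
.draw_screen_counts <- function(params, enriched) {
  n <- nrow(params$library)
  mu <- rep(params$n_reads / n, n)
  if (enriched) {
    idx <- match(params$enriched_guides, params$library$guide_id)
    mu[idx] <- mu[idx] * params$effect
  }
  if (params$dispersion > 0)
    as.integer(rnbinom(n, mu = mu, size = 1 / params$dispersion))
  else as.integer(stats::rpois(n, mu))
}

#' Simulate FASTQ files for a FACS-sorted screen
#'
#' Per-guide counts are drawn from a negative binomial around
#' library-proportional means, with the effect multiplier applied in the
#' designated pool; each counted read carries the exact 20-nt guide at
#' `guide_offset`, except for a configurable fraction given a single random
#' substitution (those reads must be discarded by [count_guides()]).
#'
#' @param params A [screen_sim_params()].
#' @param samples Named character vector mapping sample name to pool
#'   (`"low"`/`"high"`), e.g. `c(low_1 = "low", high_1 = "high")`.
#' @param out_dir Directory for the FASTQ files.
#' @return List with `fastqs` (named paths), `counts` (drawn ground-truth
#'   guide x sample matrix) and `n_mutated` (per sample).
#' @export
sim_screen_fastq <- function(params,
                             samples = c(low_1 = "low", high_1 = "high"),
                             out_dir = tempfile("screen_")) {
  stopifnot(inherits(params, "screen_sim_params"))
  if (is.null(names(samples)))
    stopf("`samples` must be named (sample name -> pool)")
  if (!all(samples %in% c("low", "high")))
    stopf("pool labels must be 'low' or 'high'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lib <- params$library
  with_seed(params$seed, {
    counts <- vapply(unname(samples), function(pool)
      .draw_screen_counts(params, pool == params$enriched_pool),
      integer(nrow(lib)))
    dimnames(counts) <- list(lib$guide_id, names(samples))
    prefix <- if (params$guide_offset > 0)
      random_dna(1, params$guide_offset) else ""
    suffix_len <- params$read_length - params$guide_offset - 20L
    suffix <- if (suffix_len > 0) random_dna(1, suffix_len) else ""
    fastqs <- character(length(samples))
    names(fastqs) <- names(samples)
    n_mut <- setNames(integer(length(samples)), names(samples))
    for (s in names(samples)) {
      reads <- rep(lib$sequence, counts[, s])
      n_reads <- length(reads)
      k <- round(params$mutation_fraction * n_reads)
      if (k > 0) {
        pick <- sample.int(n_reads, k)
        pos <- sample.int(20L, k, replace = TRUE)
        for (j in seq_len(k)) {
          i <- pick[j]
          old <- substr(reads[i], pos[j], pos[j])
          new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
          substr(reads[i], pos[j], pos[j]) <- new
        }
        n_mut[s] <- k
      }
      full <- paste0(prefix, reads, suffix)
      dna <- Biostrings::DNAStringSet(full)
      names(dna) <- sprintf("%s_read%07d", s, seq_len(n_reads))
      path <- file.path(out_dir, paste0(s, ".fastq"))
      qual <- Biostrings::BStringSet(rep(strrep("?", params$read_length),
                                         n_reads))  # constant Q30
      Biostrings::writeXStringSet(dna, path, format = "fastq",
                                  qualities = qual)
      fastqs[s] <- path
    }
    list(fastqs = fastqs, counts = counts, n_mutated = n_mut)
  })
}
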