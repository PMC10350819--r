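#' Validate an sgRNA library
#'
#' Sequences are canonicalized to uppercase; duplicates (after
#' canonicalization), non-ACGT characters and wrong lengths are errors that
#' name the offending guide ids. Non-targeting guides carry the gene label
#' `"NON_TARGETING"`.
#'
#' @param tab Data frame with columns `guide_id, gene, sequence`.
#' @return The validated table with class `guide_library`.
#' @export
guide_library <- function(tab) {
  need <- c("guide_id", "gene", "sequence")
  if (!all(need %in% names(tab)))
    stopf("guide library must have columns: %s", paste(need, collapse = ", "))
  tab$sequence <- toupper(tab$sequence)
  bad_len <- nchar(tab$sequence) != 20L
  if (any(bad_len))
    stopf("guides not 20 nt: %s",
          paste(head(tab$guide_id[bad_len], 5), collapse = ", "))
  bad_chr <- grepl("[^ACGT]", tab$sequence)
  if (any(bad_chr))
    stopf("non-ACGT sequences: %s",
          paste(head(tab$guide_id[bad_chr], 5), collapse = ", "))
  dup <- duplicated(tab$sequence) | duplicated(tab$sequence, fromLast = TRUE)
  if (any(dup))
    stopf("duplicate sequences shared by guides: %s",
          paste(head(tab$guide_id[dup], 10), collapse = ", "))
  if (anyDuplicated(tab$guide_id))
    stopf("duplicate guide ids in library")
  class(tab) <- unique(c("guide_library", class(tab)))
  tab
}

#' Load an sgRNA library from a three-column TSV
#'
#' @param path TSV with columns `guide_id, gene, sequence` (header
#'   optional; detected from the first line).
#' @return A [guide_library()].
#' @export
load_guide_library <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("guide_id", first, fixed = TRUE)
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(tab) != 3L) stopf("library TSV must have three columns")
    names(tab) <- c("guide_id", "gene", "sequence")
  }
  guide_library(tab)
}

#' Count exact 20-mer guide matches in a FASTQ file
#'
#' Each read's 20-mer at `guide_offset` (0-based) is looked up against the
#' library by exact match; hits increment that guide, everything else --
#' including reads too short to contain the 20-mer and reads with any
#' substitution inside it -- is discarded and tallied. Optionally a
#' plus/minus 1-nt offset scan rescues reads whose cassette slipped by one
#' base (off by default). Counting is order-independent and deterministic,
#' and `matched + discarded` always equals the number of reads processed.
#'
#' @param fastq Path to a FASTQ(.gz) file.
#' @param library A [guide_library()].
#' @param guide_offset 0-based position of the guide within the read.
#' @param offset_scan Also try offsets `guide_offset - 1` and
#'   `guide_offset + 1` for otherwise unmatched reads.
#' @return List with `counts` (named integer vector over all library
#'   guides), `matched`, `discarded`, `total`.
#' @export
count_guides <- function(fastq, library, guide_offset = 0L,
                         offset_scan = FALSE) {
  stopifnot(inherits(library, "guide_library"))
  assert_scalar_number(guide_offset, "guide_offset", lower = 0,
                       integer = TRUE)
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  total <- length(reads)
  counts <- setNames(integer(nrow(library)), library$guide_id)
  offsets <- if (offset_scan)
    unique(c(guide_offset, max(0L, guide_offset - 1L), guide_offset + 1L))
  else guide_offset
  unmatched <- toupper(reads)
  for (off in offsets) {
    if (!length(unmatched)) break
    long_enough <- nchar(unmatched) >= off + 20L
    kmer <- substr(unmatched[long_enough], off + 1L, off + 20L)
    idx <- match(kmer, library$sequence)
    hit <- !is.na(idx)
    if (any(hit)) {
      tab <- tabulate(idx[hit], nbins = nrow(library))
      counts <- counts + tab
    }
    unmatched <- c(unmatched[!long_enough], unmatched[long_enough][!hit])
  }
  matched <- sum(counts)
  list(counts = counts, matched = matched,
       discarded = total - matched, total = total)
}

#' Build a guide x sample count table from FASTQ files
#'
#' @param fastqs Named character vector of FASTQ paths (names become
#'   sample names).
#' @param library A [guide_library()].
#' @inheritParams count_guides
#' @return A `count_table`: integer matrix (guides x samples) with
#'   attributes `matched`, `discarded`, `total` (per sample) and `library`.
#' @export
screen_count_table <- function(fastqs, library, guide_offset = 0L,
                               offset_scan = FALSE) {
  if (is.null(names(fastqs)) || any(names(fastqs) == ""))
    stopf("`fastqs` must be a named vector (names = sample names)")
  cols <- lapply(fastqs, count_guides, library = library,
                 guide_offset = guide_offset, offset_scan = offset_scan)
  mat <- vapply(cols, `[[`, integer(nrow(library)), "counts")
  dimnames(mat) <- list(library$guide_id, names(fastqs))
  structure(mat,
            matched = vapply(cols, `[[`, numeric(1), "matched"),
            discarded = vapply(cols, `[[`, numeric(1), "discarded"),
            total = vapply(cols, `[[`, numeric(1), "total"),
            library = library,
            class = c("count_table", "matrix", "array"))
}

#' Write a count table in a MAGeCK-compatible layout
#'
#' Columns `sgRNA, gene, <sample...>`, tab-separated, for users who want to
#' run the original ranking tool on counts produced here.
#'
#' @param table A `count_table` from [screen_count_table()].
#' @param path Output TSV path.
#' @export
write_count_table <- function(table, path) {
  lib <- attr(table, "library")
  out <- data.frame(sgRNA = rownames(table),
                    gene = lib$gene[match(rownames(table), lib$guide_id)],
                    as.data.frame(unclass(table)[, , drop = FALSE]),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scale counts to reads per million matched reads
#'
#' @param table A `count_table` (or plain matrix of non-negative counts).
#' @return Matrix of the same shape with each column summing to `1e6`.
#' @export
normalize_counts <- function(table) {
  mat <- unclass(table)
  totals <- colSums(mat)
  if (any(totals == 0))
    stopf("sample(s) with zero matched reads: %s",
          paste(colnames(mat)[totals == 0], collapse = ", "))
  sweep(mat, 2, totals, "/") * 1e6
}

#' Per-guide log2 fold change between sorted pools
#'
#' `log2((mean(low) + c) / (mean(high) + c))` on normalized counts, with
#' pseudocount `c` (default 0.5) so zero counts stay finite. Positive values
#' mark candidate positive regulators of the reporter (guides enriched in
#' the low-fluorescence pool).
#'
#' @param norm Normalized count matrix from [normalize_counts()].
#' @param low_samples,high_samples Column names of the low- and
#'   high-fluorescence pools.
#' @param pseudocount Added to both means (default 0.5).
#' @return Named numeric vector of per-guide log2 fold changes.
#' @export
guide_lfc <- function(norm, low_samples, high_samples, pseudocount = 0.5) {
  missing_cols <- setdiff(c(low_samples, high_samples), colnames(norm))
  if (length(missing_cols))
    stopf("samples not in matrix: %s", paste(missing_cols, collapse = ", "))
  lo <- rowMeans(norm[, low_samples, drop = FALSE])
  hi <- rowMeans(norm[, high_samples, drop = FALSE])
  log2((lo + pseudocount) / (hi + pseudocount))
}

#' Gene-level enrichment against the non-targeting null
#'
#' Guide log2 fold changes are standardized against the non-targeting-guide
#' distribution, `z = (lfc - median_NT) / MAD_NT`; a gene's score is the
#' mean z of its guides. Significance comes from a permutation null built by
#' drawing size-matched random sets of targeting guides, two-sided with the
#' add-one correction, followed by Benjamini-Hochberg adjustment across
#' genes. With fewer than 10 non-targeting guides the null falls back to all
#' guides (with a warning). This scoring is deliberately simple plumbing,
#' not a reimplementation of robust rank aggregation.
#'
#' @param lfc Named per-guide log2 fold changes from [guide_lfc()].
#' @param library The [guide_library()] mapping guides to genes.
#' @param n_perm Permutation draws per guide-set size (default `1e4`).
#' @param seed Integer seed for the permutation draws.
#' @param nontargeting_label Gene label marking control guides.
#' @return An `enrichment_table`: list with `guides` (guide_id, gene, lfc,
#'   z) and `genes` (gene, n_guides, score, p, q) data frames.
#' @export
gene_score <- function(lfc, library, n_perm = 10000L, seed = 1L,
                       nontargeting_label = "NON_TARGETING") {
  stopifnot(inherits(library, "guide_library"))
  lib <- library[match(names(lfc), library$guide_id), ]
  if (any(is.na(lib$guide_id)))
    stopf("lfc names must all be library guide ids")
  is_nt <- lib$gene == nontargeting_label
  null_lfc <- lfc[is_nt]
  if (sum(is_nt) < 10L) {
    warnf("only %d non-targeting guides; falling back to all-guide null",
          sum(is_nt))
    null_lfc <- lfc
  }
  ctr <- median(null_lfc)
  scale <- mad(null_lfc)
  if (scale == 0) scale <- sd(null_lfc)
  # fully degenerate null (all control lfc identical): unit scale keeps
  # z finite; identical-everything then gives z = 0 and p = 1
  if (!is.finite(scale) || scale == 0) scale <- 1
  z <- (lfc - ctr) / scale
  guides <- data.frame(guide_id = lib$guide_id, gene = lib$gene,
                       lfc = as.numeric(lfc), z = as.numeric(z))
  targ <- guides[!is_nt, ]
  score <- tapply(targ$z, targ$gene, mean)
  sizes <- tapply(targ$z, targ$gene, length)
  genes <- data.frame(gene = names(score),
                      n_guides = as.integer(sizes),
                      score = as.numeric(score))
  genes$p <- NA_real_
  with_seed(seed, {
    for (s in sort(unique(genes$n_guides))) {
      null <- colMeans(matrix(sample(targ$z, s * n_perm, replace = TRUE),
                              nrow = s))
      sel <- genes$n_guides == s
      genes$p[sel] <- vapply(genes$score[sel], function(g)
        (sum(abs(null) >= abs(g)) + 1) / (n_perm + 1), numeric(1))
    }
  })
  genes$q <- p.adjust(genes$p, method = "BH")
  genes <- genes[order(genes$p, -abs(genes$score)), ]
  rownames(genes) <- NULL
  structure(list(guides = guides, genes = genes,
                 n_perm = n_perm, nontargeting_label = nontargeting_label),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("<enrichment_table> %d genes, %d guides (null: %s)\n",
              nrow(x$genes), nrow(x$guides), x$nontargeting_label))
  print(head(x$genes, 10))
  invisible(x)
}
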