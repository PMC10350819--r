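small_lib <- function(seed = 3) sim_guide_library(6, 4, 12, seed = seed)

test_that("guide library validation canonicalizes and reports defects", {
  tab <- data.frame(guide_id = c("g1", "g2", "g3"),
                    gene = c("A", "A", "NON_TARGETING"),
                    sequence = c("acgtacgtacgtacgtacgt",
                                 "AAAACCCCGGGGTTTTACGT",
                                 "TTTTACGTACGTACGTACGA"))
  lib <- guide_library(tab)
  expect_equal(lib$sequence[1], "ACGTACGTACGTACGTACGT")

  dup <- tab; dup$sequence[2] <- tab$sequence[1]
  expect_error(guide_library(dup), "g1.*g2|duplicate")
  short <- tab; short$sequence[1] <- "ACGT"
  expect_error(guide_library(short), "20 nt")
  bad <- tab; bad$sequence[1] <- "NCGTACGTACGTACGTACGT"
  expect_error(guide_library(bad), "non-ACGT")
})

test_that("library TSV round trip with and without header", {
  lib <- small_lib()
  path <- tempfile(fileext = ".tsv")
  write.table(as.data.frame(lib)[c("guide_id", "gene", "sequence")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(load_guide_library(path)), nrow(lib))
  write.table(as.data.frame(lib)[c("guide_id", "gene", "sequence")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_equal(load_guide_library(path)$sequence, lib$sequence)
})

test_that("count_guides matches exact 20-mers and discards the rest", {
  lib <- small_lib()
  fq <- tempfile(fileext = ".fastq")
  g1 <- lib$sequence[1]
  mut <- g1; substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                            substr(g1, 10, 10))[1]
  reads <- c(paste0(g1, "A"),     # guide + 1 extra base: counted
             mut,                 # single substitution: discarded
             "ACGTACG")           # truncated: discarded, not fatal
  writeLines(as.vector(rbind(paste0("@r", seq_along(reads)), reads, "+",
                             strrep("I", nchar(reads)))), fq)
  res <- count_guides(fq, lib)
  expect_equal(unname(res$counts[lib$guide_id[1]]), 1L)
  expect_equal(res$matched, 1L)
  expect_equal(res$discarded, 2L)
  expect_equal(res$matched + res$discarded, res$total)
})

test_that("offset scan rescues reads shifted by one base when enabled", {
  lib <- small_lib()
  fq <- tempfile(fileext = ".fastq")
  shifted <- paste0("T", lib$sequence[2], "A")
  writeLines(c("@r1", shifted, "+", strrep("I", nchar(shifted))), fq)
  strict <- count_guides(fq, lib, guide_offset = 0L)
  expect_equal(strict$matched, 0L)
  scan <- count_guides(fq, lib, guide_offset = 0L, offset_scan = TRUE)
  expect_equal(unname(scan$counts[lib$guide_id[2]]), 1L)
})

test_that("simulated screen round trip recovers drawn counts bit-exactly", {
  lib <- small_lib()
  sp <- screen_sim_params(lib, enriched_guides = lib$guide_id[1:4],
                          effect = 8, n_reads = 4000, seed = 6)
  sim <- sim_screen_fastq(sp, samples = c(low_1 = "low", high_1 = "high"))
  tab <- screen_count_table(sim$fastqs, lib)
  expect_identical(unclass(tab)[, ], sim$counts)
  expect_true(all(attr(tab, "matched") + attr(tab, "discarded") ==
                    attr(tab, "total")))
  expect_true(all(attr(tab, "discarded") == 0))
})

test_that("mutated reads are discarded per the exact-match rule", {
  lib <- small_lib()
  sp <- screen_sim_params(lib, n_reads = 1500, mutation_fraction = 1,
                          seed = 7)
  sim <- sim_screen_fastq(sp, samples = c(low_1 = "low"))
  res <- count_guides(sim$fastqs[["low_1"]], lib)
  expect_equal(res$matched, 0L)
  expect_equal(res$discarded, res$total)
  expect_gt(res$total, 0L)

  # partial mutation: conservation still holds and matched = total - mutated
  sp2 <- screen_sim_params(lib, n_reads = 1500, mutation_fraction = 0.3,
                           seed = 8)
  sim2 <- sim_screen_fastq(sp2, samples = c(low_1 = "low"))
  res2 <- count_guides(sim2$fastqs[["low_1"]], lib)
  expect_equal(res2$discarded, unname(sim2$n_mutated["low_1"]))
  expect_equal(res2$matched + res2$discarded, res2$total)
})

test_that("counting is order-independent over reads", {
  lib <- small_lib()
  sp <- screen_sim_params(lib, n_reads = 800, seed = 10)
  sim <- sim_screen_fastq(sp, samples = c(low_1 = "low"))
  lines <- readLines(sim$fastqs[["low_1"]])
  recs <- split(lines, rep(seq_len(length(lines) / 4), each = 4))
  shuffled <- tempfile(fileext = ".fastq")
  set.seed(1); writeLines(unlist(recs[sample(length(recs))]), shuffled)
  expect_identical(count_guides(shuffled, lib)$counts,
                   count_guides(sim$fastqs[["low_1"]], lib)$counts)
})

test_that("normalize_counts scales each sample to one million matched reads", {
  mat <- matrix(c(10L, 30L, 60L, 5L, 5L, 90L), ncol = 2,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  norm <- normalize_counts(mat)
  expect_equal(unname(colSums(norm)), c(1e6, 1e6))
  expect_equal(normalize_counts(mat * 2L), norm)   # depth invariance
  solo <- matrix(5L, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(as.numeric(normalize_counts(solo)), 1e6)
  zero <- matrix(0L, 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_error(normalize_counts(zero), "zero matched")
})

test_that("guide_lfc uses the pseudocount contract", {
  norm <- matrix(c(200, 100, 0, 100, 100, 0), ncol = 2,
                 dimnames = list(c("g1", "g2", "g3"), c("low", "high")))
  lfc <- guide_lfc(norm, "low", "high", pseudocount = 0.5)
  expect_equal(unname(lfc["g2"]), 0)
  expect_equal(unname(lfc["g1"]), log2(200.5 / 100.5))
  expect_true(is.finite(lfc["g3"]))
  expect_equal(unname(lfc["g3"]), 0)
  expect_error(guide_lfc(norm, "low", "nope"), "nope")
})

test_that("gene_score standardizes against the non-targeting null", {
  lib <- small_lib()
  # all guides identical lfc -> all z = 0, all p = 1
  lfc <- setNames(rep(0.7, nrow(lib)), lib$guide_id)
  sc <- gene_score(lfc, lib, n_perm = 200, seed = 1)
  expect_true(all(sc$guides$z == 0))
  expect_true(all(sc$genes$p == 1))

  # too few non-targeting guides -> warn and fall back to all-guide null
  tiny <- guide_library(as.data.frame(lib)[lib$gene != "NON_TARGETING" |
                                             seq_len(nrow(lib)) <= 2, ])
  lfc2 <- setNames(rnorm(nrow(tiny)), tiny$guide_id)
  expect_warning(gene_score(lfc2, tiny, n_perm = 100), "falling back")
})

test_that("spiked enrichment is recovered and the null stays calibrated", {
  lib <- sim_guide_library(60, 4, 40, seed = 12)
  spiked_genes <- sprintf("GENE%04d", 1:4)
  sp <- screen_sim_params(
    lib, enriched_guides = lib$guide_id[lib$gene %in% spiked_genes],
    effect = 8, n_reads = 6e4, dispersion = 0.1, seed = 13)
  sim <- sim_screen_fastq(sp, samples = c(low_1 = "low", low_2 = "low",
                                          high_1 = "high", high_2 = "high"))
  tab <- screen_count_table(sim$fastqs, lib)
  lfc <- guide_lfc(normalize_counts(tab), c("low_1", "low_2"),
                   c("high_1", "high_2"))
  sc <- gene_score(lfc, lib, n_perm = 2000, seed = 14)
  hits <- sc$genes$gene[sc$genes$q < 0.05]
  expect_true(all(spiked_genes %in% hits))
  # spiked guides enrich in the low pool: positive scores
  expect_true(all(sc$genes$score[sc$genes$gene %in% spiked_genes] > 0))
})

test_that("count table export is MAGeCK-compatible", {
  lib <- small_lib()
  sp <- screen_sim_params(lib, n_reads = 1000, seed = 15)
  sim <- sim_screen_fastq(sp, samples = c(low_1 = "low", high_1 = "high"))
  tab <- screen_count_table(sim$fastqs, lib)
  path <- tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  back <- read.delim(path)
  expect_equal(names(back)[1:2], c("sgRNA", "gene"))
  expect_equal(back$low_1, unname(unclass(tab)[, "low_1"]))
})
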