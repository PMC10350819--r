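# independent oracles used to freeze expected values; these deliberately
# avoid the code paths they check

# exhaustive two-group permutation p-value by direct enumeration
oracle_perm_p <- function(a, b) {
  pool <- c(a, b)
  idx <- utils::combn(length(pool), length(a), simplify = FALSE)
  effs <- vapply(idx, function(i) mean(pool[i]) - mean(pool[-i]), numeric(1))
  obs <- mean(a) - mean(b)
  (sum(abs(effs) >= abs(obs) - 1e-12) + 1) / (length(effs) + 1)
}

# brute-force G4 presence: for every substring of length <= max_len, try all
# loop-length partitions of the remainder around four equal G-tracts
oracle_g4_spans <- function(seq_chr, min_tract = 2, max_len = 30) {
  s <- chartr("U", "T", toupper(seq_chr))
  n <- nchar(s)
  spans <- list()
  for (start in seq_len(n)) {
    len_max <- min(max_len, n - start + 1)
    if (len_max < 4 * min_tract) next
    for (len in (4 * min_tract):len_max) {
      sub <- substr(s, start, start + len - 1)
      g_max <- len %/% 4
      if (g_max < min_tract) next
      for (g in min_tract:g_max) {
        rest <- len - 4 * g
        for (l1 in 0:rest) for (l2 in 0:(rest - l1)) {
          l3 <- rest - l1 - l2
          pat <- sprintf("^G{%d}.{%d}G{%d}.{%d}G{%d}.{%d}G{%d}$",
                         g, l1, g, l2, g, l3, g)
          if (grepl(pat, sub)) {
            spans[[length(spans) + 1L]] <-
              c(start - 1L, start - 1L + len, g)
          }
        }
      }
    }
  }
  if (!length(spans)) return(matrix(integer(), ncol = 3))
  unique(do.call(rbind, spans))
}

# one SAM record line for a synthetic spliced read
sam_line <- function(qname, chrom, pos1, cigar, flag = 0L, mapq = 60L,
                     seq = "*") {
  paste(qname, flag, chrom, pos1, mapq, cigar, "*", 0L, 0L, seq, "*",
        sep = "\t")
}

write_test_sam <- function(records, chrom = "synth1", ln = 5000L) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", chrom, ln),
               records), path)
  path
}
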