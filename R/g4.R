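#' Scan a sequence for G-quadruplex-forming motifs (QGRS-style)
#'
#' Enumerates candidate quadruplex-forming G-rich sequences: four G-tracts
#' of equal length `g >= min_tract` within a window of at most `max_len`
#' nt, separated by loops of length 0 to `max_loop` (loops may themselves
#' contain G). `U` is treated as `T`; `N` is never part of a tract.
#' Overlapping candidates are resolved to the highest-scoring
#' non-overlapping set (greedy by score, then leftmost, then shortest).
#'
#' Scoring is QGRS-style, not a reproduction of any published score: it
#' rewards longer tracts, compactness and loop evenness,
#' `score = 40 (g - 2) + (max_len - span) - (max(loops) - min(loops))`,
#' so a candidate built on longer G-tracts always outranks one on shorter
#' tracts. The formula is also recorded in the `scoring` attribute of the
#' result.
#'
#' @param sequence Character scalar over `A,C,G,T,U,N` (case-insensitive),
#'   or a `Biostrings` XString.
#' @param min_tract Minimum G-tract length (default 2).
#' @param max_len Maximum motif span in nt (default 30).
#' @param max_loop Maximum loop length (default 36, effectively bounded by
#'   `max_len`).
#' @param all_candidates Return every candidate instead of the
#'   non-overlapping set.
#' @return Data frame with columns `start`, `end` (0-based half-open),
#'   `tract_length`, `tract_starts` (comma-separated, 0-based), `loops`
#'   (comma-separated) and `score`; zero rows when no motif exists.
#' @export
scan_g4 <- function(sequence, min_tract = 2L, max_len = 30L,
                    max_loop = 36L, all_candidates = FALSE) {
  if (!is.character(sequence)) sequence <- as.character(sequence)
  assert_scalar_number(min_tract, "min_tract", lower = 1, integer = TRUE)
  assert_scalar_number(max_len, "max_len", lower = 4, integer = TRUE)
  seq_chr <- chartr("u", "t", tolower(sequence))
  if (grepl("[^acgtn]", seq_chr))
    stopf("sequence must be over {A,C,G,T,U,N}")
  chars <- strsplit(seq_chr, "")[[1]]
  n <- length(chars)
  is_g <- chars == "g"
  # run_len[i]: length of the G-run starting at i (0 when chars[i] != G)
  run_len <- integer(n)
  i <- n
  while (i >= 1) {
    if (is_g[i]) run_len[i] <- if (i < n) run_len[i + 1] + 1L else 1L
    i <- i - 1L
  }
  cand <- list()
  max_g <- max(c(run_len, 0L))
  for (g in seq_len(max_g)) {
    if (g < min_tract) next
    starts <- which(run_len >= g)
    for (s1 in starts) {
      if (s1 + 4L * g - 1L > min(n, s1 + max_len - 1L)) next
      lim <- s1 + max_len - 1L
      s2s <- starts[starts >= s1 + g & starts <= lim - 3L * g + 1L &
                    starts - (s1 + g) <= max_loop]
      for (s2 in s2s) {
        s3s <- starts[starts >= s2 + g & starts <= lim - 2L * g + 1L &
                      starts - (s2 + g) <= max_loop]
        for (s3 in s3s) {
          s4s <- starts[starts >= s3 + g & starts <= lim - g + 1L &
                        starts - (s3 + g) <= max_loop]
          for (s4 in s4s) {
            loops <- c(s2 - (s1 + g), s3 - (s2 + g), s4 - (s3 + g))
            span <- s4 + g - s1
            cand[[length(cand) + 1L]] <- data.frame(
              start = s1 - 1L, end = s4 + g - 1L, tract_length = g,
              tract_starts = paste(c(s1, s2, s3, s4) - 1L, collapse = ","),
              loops = paste(loops, collapse = ","),
              score = 40L * (g - 2L) + (max_len - span) -
                (max(loops) - min(loops)))
          }
        }
      }
    }
  }
  empty <- data.frame(start = integer(), end = integer(),
                      tract_length = integer(), tract_starts = character(),
                      loops = character(), score = integer())
  out <- if (length(cand)) do.call(rbind, cand) else empty
  if (!all_candidates && nrow(out)) {
    out <- out[order(-out$score, out$start, out$end - out$start), ]
    keep <- logical(nrow(out))
    taken <- cbind(integer(0), integer(0))
    for (k in seq_len(nrow(out))) {
      s <- out$start[k]; e <- out$end[k]
      if (!nrow(taken) || all(e <= taken[, 1] | s >= taken[, 2])) {
        keep[k] <- TRUE
        taken <- rbind(taken, c(s, e))
      }
    }
    out <- out[keep, ]
    out <- out[order(out$start), ]
  }
  rownames(out) <- NULL
  attr(out, "scoring") <-
    "score = 40*(tract_len - 2) + (max_len - span) - (max(loops) - min(loops))"
  out
}

#' Write G4 motifs as TSV
#'
#' @param motifs Output of [scan_g4()].
#' @param path Output TSV path; the scoring variant is recorded in a
#'   comment header line.
#' @return Invisibly, `path`.
#' @export
write_g4_table <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", attr(motifs, "scoring") %||% "QGRS-style scoring"),
             con)
  write.table(motifs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
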