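# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (integer && x != round(x))
    stopf("`%s` must be an integer, got %s", name, format(x))
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", name,
          format(lower), format(upper), format(x))
  invisible(x)
}

# run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched so seeded generators compose deterministically
with_seed <- function(seed, expr) {
  assert_scalar_number(seed, "seed", integer = TRUE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""),
    character(1))
}
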