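#' Read a qPCR cycle-threshold table
#'
#' Expects CSV columns `sample_id, condition, amplicon, replicate, ct`
#' (technical replicate index and Ct in cycles).
#'
#' @param path CSV file path.
#' @return A validated `ct_table` data frame.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ct_table(tab)
}

#' Validate a Ct table
#'
#' @param tab Data frame with columns `sample_id, condition, amplicon,
#'   replicate, ct`.
#' @return The table with class `ct_table` prepended.
#' @export
ct_table <- function(tab) {
  need <- c("sample_id", "condition", "amplicon", "replicate", "ct")
  if (!all(need %in% names(tab)))
    stopf("Ct table must have columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0))
    stopf("all Ct values must be finite and > 0")
  class(tab) <- unique(c("ct_table", class(tab)))
  tab
}

#' Simulate a qPCR Ct table
#'
#' Under perfect-doubling amplification (efficiency 2, configurable) a
#' template at relative expression `e` crosses threshold at
#' `Ct = ct_ref - log_eff(e)` cycles; technical-replicate noise is Gaussian
#' on the Ct scale. A reference amplicon (loading control, expression 1 by
#' convention) should be part of `true_rel_expr`.
#'
#' @param true_rel_expr Data frame with columns `sample_id, condition,
#'   amplicon, expression` (> 0), one row per sample x amplicon.
#' @param ct_ref Ct of a unit-expression template (cycles).
#' @param noise_sd Technical-replicate Ct standard deviation.
#' @param n_tech Technical replicates per well group (default 4).
#' @param efficiency Amplification efficiency (fold per cycle).
#' @param seed Integer seed.
#' @return A `ct_table` with a `truth` attribute (the input expressions).
#' @export
sim_ct_table <- function(true_rel_expr, ct_ref = 20, noise_sd = 0,
                         n_tech = 4L, efficiency = 2, seed = 1L) {
  need <- c("sample_id", "amplicon", "expression")
  if (!all(need %in% names(true_rel_expr)))
    stopf("true_rel_expr must have columns: %s", paste(need, collapse = ", "))
  if (any(true_rel_expr$expression <= 0))
    stopf("expressions must be > 0")
  assert_scalar_number(ct_ref, "ct_ref", lower = 1e-9)
  assert_scalar_number(efficiency, "efficiency", lower = 1 + 1e-9)
  assert_scalar_number(n_tech, "n_tech", lower = 1, integer = TRUE)
  if (is.null(true_rel_expr$condition)) true_rel_expr$condition <- "NA"
  rows <- true_rel_expr[rep(seq_len(nrow(true_rel_expr)), each = n_tech), ]
  rows$replicate <- rep(seq_len(n_tech), nrow(true_rel_expr))
  ct0 <- ct_ref - log(rows$expression, base = efficiency)
  rows$ct <- with_seed(seed, ct0 + rnorm(nrow(rows), 0, noise_sd))
  if (any(rows$ct <= 0))
    stopf("simulated Ct <= 0; raise ct_ref or lower expression/noise")
  out <- ct_table(rows[c("sample_id", "condition", "amplicon",
                         "replicate", "ct")])
  rownames(out) <- NULL
  attr(out, "truth") <- true_rel_expr
  out
}

#' Reference-normalized relative expression from Ct values
#'
#' Technical replicates are collapsed by the arithmetic mean of Ct
#' (optionally dropping wells more than 0.5 cycles from the replicate
#' median), then `value = efficiency^(Ct_ref - Ct_target)` per sample and
#' amplicon. Adding a constant to every Ct within a sample (a plate offset)
#' leaves the result unchanged.
#'
#' @param ct A `ct_table`.
#' @param reference_amplicon Name of the loading-control amplicon (e.g.
#'   18S rRNA), required in every sample.
#' @param efficiency Amplification efficiency (default 2, perfect doubling).
#' @param drop_outliers Drop technical replicates more than
#'   `outlier_cycles` from the within-group median Ct (default off).
#' @param outlier_cycles Outlier threshold in cycles (default 0.5).
#' @return Data frame `sample_id, condition, amplicon, value` for the
#'   non-reference amplicons.
#' @export
relative_expression <- function(ct, reference_amplicon,
                                efficiency = 2, drop_outliers = FALSE,
                                outlier_cycles = 0.5) {
  ct <- ct_table(as.data.frame(ct))
  collapse <- function(d) {
    x <- d$ct
    if (drop_outliers && length(x) > 2) {
      keep <- abs(x - median(x)) <= outlier_cycles
      if (any(keep)) x <- x[keep]
    }
    mean(x)
  }
  key <- interaction(ct$sample_id, ct$amplicon, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ct, key), function(d)
    data.frame(sample_id = d$sample_id[1], condition = d$condition[1],
               amplicon = d$amplicon[1], mean_ct = collapse(d))))
  out <- NULL
  for (s in unique(agg$sample_id)) {
    a <- agg[agg$sample_id == s, ]
    ref <- a$mean_ct[a$amplicon == reference_amplicon]
    if (!length(ref))
      stopf("sample '%s' lacks reference amplicon '%s'", s,
            reference_amplicon)
    tgt <- a[a$amplicon != reference_amplicon, ]
    tgt$value <- efficiency^(ref - tgt$mean_ct)
    out <- rbind(out, tgt[c("sample_id", "condition", "amplicon", "value")])
  }
  rownames(out) <- NULL
  out
}

#' Per-condition fold change of relative expression
#'
#' Each condition's mean value (per amplicon) divided by the baseline
#' condition's mean.
#'
#' @param expr Output of [relative_expression()].
#' @param baseline_condition Condition serving as denominator.
#' @return Data frame `condition, amplicon, fold_change`.
#' @export
fold_change <- function(expr, baseline_condition) {
  if (!baseline_condition %in% expr$condition)
    stopf("baseline condition '%s' absent from table", baseline_condition)
  out <- NULL
  for (amp in unique(expr$amplicon)) {
    e <- expr[expr$amplicon == amp, ]
    base <- mean(e$value[e$condition == baseline_condition])
    for (cond in unique(e$condition)) {
      out <- rbind(out, data.frame(
        condition = cond, amplicon = amp,
        fold_change = mean(e$value[e$condition == cond]) / base))
    }
  }
  rownames(out) <- NULL
  out
}

#' Relative poison-exon inclusion from exon-specific amplicons
#'
#' The ratio of the PE amplicon's relative expression to that of one or
#' more constitutive-exon amplicons. With several constitutive amplicons the
#' denominator is their geometric mean (default), arithmetic mean, or a
#' single named amplicon; the mode is an explicit parameter because both
#' conventions occur in practice.
#'
#' @param expr Output of [relative_expression()].
#' @param pe_amplicon Name of the PE (e.g. cassette-exon) amplicon.
#' @param constitutive_amplicons Character vector of constitutive amplicons.
#' @param mode `"geometric_mean"`, `"arithmetic_mean"` or `"single"`
#'   (with exactly one constitutive amplicon).
#' @return Data frame `sample_id, condition, value, mode`; `value` is `NA`
#'   (flagged via `undefined`) when the denominator is zero or absent.
#' @export
pe_inclusion_ratio <- function(expr, pe_amplicon, constitutive_amplicons,
                               mode = c("geometric_mean",
                                        "arithmetic_mean", "single")) {
  mode <- match.arg(mode)
  if (mode == "single" && length(constitutive_amplicons) != 1L)
    stopf("mode 'single' requires exactly one constitutive amplicon")
  out <- NULL
  for (s in unique(expr$sample_id)) {
    e <- expr[expr$sample_id == s, ]
    pe <- e$value[e$amplicon == pe_amplicon]
    denom_vals <- vapply(constitutive_amplicons, function(a) {
      v <- e$value[e$amplicon == a]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
    denom <- switch(mode,
      single = denom_vals[1],
      geometric_mean = exp(mean(log(denom_vals))),
      arithmetic_mean = mean(denom_vals))
    value <- if (!length(pe) || !is.finite(denom) || denom == 0)
      NA_real_ else pe[1] / denom
    out <- rbind(out, data.frame(
      sample_id = s, condition = e$condition[1], value = value,
      mode = mode, undefined = is.na(value)))
  }
  rownames(out) <- NULL
  out
}
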