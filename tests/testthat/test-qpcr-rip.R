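make_expr <- function(expression, amplicons = names(expression),
                      sample = "s1", condition = "37C") {
  data.frame(sample_id = sample, condition = condition,
             amplicon = amplicons, expression = as.numeric(expression))
}

test_that("sim_ct_table encodes expression on the Ct scale", {
  # unit expression everywhere -> all Ct equal ct_ref
  tab <- sim_ct_table(make_expr(c(ref = 1, a = 1)), ct_ref = 20,
                      noise_sd = 0)
  expect_true(all(tab$ct == 20))
  # 4-fold expression -> Ct lower by 2 cycles
  tab <- sim_ct_table(make_expr(c(ref = 1, a = 4)), ct_ref = 20,
                      noise_sd = 0)
  expect_equal(unique(tab$ct[tab$amplicon == "a"]), 18)
  # expression 0.02 vs reference 1 -> delta-Ct = log2(50)
  tab <- sim_ct_table(make_expr(c(ref = 1, pe = 0.02)), noise_sd = 0)
  dct <- mean(tab$ct[tab$amplicon == "pe"]) -
    mean(tab$ct[tab$amplicon == "ref"])
  expect_equal(dct, log2(50))
  expect_equal(dct, 5.643856, tolerance = 1e-6)
  expect_error(sim_ct_table(make_expr(c(ref = 1, a = -1))), "> 0")
})

test_that("relative_expression collapses replicates and normalizes", {
  tab <- sim_ct_table(make_expr(c(ref = 1, a = 1, b = 0.25)), noise_sd = 0)
  rel <- relative_expression(tab, "ref")
  expect_equal(rel$value[rel$amplicon == "a"], 1)
  expect_equal(rel$value[rel$amplicon == "b"], 0.25)

  # recovery of 0.02 under technical noise collapsed over 4 replicates
  tab <- sim_ct_table(make_expr(c(ref = 1, pe = 0.02)), noise_sd = 0.05,
                      seed = 8)
  rel <- relative_expression(tab, "ref")
  expect_equal(rel$value[rel$amplicon == "pe"], 0.02, tolerance = 0.1)

  # plate offset cancellation: +3 cycles on every well changes nothing
  shifted <- tab; shifted$ct <- shifted$ct + 3
  expect_equal(relative_expression(ct_table(shifted), "ref")$value,
               rel$value)

  # missing reference names the sample
  expect_error(relative_expression(
    ct_table(tab[tab$amplicon != "ref", ]), "ref"), "s1")
})

test_that("technical-replicate outlier drop is opt-in", {
  tab <- sim_ct_table(make_expr(c(ref = 1, a = 1)), ct_ref = 20,
                      noise_sd = 0)
  tab$ct[tab$amplicon == "a" & tab$replicate == 4] <- 22  # aberrant well
  with_drop <- relative_expression(tab, "ref", drop_outliers = TRUE)
  without <- relative_expression(tab, "ref")
  expect_equal(with_drop$value, 1)
  expect_lt(without$value, 1)
})

test_that("fold_change compares condition means against baseline", {
  expr <- rbind(make_expr(c(ref = 1, a = 1), sample = "w1"),
                make_expr(c(ref = 1, a = 1), sample = "w2"),
                make_expr(c(ref = 1, a = 4), sample = "c1",
                          condition = "32C"),
                make_expr(c(ref = 1, a = 4), sample = "c2",
                          condition = "32C"))
  tab <- sim_ct_table(expr, noise_sd = 0)
  rel <- relative_expression(tab, "ref")
  fc <- fold_change(rel, "37C")
  expect_equal(fc$fold_change[fc$condition == "37C"], 1)
  expect_equal(fc$fold_change[fc$condition == "32C"], 4)
  expect_error(fold_change(rel, "42C"), "baseline")
})

test_that("pe_inclusion_ratio supports single and mean denominators", {
  expr <- data.frame(sample_id = "s1", condition = "37C",
                     amplicon = c("PE", "E3", "E45"),
                     value = c(0.02, 0.9, 1.1))
  single <- pe_inclusion_ratio(expr, "PE", "E3", mode = "single")
  expect_equal(single$value, 0.02 / 0.9)

  # frozen: geometric-mean denominator sqrt(0.99), ratio ~ 0.0201008
  geo <- pe_inclusion_ratio(expr, "PE", c("E3", "E45"),
                            mode = "geometric_mean")
  expect_equal(geo$value, 0.02 / sqrt(0.99))
  expect_equal(geo$value, 0.0201008, tolerance = 1e-5)

  # geometric mean of the two single-denominator ratios equals the
  # geometric-mean-denominator ratio
  r3 <- pe_inclusion_ratio(expr, "PE", "E3", mode = "single")$value
  r45 <- pe_inclusion_ratio(expr, "PE", "E45", mode = "single")$value
  expect_equal(geo$value, sqrt(r3 * r45))

  # modes agree when constitutive amplicons are equal
  eq <- data.frame(sample_id = "s1", condition = "37C",
                   amplicon = c("PE", "E3", "E45"), value = c(0.02, 1, 1))
  expect_equal(
    pe_inclusion_ratio(eq, "PE", c("E3", "E45"), "geometric_mean")$value,
    pe_inclusion_ratio(eq, "PE", c("E3", "E45"), "arithmetic_mean")$value)

  # absent denominator -> flagged undefined, not zero
  miss <- pe_inclusion_ratio(expr, "PE", "E99", mode = "single")
  expect_true(miss$undefined)
})

test_that("rip_fold_change cancels expression and pulldown confounds", {
  m37 <- rip_measurement("r1", "37C", 1, 2, 5, 1)
  # identical measurements -> 1
  m32 <- rip_measurement("r1", "32C", 1, 2, 5, 1)
  expect_equal(rip_fold_change(m37, m32), 1)
  # IP RNA doubles, all else equal -> 2
  m32b <- rip_measurement("r1", "32C", 1, 4, 5, 1)
  expect_equal(rip_fold_change(m37, m32b), 2)
  # IP RNA doubles AND pulldown efficiency doubles -> confound cancels to 1
  m32c <- rip_measurement("r1", "32C", 1, 4, 5, 2)
  expect_equal(rip_fold_change(m37, m32c), 1)
  # invariance to independent rescaling of RNA and protein units
  m37s <- rip_measurement("r1", "37C", 1 * 7, 2 * 7, 5 * 0.3, 1 * 0.3)
  m32s <- rip_measurement("r1", "32C", 1 * 7, 4 * 7, 5 * 0.3, 2 * 0.3)
  expect_equal(rip_fold_change(m37s, m32s), rip_fold_change(m37, m32c))
  # unpaired replicates refuse to combine
  m_other <- rip_measurement("r2", "32C", 1, 2, 5, 1)
  expect_error(rip_fold_change(m37, m_other), "replicate id")
  # nonpositive quantities rejected at construction
  expect_error(rip_measurement("r", "37C", 0, 1, 1, 1), "> 0")
})

test_that("rip_fold_change_table pairs temperatures per replicate", {
  tab <- data.frame(
    replicate = rep(c("r1", "r2"), each = 2),
    temperature = rep(c("37C", "32C"), 2),
    target_input_rna = c(1, 1, 1, 2),
    target_ip_rna = c(2, 4, 2, 4),
    protein_input = c(5, 5, 5, 5),
    protein_ip = c(1, 1, 1, 1))
  csv <- tempfile(fileext = ".csv")
  write.csv(tab, csv, row.names = FALSE)
  res <- rip_fold_change_table(csv)
  expect_equal(res$fold_change[res$replicate == "r1"], 2)
  expect_equal(res$fold_change[res$replicate == "r2"], 1)
})
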