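test_that("transition amounts follow stable-isotope-dilution arithmetic", {
  # HPLC setup: 500 fmol IS on 33.3 ug protein at unit area ratio
  q <- quantify_transitions(data.frame(
    area_analyte = 1e5, area_is = 1e5, is_amount_fmol = 500,
    protein_injected_ug = 33.3))
  expect_equal(q$amount, 500 / 33.3, tolerance = 1e-12)
  expect_equal(round(q$amount, 3), 15.015)
  # microLC setup: ratio 0.1, 50 fmol IS, 6.73 ug
  q <- quantify_transitions(data.frame(
    area_analyte = 1e4, area_is = 1e5, is_amount_fmol = 50,
    protein_injected_ug = 6.73))
  expect_equal(round(q$amount, 3), 0.743)
  # no analyte peak
  expect_equal(quantify_transitions(data.frame(
    area_analyte = 0, area_is = 1e5, is_amount_fmol = 500,
    protein_injected_ug = 33.3))$amount, 0)
})

test_that("zero internal-standard areas invalidate the measurement", {
  df <- data.frame(area_analyte = c(1e4, 1e4), area_is = c(1e5, 0),
                   is_amount_fmol = 500, protein_injected_ug = 33.3)
  expect_warning(q <- quantify_transitions(df), "zero internal")
  expect_equal(q$valid, c(TRUE, FALSE))
  expect_true(is.na(q$amount[2]))
})

test_that("quantification is linear in analyte area and 1/protein load", {
  set.seed(21)
  base <- data.frame(area_analyte = rlnorm(20, 9, 1),
                     area_is = rlnorm(20, 11, 0.3),
                     is_amount_fmol = 500, protein_injected_ug = 33.3)
  a0 <- quantify_transitions(base)$amount
  for (k in c(0.1, 3, 42)) {
    up <- transform(base, area_analyte = k * area_analyte)
    expect_equal(quantify_transitions(up)$amount, k * a0)
    load <- transform(base, protein_injected_ug = k * protein_injected_ug)
    expect_equal(quantify_transitions(load)$amount, a0 / k)
  }
})

test_that("expression requires positive peaks in 3 or 4 transition sets", {
  loq <- make_loq_table(loq = 0.1)
  for (n_pos in 0:4) {
    amounts <- c(rep(1, n_pos), rep(0.01, 4 - n_pos))  # sub-LOQ fillers
    res <- assess_positivity(make_transitions(amounts = amounts), loq)
    expect_equal(res$positive_count, n_pos)
    expect_equal(res$expressed, n_pos >= 3)
  }
  # wrong transition count is a schema error
  five <- rbind(make_transitions(),
                transform(make_transitions(amounts = rep(1, 4))[1:3, ],
                          transition_id = "Q1Q3-5"))
  expect_error(assess_positivity(five, loq), "exactly 4")
})

test_that("a retention-time mismatch makes a transition non-positive", {
  loq <- make_loq_table(loq = 0.1)
  tr <- make_transitions(amounts = rep(1, 4))
  tr$rt_match[tr$transition_id == "Q1Q3-1"] <- FALSE
  res <- assess_positivity(tr, loq)
  expect_equal(res$positive_count, 3L)
  expect_true(res$expressed)
})

test_that("positivity is monotone in transition amounts", {
  loq <- make_loq_table(loq = 0.1)
  set.seed(31)
  for (i in 1:25) {
    amounts <- runif(4, 0, 0.3)
    before <- assess_positivity(make_transitions(amounts = amounts), loq)
    j <- sample(4, 1)
    amounts[j] <- amounts[j] * runif(1, 1, 50)
    after <- assess_positivity(make_transitions(amounts = amounts), loq)
    expect_gte(after$positive_count, before$positive_count)
    if (before$expressed) expect_true(after$expressed)
  }
})

test_that("expression level pools positive transitions across runs", {
  loq <- make_loq_table(loq = 0.1)
  # 4 transitions x 3 runs, all identical: SEM 0
  res <- summarize_expression(make_transitions(amounts = rep(2.5, 4)), loq)
  expect_equal(res$level, 2.5)
  expect_equal(res$sem, 0)
  expect_equal(res$n_values, 12L)
  # hand-computed SD/sqrt(n) on {1,2,3,4}
  tr <- make_transitions(amounts = c(1, 2, 3, 4), runs = 1)
  res <- summarize_expression(tr, loq)
  expect_equal(res$level, 2.5)
  expect_equal(res$sem, sd(1:4) / 2)
  expect_equal(round(res$sem, 3), 0.645)
})

test_that("sub-LOQ transitions are excluded from the pooled mean", {
  loq <- make_loq_table(loq = 0.5)
  tr <- make_transitions(amounts = c(2, 2, 2, 0.01))
  res <- summarize_expression(tr, loq)
  expect_equal(res$positive_count, 3L)
  expect_equal(res$level, 2)  # the 0.01 set does not dilute the mean
  expect_equal(res$n_values, 9L)
})

test_that("a molecule failing positivity is censored as ULQ", {
  loq <- make_loq_table(loq = 0.5)
  res <- summarize_expression(make_transitions(amounts = rep(0.05, 4)), loq)
  expect_equal(res$status, "ULQ")
  expect_true(is.na(res$level))
  expect_equal(res$loq, 0.5)
  expect_equal(format_expression_cell(res), "U.L.Q.(< 0.500)")
})

test_that("LOQ is k x blank SD per transition, min over transitions per molecule", {
  blanks <- make_transitions(amounts = rep(1, 4), runs = 5)
  # constant blanks: zero noise floor
  expect_equal(compute_loq(blanks)$loq, rep(0, 4))
  # known SD: transition 1 gets spread {0.9, 1.0, 1.1, 1.0, 1.0}
  blanks$area_analyte[blanks$transition_id == "Q1Q3-1"] <-
    c(0.9, 1.0, 1.1, 1.0, 1.0) * 1e5
  lt <- compute_loq(blanks, k_noise = 3)
  s <- sd(c(0.9, 1.0, 1.1, 1.0, 1.0))
  expect_equal(lt$loq[lt$transition_id == "Q1Q3-1"], 3 * s)
  expect_equal(molecule_loq(lt)$loq, 0)  # other transitions are exact
  # insufficient blanks: fallback with warning, or error without one
  few <- make_transitions(amounts = rep(1, 4), runs = 2)
  w <- capture_warnings(lt2 <- compute_loq(few, loq_fallback = 0.2))
  expect_length(w, 4)  # one per transition
  expect_match(w, "fallback", all = TRUE)
  expect_equal(lt2$loq, rep(0.2, 4))
  expect_error(compute_loq(few), "loq_fallback")
})

test_that("fold changes honour censoring direction", {
  wt_mdr1a <- expr_row("Mdr1a", "WT", level = 22.3)
  h_hmdr1 <- expr_row("hMDR1", "HM", level = 0.355)
  h_mdr1a <- expr_row("Mdr1a", "HM", level = 2.45)
  ulq <- expr_row("Mdr1b", "HM", level = NA, loq = 0.112)
  # point ratios at printed precision
  expect_equal(signif(fold_change(wt_mdr1a, h_hmdr1)$value, 3), 62.8)
  expect_equal(signif(fold_change(h_mdr1a, h_hmdr1)$value, 3), 6.90)
  # censored denominator: only a lower bound can be claimed
  fc <- fold_change(h_hmdr1, ulq)
  expect_equal(fc$kind, "lower_bound")
  expect_equal(signif(fc$value, 3), 3.17)  # 0.355 / 0.112
  # censored numerator: upper bound; both censored: undefined
  expect_equal(fold_change(ulq, h_hmdr1)$kind, "upper_bound")
  expect_equal(fold_change(ulq, expr_row("x", "WT", NA))$kind, "undefined")
})

test_that("point fold changes are antisymmetric", {
  set.seed(41)
  for (i in 1:20) {
    a <- expr_row("a", "G1", level = rlnorm(1, 1, 1))
    b <- expr_row("b", "G2", level = rlnorm(1, 1, 1))
    expect_equal(fold_change(a, b)$value, 1 / fold_change(b, a)$value)
  }
})

test_that("group comparisons of pooled amounts respect censoring", {
  # identical pools: no difference
  res <- compare_expression_groups(c(1, 2, 3), c(1, 2, 3))
  expect_true(res$testable)
  expect_equal(res$t, 0)
  expect_false(res$significant)
  # 10-fold separated means at low noise: significant at p < 0.01
  set.seed(51)
  a <- rlnorm(12, log(10), 0.05)
  b <- rlnorm(12, log(1), 0.05)
  res <- compare_expression_groups(a, b)
  expect_true(res$significant)
  expect_lt(res$p, 0.01)
  # a ULQ side makes the comparison not-testable
  expect_false(compare_expression_groups(NULL, c(1, 2, 3))$testable)
})

test_that("expression cells format like published tables", {
  e <- expr_row("Glut1", "WT", level = 194.23)
  e$sem <- 13.2
  expect_equal(format_expression_cell(e), "194 ± 13.2")
  u <- expr_row("Pmat", "WT", level = NA, loq = 0.099)
  expect_equal(format_expression_cell(u), "U.L.Q.(< 0.0990)")
})
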