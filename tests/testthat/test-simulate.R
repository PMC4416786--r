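test_that("identical seeds give byte-identical study files", {
  t1 <- cohort_truth(seed = 99, cv = 0.1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_study(t1, d1)
  p2 <- simulate_study(cohort_truth(seed = 99, cv = 0.1), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     label = paste("file", k))
  }
  # a different seed perturbs the data
  p3 <- simulate_study(cohort_truth(seed = 100, cv = 0.1),
                       withr::local_tempdir())
  expect_false(identical(readLines(p1[["concentrations"]]),
                         readLines(p3[["concentrations"]])))
})

test_that("generated tables validate against the schema readers", {
  truth <- cohort_truth(seed = 3, cv = 0.1)
  paths <- simulate_study(truth, withr::local_tempdir(),
                          fail_fraction = 1 / 6)
  f <- validate_inputs(as.list(paths[names(paths) != "truth"]))
  expect_equal(nrow(f), 0L)
})

test_that("zero-noise cohorts invert to the exact generating truth", {
  truth <- cohort_truth(seed = 8, cv = 0, cv_biological = 0)
  conc <- generate_cohort(truth, n_per_group = 3)
  dia <- generate_dialysis(truth)
  sli <- generate_slices(truth)
  fu <- compute_fu_plasma(dia)$summary
  vu <- compute_vu_brain(sli)$summary
  # verapamil-hMDR1-like active uptake recovered exactly
  binding <- merge(fu[, c("drug", "genotype", "f_u_plasma")],
                   vu[, c("drug", "v_u_brain")], by = "drug")
  dm <- distribution_metrics(conc, binding, truth$vascular)
  ver <- dm[dm$drug == "verapamil" & dm$genotype == "HMDR1", ]
  expect_equal(unique(round(ver$kpuu, 10)),
               round(9 / (48.2 * 0.117), 10))
  expect_equal(signif(ver$kpuu[1], 3), 1.60)
  # binding assays recover their truths exactly
  expect_equal(fu$f_u_plasma[fu$drug == "oxycodone" &
                               fu$genotype == "C57BL6_WT"], 0.681)
  expect_equal(vu$v_u_brain[vu$drug == "digoxin"], 44.8)
})

test_that("noisy dialysis recovery stays within three standard errors", {
  truth <- cohort_truth(seed = 12, cv = 0.1)
  dia <- generate_dialysis(truth, replicates = 3)
  fu <- compute_fu_plasma(dia)$summary
  m <- merge(fu, unique(truth$drugs[, c("drug", "genotype",
                                        "f_u_plasma")]),
             by = c("drug", "genotype"),
             suffixes = c("_est", "_true"))
  # every estimate lands well inside the noise envelope ...
  expect_true(all(abs(m$f_u_plasma_est / m$f_u_plasma_true - 1) < 0.4))
  # ... and most groups agree within 3 SEM of their own replicate spread
  tol <- pmax(3 * m$sem, 1e-6)
  expect_gte(mean(abs(m$f_u_plasma_est - m$f_u_plasma_true) <= tol), 0.75)
})

test_that("slice generator exercises the viability QC", {
  truth <- cohort_truth(seed = 5, cv = 0)
  # all slices non-viable: the estimator must refuse
  bad <- generate_slices(truth, n_slices = 4, fail_fraction = 1)
  expect_true(all(bad$end_ph < 7.25))
  expect_error(compute_vu_brain(bad), "QC failure")
  # one-third failing with distorted content: QC restores the exact truth
  mixed <- generate_slices(truth, n_slices = 6, fail_fraction = 1 / 3)
  vu <- compute_vu_brain(mixed)$summary
  expect_equal(vu$n_pass, rep(4L, 4))
  expect_equal(vu$v_u_brain[vu$drug == "verapamil"], 48.2)
  # without QC the distorted slices would inflate the estimate
  naive <- mixed
  naive$end_ph <- 7.5
  naive$ldh_release_fraction <- 0.1
  expect_gt(compute_vu_brain(naive)$summary$v_u_brain[1],
            vu$v_u_brain[1])
})

test_that("zero-noise SRM tables reproduce the expression truths and folds", {
  truth <- cohort_truth(seed = 17, cv = 0)
  srm <- generate_srm(truth)
  expr <- qtap_expression_table(srm$transitions, blanks = srm$blanks)
  g <- function(mol, grp) expr[expr$molecule == mol & expr$group == grp, ]
  expect_equal(g("Mdr1a", "C57BL6_WT")$level, 22.3)
  expect_equal(g("Mdr1a", "HMDR1")$level, 2.45)
  expect_equal(g("hMDR1", "HMDR1")$level, 0.355)
  # species-selective probes: no human signal in wild type
  expect_equal(g("hMDR1", "C57BL6_WT")$status, "ULQ")
  # common probe sums the human and mouse contributions
  expect_equal(g("MDR1_Mdr1a", "HMDR1")$level, 0.355 + 2.45)
  # Mdr1b is absent in both lines
  expect_equal(g("Mdr1b", "C57BL6_WT")$status, "ULQ")
  expect_equal(g("Mdr1b", "HMDR1")$status, "ULQ")
  # the three headline fold differences at printed precision
  expect_equal(signif(fold_change(g("Mdr1a", "C57BL6_WT"),
                                  g("hMDR1", "HMDR1"))$value, 3), 62.8)
  expect_equal(signif(fold_change(g("Mdr1a", "C57BL6_WT"),
                                  g("Mdr1a", "HMDR1"))$value, 3), 9.10)
  expect_equal(signif(fold_change(g("Mdr1a", "HMDR1"),
                                  g("hMDR1", "HMDR1"))$value, 3), 6.90)
})

test_that("positivity flips only near the LOQ boundary under noise", {
  # sweep a single-molecule truth across the LOQ: well below is censored,
  # well above is expressed, in every seeded run
  probes <- data.frame(molecule = "probe", probe_set = "common",
                       targets = "target")
  for (level in c(0.02, 0.5)) {
    calls <- logical(5)
    for (r in 1:5) {
      truth <- cohort_truth(
        seed = 300 + r, cv = 0.1,
        proteins = data.frame(protein = "target", C57BL6_WT = level,
                              HMDR1 = level),
        probes = probes, loq = c(probe = 0.1))
      srm <- generate_srm(truth)
      expr <- qtap_expression_table(srm$transitions, blanks = srm$blanks)
      calls[r] <- all(expr$status == "expressed")
    }
    if (level > 0.1) expect_true(all(calls)) else expect_false(any(calls))
  }
})
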