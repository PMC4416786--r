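test_that("Kp is the ratio of total brain to total plasma concentration", {
  expect_equal(compute_kp(100, 100), 1)
  expect_equal(compute_kp(0, 50), 0)
  expect_equal(compute_kp(c(10, 30), c(20, 10)), c(0.5, 3))
  expect_error(compute_kp(10, 0, animal_id = "m01"), "m01")
  expect_error(compute_kp(10, -1), "non-positive plasma")
  expect_error(compute_kp(-5, 10), "negative brain")
})

test_that("effective plasma space blends water and protein spaces by fu", {
  p <- vascular_params(v_water = 0.010, v_protein = 0.008)
  expect_equal(effective_plasma_space(1, p), 0.010)
  expect_equal(effective_plasma_space(0, p), 0.008)
  expect_equal(effective_plasma_space(0.5, p), 0.009)
  expect_error(effective_plasma_space(1.2, p), "\\[0, 1\\]")
  expect_error(effective_plasma_space(-0.1, p), "\\[0, 1\\]")
})

test_that("v_eff is a convex combination for any fu and vascular params", {
  set.seed(101)
  for (i in 1:200) {
    p <- vascular_params(runif(1, 0, 0.05), runif(1, 0, 0.05))
    fu <- runif(1)
    v <- effective_plasma_space(fu, p)
    expect_gte(v, min(p$v_water, p$v_protein))
    expect_lte(v, max(p$v_water, p$v_protein))
  }
})

test_that("residual-blood correction handles edge cases and clamps", {
  p <- vascular_params(0.0103, 0.0080)
  # no plasma drug: only the 1/(1 - v_water) tissue-fraction rescale
  r <- correct_residual_blood(500, 0, 0.5, p)
  expect_equal(r$a_brain, 500 / (1 - 0.0103))
  expect_false(r$clamped)
  # homogenate signal entirely explained by residual blood
  veff <- effective_plasma_space(0.3, p)
  r <- correct_residual_blood(veff * 200, 200, 0.3, p)
  expect_equal(r$a_brain, 0)
  expect_false(r$clamped)
  # less signal than residual blood alone: clamped to zero and flagged
  r <- correct_residual_blood(0.5 * veff * 200, 200, 0.3, p)
  expect_equal(r$a_brain, 0)
  expect_true(r$clamped)
  expect_error(correct_residual_blood(-1, 10, 0.5, p), "nonnegative")
})

test_that("correction inverts the forward model to numerical precision", {
  set.seed(202)
  for (i in 1:500) {
    p <- vascular_params(runif(1, 0, 0.05), runif(1, 0, 0.05))
    fu <- runif(1)
    a_true <- rlnorm(1, 3, 2)
    cp <- rlnorm(1, 3, 2)
    veff <- effective_plasma_space(fu, p)
    c_homog_g <- a_true * (1 - p$v_water) + veff * cp
    r <- correct_residual_blood(c_homog_g, cp, fu, p)
    expect_equal(r$a_brain, a_true, tolerance = 1e-12)
  }
})

test_that("Kp and Kp,uu are invariant to a common concentration scale", {
  set.seed(303)
  for (k in c(1e-3, 0.5, 7, 1e4)) {
    cb <- rlnorm(5, 2, 1)
    cp <- rlnorm(5, 2, 1)
    expect_equal(compute_kp(k * cb, k * cp), compute_kp(cb, cp))
    expect_equal(compute_kpuu(compute_kp(k * cb, k * cp), 44.8, 0.594),
                 compute_kpuu(compute_kp(cb, cp), 44.8, 0.594))
  }
})

test_that("Kp,uu follows Kp / (Vu,brain x fu,p) with printed-style rounding", {
  # digoxin-like strong efflux and verapamil-like humanized uptake
  expect_equal(round(compute_kpuu(0.05, 44.8, 0.594), 3), 0.002)
  expect_equal(signif(compute_kpuu(9, 48.2, 0.117), 3), 1.60)
  # unity by construction
  expect_equal(compute_kpuu(48.2 * 0.115, 48.2, 0.115), 1)
  expect_error(compute_kpuu(1, 0, 0.5), "v_u_brain")
  expect_error(compute_kpuu(1, 44.8, 0), "f_u_plasma")
})

test_that("distribution_metrics recovers truth from forward-modelled records", {
  p <- vascular_params(0.0103, 0.0080)
  fu <- 0.117; vu <- 48.2; kpuu_true <- 1.6; cp <- 80; dil <- 5
  a <- kpuu_true * fu * cp * vu
  c_homog <- (a * (1 - p$v_water) +
                effective_plasma_space(fu, p) * cp) / dil
  rec <- data.frame(animal_id = "m1", genotype = "HMDR1",
                    drug = "verapamil", treatment = "",
                    c_plasma_ng_ml = cp, c_brain_homog_ng_ml = c_homog,
                    homogenate_dilution = dil)
  binding <- data.frame(drug = "verapamil", genotype = NA,
                        f_u_plasma = fu, v_u_brain = vu)
  out <- distribution_metrics(rec, binding, p)
  expect_equal(out$kpuu, kpuu_true, tolerance = 1e-12)
  expect_equal(out$kp, kpuu_true * fu * vu, tolerance = 1e-12)
})

test_that("distribution_metrics resolves genotype-specific binding", {
  binding <- data.frame(drug = "digoxin",
                        genotype = c("C57BL6_WT", "HMDR1"),
                        f_u_plasma = c(0.594, 0.607),
                        v_u_brain = 44.8)
  rec <- data.frame(animal_id = c("a", "b"),
                    genotype = c("C57BL6_WT", "HMDR1"), drug = "digoxin",
                    treatment = "", c_plasma_ng_ml = 100,
                    c_brain_homog_ng_ml = 10, homogenate_dilution = 5)
  out <- distribution_metrics(rec, binding)
  expect_equal(out$f_u_plasma, c(0.594, 0.607))
  expect_error(distribution_metrics(
    transform(rec, drug = "unknown"), binding), "no binding parameters")
})
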