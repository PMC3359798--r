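test_that("AIF and CSFIF have the stated shape, zero origin and peak", {
  expect_identical(aif(0, b_ref), 0)
  expect_equal(aif(10, b_ref), oracle$aif_10, tolerance = 1e-14)
  expect_equal(csf_input_function(10, csf_ref), oracle$csfif_10,
               tolerance = 1e-14)
  expect_identical(csf_input_function(0, csf_ref), 0)

  # unique maximum at t = 1/k with value rate_in / (e * k)
  tpk <- 1 / b_ref$k_out
  expect_equal(aif(tpk, b_ref), b_ref$c_in / (exp(1) * b_ref$k_out),
               tolerance = 1e-14)
  tt <- seq(0, 200, by = 0.05)
  expect_equal(tt[which.max(aif(tt, b_ref))], tpk, tolerance = 1e-3)
  tpk2 <- 1 / csf_ref$k_out_prime
  expect_equal(csf_input_function(tpk2, csf_ref),
               csf_ref$k_in_prime / (exp(1) * csf_ref$k_out_prime),
               tolerance = 1e-14)

  expect_error(aif(-1, b_ref), "negative")
  expect_error(csf_input_function(c(1, -2), csf_ref), "negative")
})

test_that("blood concentration is the (1 - hct)-scaled AIF", {
  tt <- seq(0, 60, by = 5)
  b0 <- blood_params(0.05, 0.03, hct = 0)
  b1 <- blood_params(0.05, 0.03, hct = 1)
  expect_equal(blood_concentration(tt, b0), aif(tt, b0))
  expect_equal(blood_concentration(tt, b1), rep(0, length(tt)))
  expect_equal(blood_concentration(10, b_ref), oracle$blood_10,
               tolerance = 1e-14)
})

test_that("post-infusion extension decays mono-exponentially, continuous at t_end", {
  t_end <- 20
  v_end <- aif(t_end, b_ref)
  expect_equal(aif(t_end, b_ref, t_end = t_end), v_end)
  s <- c(1, 5, 17)
  expect_equal(aif(t_end + s, b_ref, t_end = t_end),
               v_end * exp(-b_ref$k_out * s), tolerance = 1e-14)
  # before t_end nothing changes
  expect_equal(aif(0:20, b_ref, t_end = t_end), aif(0:20, b_ref))
})

test_that("EES solution matches frozen ODE oracle and trivial cases", {
  expect_identical(ees_concentration(0, tissue_ref, b_ref), 0)
  tp0 <- tissue_params(0, 0.01, 0.002, 0.005, 0.05, 0.2, 0.72)
  expect_equal(ees_concentration(grid60, tp0, b_ref),
               rep(0, length(grid60)))
  expect_equal(ees_concentration(30, tissue_ref, b_ref), oracle$ees_30,
               tolerance = 1e-9)
})

test_that("closed-form EES agrees with the adaptive ODE solver over random draws", {
  set.seed(71)
  for (i in 1:30) {
    p <- draw_params(degenerate = i > 20)
    cf <- ees_concentration(grid60, p$tissue, p$blood)
    num <- solve_numeric("ees", p, grid60)$values
    expect_lt(rel_err(cf, num), 1e-8)
  }
})

test_that("EES evaluation is continuous through the degenerate k_ep = k_out limit", {
  t <- c(5, 30, 60)
  base <- blood_params(0.05, 0.03, 0.45)
  val_at <- function(dk) {
    tp <- tissue_params(5e-4, 0.03 + dk, 0.002, 0.005, 0.05, 0.2, 0.72)
    ees_concentration(t, tp, base)
  }
  v0 <- val_at(0)                       # exact t^2/2 limit
  expect_equal(v0, 5e-4 * 0.0275 * exp(-0.03 * t) * t^2 / 2,
               tolerance = 1e-12)
  # approach to the limit: the genuine parametric sensitivity is
  # O(|dk| * t), so deviations must shrink linearly with dk, with no
  # numerical jump superimposed
  for (dk in c(-1e-8, 1e-8, -1e-6, 1e-6))
    expect_lt(rel_err(val_at(dk), v0), 100 * abs(dk))
  # across the series/direct evaluation boundary |z| = 0.5
  zb <- 0.5 / 60
  expect_lt(rel_err(val_at(zb * (1 - 1e-9)), val_at(zb * (1 + 1e-9))), 1e-9)
})

test_that("EES approaches the quasi-steady limit k_trans C_BLOOD / k_ep for fast k_ep", {
  # requires both the exponential transient exp(-k_ep t) and the
  # forcing-ramp correction |d log C_BLOOD/dt| / k_ep ~ 1/(k_ep t) to be
  # small, hence t well beyond 1/k_ep
  tp <- tissue_params(5e-4, 1000, 0, 0, 0.05, 0.2, 0.72, v_now = 0.03)
  tt <- seq(0.5, 5, length.out = 40)
  qs <- tp$k_trans * blood_concentration(tt, b_ref) / tp$k_ep
  expect_lt(max(abs(ees_concentration(tt, tp, b_ref) - qs) / qs), 0.01)
})

test_that("IES solution: trivial zeros, frozen oracle value, closed vs ODE", {
  tp0 <- tissue_params(5e-4, 0.01, 0, 0.005, 0.05, 0.2, 0.72)
  expect_equal(ies_concentration(grid60, tp0, b_ref),
               rep(0, length(grid60)))
  expect_identical(ies_concentration(0, tissue_ref, b_ref), 0)
  expect_equal(ies_concentration(30, tissue_ref, b_ref), oracle$ies_30,
               tolerance = 1e-8)
  set.seed(72)
  for (i in 1:15) {
    p <- draw_params()
    cf <- ies_concentration(grid60, p$tissue, p$blood, method = "closed")
    num <- ies_concentration(grid60, p$tissue, p$blood, method = "ode")
    expect_lt(rel_err(cf, num), 1e-8)
    # the automatic dispatch agrees with the ODE path too
    auto <- ies_concentration(grid60, p$tissue, p$blood, method = "auto")
    expect_lt(rel_err(auto, num), 1e-8)
  }
})

test_that("tissue mixture obeys superposition and its trivial limits", {
  now_only <- tissue_params(5e-4, 0.01, 0.002, 0.005, 0, 0, 0, v_now = 1)
  expect_equal(tissue_concentration(grid60, now_only, b_ref),
               rep(0, length(grid60)))
  blood_only <- tissue_params(5e-4, 0.01, 0.002, 0.005, 1, 0, 0, v_now = 0)
  expect_equal(tissue_concentration(grid60, blood_only, b_ref),
               blood_concentration(grid60, b_ref))

  # exact linearity in the volume fractions
  comp <- cbind(blood_concentration(grid60, b_ref),
                ees_concentration(grid60, tissue_ref, b_ref),
                ies_concentration(grid60, tissue_ref, b_ref))
  mix <- tissue_concentration(grid60, tissue_ref, b_ref)
  expect_equal(mix, drop(comp %*% c(0.05, 0.20, 0.72)), tolerance = 1e-12)

  # weighted frozen-oracle combination at t = 30
  expect_equal(tissue_concentration(30, tissue_ref, b_ref),
               0.05 * oracle$blood_30 + 0.20 * oracle$ees_30 +
                 0.72 * oracle$ies_30,
               tolerance = 1e-8)
})

test_that("CSF voxel mixture reduces to its components and matches the oracle", {
  pure_csf <- csf_params(0.06, 0.03, v_blood = 0)
  expect_equal(csf_voxel_concentration(grid60, pure_csf, b_ref),
               csf_input_function(grid60, pure_csf))
  pure_blood <- csf_params(0.06, 0.03, v_blood = 1, v_csf = 0)
  expect_equal(csf_voxel_concentration(grid60, pure_blood, b_ref),
               blood_concentration(grid60, b_ref))
  expect_equal(csf_voxel_concentration(10, csf_ref, b_ref),
               oracle$csfmix_10, tolerance = 1e-14)
  expect_error(csf_params(0.06, 0.03, v_blood = 0.3, v_csf = 0.3),
               "must equal 1")
})

test_that("solve_numeric handles the degenerate equal-rates branch and trivial input", {
  tp0 <- tissue_params(0, 0.01, 0.002, 0.005, 0.05, 0.2, 0.72)
  expect_equal(solve_numeric("ees", list(tissue = tp0, blood = b_ref),
                             grid60)$values,
               rep(0, length(grid60)))
  tpd <- tissue_params(5e-4, 0.03, 0.002, 0.005, 0.05, 0.2, 0.72)
  num <- solve_numeric("ees", list(tissue = tpd, blood = b_ref),
                       grid60)$values
  limit <- 5e-4 * 0.0275 * exp(-0.03 * grid60) * grid60^2 / 2
  expect_lt(rel_err(num, limit), 1e-8)
})

test_that("noiseless model concentrations are nonnegative for nonnegative parameters", {
  set.seed(73)
  tt <- seq(0, 90, by = 0.5)
  for (i in 1:20) {
    p <- draw_params(degenerate = i %% 5 == 0)
    expect_gte(min(blood_concentration(tt, p$blood)), 0)
    expect_gte(min(ees_concentration(tt, p$tissue, p$blood)), -1e-15)
    expect_gte(min(ies_concentration(tt, p$tissue, p$blood)), -1e-15)
    expect_gte(min(tissue_concentration(tt, p$tissue, p$blood)), -1e-15)
  }
})

test_that("parameter constructors enforce their invariants", {
  expect_error(blood_params(-0.01, 0.03), ">= 0")
  expect_error(blood_params(0.05, 0), "> 0")
  expect_error(blood_params(0.05, 0.03, hct = 1.2), "<= 1")
  expect_error(tissue_params(5e-4, 0.01, 0.002, 0.005,
                             v_blood = 0.5, v_ees = 0.4, v_ies = 0.3),
               "exceeds 1")
  expect_error(tissue_params(5e-4, 0.01, 0.002, 0.005,
                             v_blood = 0.1, v_ees = 0.2, v_ies = 0.3,
                             v_now = 0.5), "sum to 1", fixed = FALSE)
  expect_error(tissue_params(-1e-4, 0.01, 0.002, 0.005, 0.05, 0.2, 0.72),
               ">= 0")
  expect_error(concentration_curve(c(0, 1, 1), c(0, 1, 2)),
               "strictly increasing")
  expect_error(concentration_curve(c(-1, 1), c(0, 1)), ">= 0")
})
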