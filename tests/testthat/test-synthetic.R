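test_that("generate_curve: zero noise reproduces the forward model exactly", {
  cv <- generate_curve("blood", list(blood = b_ref), grid60, noise_sd = 0)
  expect_identical(cv$values, blood_concentration(grid60, b_ref))
  cvt <- generate_curve("tissue",
                        list(tissue = tissue_ref, blood = b_ref), grid60)
  expect_identical(cvt$values,
                   tissue_concentration(grid60, tissue_ref, b_ref))
  expect_error(generate_curve("nope", list(blood = b_ref), grid60),
               "unknown model_id")
})

test_that("generate_curve is reproducible under a seed and restores the RNG", {
  set.seed(1); before <- .Random.seed
  a <- generate_curve("csfif", list(csf = csf_ref), grid60, 0.005, seed = 9)
  expect_identical(.Random.seed, before)
  b <- generate_curve("csfif", list(csf = csf_ref), grid60, 0.005, seed = 9)
  expect_identical(a, b)
})

test_that("added noise has the requested variance", {
  tt <- seq(0, 999.9, by = 0.1) # 1e4 samples
  clean <- aif(tt, b_ref)
  noisy <- generate_curve("aif", list(blood = b_ref), tt, 0.005, seed = 11)
  v <- var(noisy$values - clean)
  expect_lt(abs(v - 0.005^2) / 0.005^2, 0.05)
})

test_that("degenerate cohort (n = 1, zero spread) reproduces the distribution means", {
  sp <- cohort_spec(n_per_stage = 1, stages = "control")
  sp$rate_table[grep("_sd$", names(sp$rate_table))] <- 0
  co <- generate_cohort(sp, seed = 1)
  expect_equal(co$truth$c_in, 0.06)
  expect_equal(co$truth$k_out, 0.031)
  expect_equal(co$truth$k_in_prime, 0.06)
  expect_equal(co$truth$k_out_prime, 0.045)
  expect_equal(co$truth$v_blood, 0.12)
})

test_that("equal stage distributions give IOF = 1 for every stage", {
  sp <- cohort_spec(n_per_stage = 1)
  sp$rate_table[grep("_sd$", names(sp$rate_table))] <- 0
  co <- generate_cohort(sp, seed = 2)
  res <- iof_analysis(co$truth[, c("subject", "region", "stage",
                                   "k_in_prime", "k_out_prime")],
                      "control")
  expect_identical(res$iof, rep(1, 3))
})

test_that("cohort generation is bit-identical under the same spec and seed", {
  sp <- scale_stage(cohort_spec(n_per_stage = 3), "mild", "k_in_prime", 2)
  expect_identical(generate_cohort(sp, seed = 5), generate_cohort(sp, seed = 5))
  # and different under another seed
  expect_false(identical(generate_cohort(sp, seed = 5)$curves$conc_mM,
                         generate_cohort(sp, seed = 6)$curves$conc_mM))
})

test_that("drawn parameters respect truncation at zero", {
  sp <- cohort_spec(n_per_stage = 60)
  sp$rate_table$v_blood_mean <- 0.02
  sp$rate_table$v_blood_sd <- 0.05 # mass below 0 without truncation
  co <- generate_cohort(sp, seed = 7)
  expect_gte(min(co$truth$v_blood), 0)
  expect_gte(min(co$truth$k_in_prime), 0)
  expect_error(dcekin:::.rtrunc0norm(5, -1, 1e-6), "infeasible")
})

test_that("scale_stage multiplies one stage's distribution only", {
  sp <- scale_stage(cohort_spec(), "mild", "k_in_prime", 2)
  rt <- sp$rate_table
  expect_equal(rt$k_in_prime_mean[rt$stage == "mild"], 0.12)
  expect_equal(rt$k_in_prime_mean[rt$stage == "control"], 0.06)
  expect_error(scale_stage(sp, "nope", "k_in_prime", 2), "unknown stage")
})

phantom_layout <- function(classes_vec, dm = c(2, 2, 1)) {
  list(dim = dm, classes = array(classes_vec, dim = dm),
       params = list(blood = b_ref, tissue = tissue_ref, csf = csf_ref))
}

test_that("all-background phantom is identically zero", {
  ph <- generate_phantom(phantom_layout(rep("background", 4)), grid60)
  expect_true(all(ph$image == 0))
})

test_that("phantom voxels follow their class forward models", {
  lay <- phantom_layout(c("blood", "tissue", "csf", "background"))
  ph <- generate_phantom(lay, grid60)
  expect_equal(ph$image[1, 1, 1, ], blood_concentration(grid60, b_ref))
  expect_equal(ph$image[2, 1, 1, ],
               tissue_concentration(grid60, tissue_ref, b_ref))
  expect_equal(ph$image[1, 2, 1, ],
               csf_voxel_concentration(grid60, csf_ref, b_ref))
  expect_true(all(ph$image[2, 2, 1, ] == 0))
  expect_equal(ph$truth$k_trans[2, 1, 1], tissue_ref$k_trans)
  expect_equal(ph$truth$v_blood[1, 1, 1], 1)
  expect_error(generate_phantom(list(dim = c(2, 2), classes = 1:4), grid60),
               "3 positive integers")
})

test_that("noiseless phantom refit recovers the class k_trans", {
  lay <- phantom_layout(c(rep("tissue", 6), "blood", "csf"), c(2, 2, 2))
  ph <- generate_phantom(lay, grid60, noise_sd = 0)
  kt <- vapply(1:2, function(ix) {
    cv <- concentration_curve(ph$times, ph$image[ix, 1, 1, ])
    fit_tissue(cv, b_ref, v_ees_fixed = 0.20)$params$k_trans
  }, numeric(1))
  expect_lt(max(abs(kt - tissue_ref$k_trans) / tissue_ref$k_trans), 1e-4)
})

test_that("noisy phantom refit recovers CSF input rates", {
  # CSF evacuation rate well separated from the blood elimination rate,
  # matching the cohort generator's identifiable design
  csf_ph <- csf_params(0.06, 0.045, v_blood = 0.12)
  lay <- list(dim = c(2, 2, 1),
              classes = array(c("csf", "csf", "csf", "blood"), c(2, 2, 1)),
              params = list(blood = b_ref, csf = csf_ph))
  ph <- generate_phantom(lay, grid60, noise_sd = 0.002, seed = 13)
  est <- vapply(which(ph$truth$class == "csf"), function(i) {
    idx <- arrayInd(i, c(2, 2, 1))
    cv <- concentration_curve(ph$times,
                              ph$image[idx[1], idx[2], idx[3], ])
    fit_csf(cv, b_ref)$params$k_in_prime
  }, numeric(1))
  expect_lt(median(abs(est - 0.06) / 0.06), 0.10)
})

test_that("phantom NIfTI export writes the image and truth maps", {
  lay <- phantom_layout(c("blood", "tissue", "csf", "background"))
  ph <- generate_phantom(lay, seq(0, 10, by = 2))
  dir <- withr::local_tempdir()
  files <- write_phantom(ph, dir)
  expect_true(all(file.exists(
    file.path(dir, c("phantom_4d.nii.gz", "truth_k_trans.nii.gz")))))
  back <- RNifti::readNifti(file.path(dir, "phantom_4d.nii.gz"))
  expect_equal(dim(back), c(2, 2, 1, 6))
  expect_equal(as.numeric(back[1, 1, 1, ]),
               blood_concentration(seq(0, 10, by = 2), b_ref),
               tolerance = 1e-6)
})
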