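test_that("the PET phantom peaks at the planted SUV inside the VOI", {
  ph <- generate_pet_phantom(peak_suv = 9.2, seed = 61)
  expect_equal(suv_max(ph$pet, ph$voi), 9.2)
  # a confounder at 3x the peak does not leak into the VOI
  hot <- generate_pet_phantom(peak_suv = 5, seed = 61)
  expect_equal(hot$params$confounder$suv, 15)
  expect_equal(suv_max(hot$pet, hot$voi), 5)
  expect_gt(max(hot$pet$values), 14)   # the confounder is in the field
})

test_that("a confounder intersecting the VOI is rejected", {
  expect_error(
    generate_pet_phantom(confounder = list(centre = c(64, 64, 64),
                                           radius_mm = 10, suv = 30)),
    "confounder")
})

test_that("the analytic MTV curve is the Gaussian superlevel-set volume", {
  ph <- generate_pet_phantom(background_suv = 0, sigma_mm = 10, seed = 62)
  t <- ph$truth_mtv$threshold_percent
  expect_equal(ph$truth_mtv$volume_cm3,
               4 / 3 * pi * (10 * sqrt(-2 * log(t / 100)))^3 / 1000)
})

test_that("DWI truth masks partition the VOI with the planted geometry", {
  ph <- small_dwi_phantom(seed = 63)
  lab <- ph$truth$fat_fibrotic$values + ph$truth$tumour$values +
    ph$truth$normal_cystic$values
  expect_true(all(lab[ph$voi$values] == 1))
  expect_true(all(lab[!ph$voi$values] == 0))
  # planted solid fraction ~ tumour volume over anatomical volume
  f <- ph$truth_volumes["tumour"] / ph$truth_volumes["atv"]
  expect_equal(unname(f), 0.55, tolerance = 0.05)
})

test_that("fitting a noiseless DWI phantom recovers the voxel truth", {
  ph <- small_dwi_phantom(seed = 64)
  fit <- fit_adc(ph$dwi, mask = ph$voi)
  inside <- ph$voi$values
  rel <- abs(fit$adc[inside] - ph$adc_truth[inside]) /
    pmax(ph$adc_truth[inside], 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("phantoms and cohorts are reproducible from their seeds", {
  a <- small_dwi_phantom(rician_sigma = 3, seed = 65)
  b <- small_dwi_phantom(rician_sigma = 3, seed = 65)
  expect_identical(a$dwi$values, b$dwi$values)

  co1 <- generate_cohort(n_patients = 3, master_seed = 9,
                         pet_shape = c(32, 32, 32),
                         dwi_shape = c(48, 48, 48),
                         axis_range_mm = c(10, 16))
  co2 <- generate_cohort(n_patients = 3, master_seed = 9,
                         pet_shape = c(32, 32, 32),
                         dwi_shape = c(48, 48, 48),
                         axis_range_mm = c(10, 16))
  expect_identical(co1$truth_table, co2$truth_table)
  expect_identical(co1$patients[[2]]$pet_phantom$pet$values,
                   co2$patients[[2]]$pet_phantom$pet$values)
  expect_equal(nrow(co1$truth_table), 3)
  expect_error(generate_cohort(n_patients = 1), "at least 2")
})

test_that("phantom generation does not disturb the global RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_pet_phantom(noise_sd = 0.2, seed = 7))
  invisible(small_dwi_phantom(rician_sigma = 2, seed = 7))
  after <- runif(1)
  expect_identical(before, after)
})
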