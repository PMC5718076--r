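test_that("mono-exponential signal model evaluates correctly", {
  expect_equal(predict_signal(100, 2.3e-3, 0), 100)
  expect_equal(predict_signal(100, 0, 1000), 100)
  expect_equal(predict_signal(100, 1.0e-3, 1000), 100 * exp(-1))
  expect_error(predict_signal(-1, 1e-3, 0), "non-negative")
})

make_series <- function(S, b, spacing = c(2, 2, 2)) {
  # wrap a voxel x b signal matrix as a 1-slice dwi_series
  arr <- array(t(S), dim = c(length(b), nrow(S), 1, 1))
  dwi_series(arr, b, spacing)
}

test_that("two-point and flat series are solved in closed form", {
  b <- c(0, 1000)
  fit <- fit_adc(make_series(rbind(c(100, 100 * exp(-1))), b),
                 background_frac = 0)
  expect_equal(fit$adc[1, 1, 1], 1.0e-3, tolerance = 1e-9)
  expect_equal(fit$s0[1, 1, 1], 100, tolerance = 1e-9)

  bb <- default_b_values()
  flat <- fit_adc(make_series(rbind(rep(42, length(bb))), bb),
                  background_frac = 0)
  expect_equal(flat$adc[1, 1, 1], 0)
  expect_equal(flat$s0[1, 1, 1], 42)
})

test_that("noiseless signals are recovered over the whole ADC range", {
  b <- default_b_values()
  set.seed(11)
  s0 <- runif(400, 20, 300)
  adc <- runif(400, 0.1e-3, 3.0e-3)
  S <- outer(s0, rep(1, length(b))) * exp(-outer(adc, b))
  fit <- fit_adc(make_series(S, b), background_frac = 0)
  expect_true(all(fit$fit_ok))
  expect_lt(max(abs(fit$adc[, 1, 1] - adc) / adc), 1e-6)
  expect_lt(max(abs(fit$s0[, 1, 1] - s0) / s0), 1e-6)
})

test_that("rescaling all signals rescales s0 and leaves ADC unchanged", {
  b <- default_b_values()
  set.seed(12)
  s0 <- runif(50, 20, 300)
  adc <- runif(50, 0.2e-3, 2.5e-3)
  S <- outer(s0, rep(1, length(b))) * exp(-outer(adc, b))
  S <- S * (1 + 0.02 * matrix(rnorm(length(S)), nrow(S)))  # mild noise
  S <- abs(S)
  f1 <- fit_adc(make_series(S, b), background_frac = 0)
  f2 <- fit_adc(make_series(S * 7.3, b), background_frac = 0)
  expect_equal(f2$adc, f1$adc, tolerance = 1e-8)
  expect_equal(f2$s0, f1$s0 * 7.3, tolerance = 1e-8)
})

test_that("the vectorised LM fit agrees with a reference per-voxel LM", {
  skip_if_not_installed("minpack.lm")
  b <- default_b_values()
  set.seed(13)
  n <- 25
  s0 <- runif(n, 50, 200)
  adc <- runif(n, 0.3e-3, 2.0e-3)
  S <- outer(s0, rep(1, length(b))) * exp(-outer(adc, b))
  S <- abs(S + matrix(rnorm(length(S), 0, 3), n))
  fit <- fit_adc(make_series(S, b), background_frac = 0)
  for (i in seq_len(n)) {
    ref <- minpack.lm::nls.lm(
      par = list(s0 = S[i, 1], adc = 1e-3),
      fn = function(p) S[i, ] - p$s0 * exp(-b * p$adc))
    expect_equal(fit$s0[i, 1, 1], coef(ref)[["s0"]], tolerance = 1e-5)
    expect_equal(fit$adc[i, 1, 1], coef(ref)[["adc"]], tolerance = 1e-5)
  }
})

test_that("voxels without enough usable samples are flagged, not fatal", {
  b <- c(0, 500, 1000)
  S <- rbind(c(100, 60, 36),   # fine
             c(100, 0, 0),     # only one positive sample
             c(0, 0, 0))       # nothing usable
  fit <- fit_adc(make_series(S, b), background_frac = 0)
  expect_true(fit$fit_ok[1, 1, 1])
  expect_false(fit$fit_ok[2, 1, 1])
  expect_false(fit$fit_ok[3, 1, 1])
  # an all-unusable input is an error
  expect_error(fit_adc(make_series(rbind(c(0, 0, 0)), b),
                       background_frac = 0), "no voxel")
})

test_that("background voxels below the s0 floor are excluded", {
  ph <- small_dwi_phantom(seed = 21)
  fit <- fit_adc(ph$dwi)   # whole grid, default 5% background floor
  inside <- ph$voi$values
  expect_true(all(fit$fit_ok[inside]))
  expect_true(all(is.na(fit$adc[!inside])))
})

test_that("median ADC bias under Rician noise at SNR 30 is below 2%", {
  b <- default_b_values()
  set.seed(14)
  n <- 2000
  s0 <- rep(150, n)
  adc <- runif(n, 0.7e-3, 1.2e-3)
  S <- outer(s0, rep(1, length(b))) * exp(-outer(adc, b))
  sigma <- 150 / 30
  S <- sqrt((S + matrix(rnorm(length(S), 0, sigma), n))^2 +
              matrix(rnorm(length(S), 0, sigma), n)^2)
  fit <- fit_adc(make_series(S, b), background_frac = 0)
  bias <- median((fit$adc[, 1, 1] - adc) / adc)
  expect_lt(abs(bias), 0.02)
})

test_that("negative ADC estimates are clamped to zero and flagged", {
  b <- c(0, 200, 400)
  S <- rbind(c(100, 105, 112))   # rising signal -> negative ADC
  fit <- fit_adc(make_series(S, b), method = "loglinear",
                 background_frac = 0)
  expect_equal(fit$adc[1, 1, 1], 0)
  expect_true(fit$adc_clamped[1, 1, 1])
})

test_that("predictions from a fit reproduce the fitted signals", {
  b <- default_b_values()
  set.seed(15)
  s0 <- runif(20, 50, 200)
  adc <- runif(20, 0.3e-3, 2e-3)
  S <- outer(s0, rep(1, length(b))) * exp(-outer(adc, b))
  fit <- fit_adc(make_series(S, b), background_frac = 0)
  pred <- predict(fit)
  expect_equal(as.vector(pred[, , 1, 1]), as.vector(t(S)),
               tolerance = 1e-6)
})
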