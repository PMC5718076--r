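toy_table <- function(atv, mod, name = "ftv_manual") {
  df <- data.frame(patient_id = sprintf("P%02d", seq_along(atv)),
                   atv = atv)
  for (m in modality_columns()) df[[m]] <- mod
  df[[name]] <- mod
  cohort_table(df)
}

test_that("a modality identical to ATV has zero difference and p = 1", {
  tab <- toy_table(c(10, 20, 30), c(10, 20, 30))
  pd <- paired_difference(tab, "ftv_manual")
  expect_equal(pd$diff_cm3, 0)
  expect_equal(pd$pct, 0)
  expect_equal(pd$p, 1)
})

test_that("paired t statistics match the long-hand closed form", {
  atv <- c(12.0, 25.5, 31.0)
  mod <- c(10.0, 28.0, 24.5)
  pd <- paired_difference(toy_table(atv, mod), "ftv_manual")
  # independent long-hand computation: t = dbar / (s_d / sqrt(n))
  d <- atv - mod
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  p_ref <- 2 * pt(-abs(t_stat), df = n - 1)
  expect_equal(pd$diff_cm3, mean(atv) - mean(mod), tolerance = 1e-12)
  expect_equal(pd$pct, 100 * (mean(atv) - mean(mod)) / mean(atv),
               tolerance = 1e-12)
  expect_equal(pd$p, p_ref, tolerance = 1e-12)
})

test_that("insufficient or degenerate input raises informative errors", {
  expect_error(paired_difference(toy_table(5, 3), "ftv_manual"),
               "fewer than 2")
  expect_error(paired_difference(toy_table(c(0, 0), c(1, 2)),
                                 "ftv_manual"), "mean ATV is zero")
  expect_error(pearson_correlation(toy_table(c(1, 2), c(1, 2)),
                                   "ftv_manual"), "fewer than 3")
  expect_error(pearson_correlation(toy_table(c(5, 5, 5), c(1, 2, 3)),
                                   "ftv_manual"), "variance")
})

test_that("Pearson correlation matches the closed form and t transform", {
  atv <- c(10, 22, 35, 41, 58)
  mod <- c(12, 19, 30, 45, 52)
  pc <- pearson_correlation(toy_table(atv, mod), "ftv_manual")
  # independent closed form: covariance over product of SDs, p via the
  # t transform on n - 2 degrees of freedom
  r_ref <- sum((atv - mean(atv)) * (mod - mean(mod))) /
    sqrt(sum((atv - mean(atv))^2) * sum((mod - mean(mod))^2))
  t_ref <- r_ref * sqrt((length(atv) - 2) / (1 - r_ref^2))
  p_ref <- 2 * pt(-abs(t_ref), df = length(atv) - 2)
  expect_equal(pc$r, r_ref, tolerance = 1e-12)
  expect_equal(pc$p, p_ref, tolerance = 1e-12)

  # identity and reflection are exactly +/- 1
  expect_equal(pearson_correlation(toy_table(atv, atv), "ftv_manual")$r, 1)
  expect_equal(pearson_correlation(toy_table(atv, 100 - atv),
                                   "ftv_manual")$r, -1)
})

test_that("the report covers all 15 modalities and flags the closest", {
  means <- reference_cohort_means()
  tab <- cohort_with_means(as.list(means))
  rep <- build_report(tab)
  expect_equal(nrow(rep), 15)
  expect_equal(attr(rep, "closest_modality"), "mtv_30")
  # sign convention: a modality smaller than ATV gives a positive diff
  expect_gt(rep$paired_diff_cm3[rep$modality == "ftv_semi"], 0)
  expect_lt(rep$paired_diff_cm3[rep$modality == "mtv_20"], 0)
})

test_that("a planted closest modality is recovered from a noisy cohort", {
  set.seed(55)
  n <- 29
  atv <- runif(n, 20, 90)
  df <- data.frame(patient_id = sprintf("P%02d", 1:n), atv = atv)
  offs <- seq(-25, 35, length.out = 15)
  offs[9] <- 0.2   # planted closest modality
  cols <- modality_columns()
  for (i in seq_along(cols))
    df[[cols[i]]] <- pmax(atv - offs[i] + rnorm(n, 0, 2), 0)
  rep <- build_report(cohort_table(df))
  expect_equal(attr(rep, "closest_modality"), cols[9])
})

test_that("an all-identical cohort yields zero diffs and no correlations", {
  df <- data.frame(patient_id = sprintf("P%02d", 1:5), atv = rep(30, 5))
  for (m in modality_columns()) df[[m]] <- rep(30, 5)
  rep <- build_report(cohort_table(df))
  expect_true(all(rep$paired_diff_cm3 == 0))
  expect_true(all(rep$pct_diff == 0))
  expect_true(all(is.na(rep$pearson_r)))
})
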