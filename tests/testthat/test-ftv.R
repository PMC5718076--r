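test_that("manual FTV is the delineated mask volume", {
  expect_equal(ftv_manual(make_mask(1000)), 1.0)
  expect_warning(v <- ftv_manual(make_mask(0)), "empty")
  expect_equal(v, 0)
  expect_equal(reader_average(ftv_manual(make_mask(1000, c(12, 10, 10))),
                              ftv_manual(make_mask(1200, c(12, 10, 10)))),
               1.1)
})

test_that("a voxelised ellipsoid mask matches its analytic volume", {
  ph <- small_dwi_phantom(anat_semi_axes = c(18, 15, 15), seed = 41)
  analytic <- 4 / 3 * pi * 18 * 15 * 15 / 1000
  measured <- ftv_manual(ph$anat_mask)
  # surface voxelisation bound: area of the equivalent sphere x 1 voxel
  r_eq <- (18 * 15 * 15)^(1 / 3)
  expect_lt(abs(measured - analytic),
            one_voxel_layer_cm3(r_eq, max(ph$dwi$spacing)))
})

test_that("noiseless planted classes are recovered exactly", {
  ph <- small_dwi_phantom(class_params = deterministic_tissue_params(),
                          seed = 42)
  fit <- fit_adc(ph$dwi, mask = ph$voi)
  model <- kmeans_segment(ph$voi, fit$s0, fit$adc, seed = 1)
  masks <- cluster_masks(model)
  for (cl in names(masks)) {
    expect_equal(dice_coefficient(masks[[cl]], ph$truth[[cl]]), 1,
                 info = cl)
  }
  v <- ftv_semi_automated(ph$voi, fit$s0, fit$adc, seed = 1)
  expect_equal(as.numeric(v), unname(ph$truth_volumes["tumour"]))
})

test_that("clustering fails on degenerate feature input", {
  voi <- make_mask(10)
  s0 <- array(7, dim = c(10, 10, 10))
  adc <- array(1e-3, dim = c(10, 10, 10))
  expect_error(kmeans_segment(voi, s0, adc, k = 3), "distinct")
})

test_that("segmentation is deterministic given the seed", {
  ph <- small_dwi_phantom(rician_sigma = 4, seed = 43)
  fit <- fit_adc(ph$dwi, mask = ph$voi)
  a <- kmeans_segment(ph$voi, fit$s0, fit$adc, seed = 17)
  b <- kmeans_segment(ph$voi, fit$s0, fit$adc, seed = 17)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centroids, b$centroids)
})

test_that("all restarts reach the same optimum on separated classes", {
  ph <- small_dwi_phantom(seed = 44)
  fit <- fit_adc(ph$dwi, mask = ph$voi)
  vols <- vapply(1:20, function(s)
    as.numeric(ftv_semi_automated(ph$voi, fit$s0, fit$adc, seed = s)),
    numeric(1))
  expect_equal(max(vols) - min(vols), 0)
})

test_that("tissue assignment follows the ADC centroid order", {
  mk <- function(centroids) {
    structure(list(k = 3L, centroids = centroids), class = "tissue_clusters")
  }
  cent <- cbind(s0 = c(240, 60, 120), adc = c(2.0e-3, 0.3e-3, 0.934e-3))
  asg <- assign_clusters(mk(cent))
  expect_equal(asg[["tumour"]], 3L)
  expect_equal(asg[["fat_fibrotic"]], 2L)
  expect_equal(asg[["normal_cystic"]], 1L)

  # permuting cluster indices permutes the map but not the tissue roles
  perm <- c(3, 1, 2)
  asg2 <- assign_clusters(mk(cent[perm, ]))
  expect_equal(cent[asg[["tumour"]], ],
               cent[perm, ][asg2[["tumour"]], ])

  # exact ADC tie: the lower-S0 cluster takes the lower-ADC role
  tied <- cbind(s0 = c(200, 50, 120), adc = c(1e-3, 1e-3, 2e-3))
  asg3 <- assign_clusters(mk(tied))
  expect_equal(asg3[["fat_fibrotic"]], 2L)
  expect_equal(asg3[["tumour"]], 1L)
})

test_that("class volumes partition the VOI exactly", {
  ph <- small_dwi_phantom(rician_sigma = 4, seed = 45)
  fit <- fit_adc(ph$dwi, mask = ph$voi)
  model <- kmeans_segment(ph$voi, fit$s0, fit$adc, seed = 2)
  masks <- cluster_masks(model)
  total <- sum(vapply(masks, voxel_count_volume, numeric(1)))
  expect_equal(total, voxel_count_volume(ph$voi))
  # pairwise disjoint
  expect_equal(sum(masks$tumour$values & masks$fat_fibrotic$values), 0)
  expect_equal(sum(masks$tumour$values & masks$normal_cystic$values), 0)
})

test_that("z-scoring absorbs positive affine rescaling of a feature", {
  ph <- small_dwi_phantom(rician_sigma = 4, seed = 46)
  fit <- fit_adc(ph$dwi, mask = ph$voi)
  a <- kmeans_segment(ph$voi, fit$s0, fit$adc, seed = 3)
  b <- kmeans_segment(ph$voi, 2.5 * fit$s0 + 40, fit$adc, seed = 3)
  expect_identical(a$labels, b$labels)
})

test_that("noisy segmentation stays close to the planted truth", {
  # Rician noise at SNR 30 relative to the tumour-class S0
  ph <- small_dwi_phantom(rician_sigma = 120 / 30, seed = 47)
  fit <- fit_adc(ph$dwi, mask = ph$voi)
  v <- ftv_semi_automated(ph$voi, fit$s0, fit$adc, seed = 4)
  truth_v <- unname(ph$truth_volumes["tumour"])
  expect_lt(abs(as.numeric(v) - truth_v) / truth_v, 0.05)
  masks <- cluster_masks(attr(v, "model"))
  expect_gte(dice_coefficient(masks$tumour, ph$truth$tumour), 0.95)
})
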