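test_that("phantom geometry, determinism and ground-truth consistency", {
  ph1 <- generate_phantom(seed = 2)
  expect_equal(ph1$label, "control")
  expect_false(any(ph1$lesion_mask))
  lesion <- list(center = c(32, 32, 12), semi_axes = c(10, 8, 6),
                 contrast = 30)
  ph2 <- generate_phantom(lesion = lesion, seed = 2)
  # rasterized ellipsoid volume close to its continuous volume 4/3*pi*abc
  expect_lt(abs(sum(ph2$lesion_mask) - 4 / 3 * pi * 10 * 8 * 6),
            0.1 * 4 / 3 * pi * 10 * 8 * 6)
  expect_true(all(ph2$lesion_mask <= ph2$brain_mask))
  # lesion mask equals the painting predicate: in-lesion voxels are brighter
  # on average by close to the nominal contrast
  delta <- mean(ph2$volume$data[ph2$lesion_mask]) -
    mean(ph2$volume$data[ph2$brain_mask & !ph2$lesion_mask])
  expect_gt(delta, 20)
  ph3 <- generate_phantom(lesion = lesion, seed = 2)
  expect_identical(ph2$volume$data, ph3$volume$data)
  expect_identical(ph2$lesion_mask, ph3$lesion_mask)
  expect_error(generate_phantom(lesion = list(center = c(5, 5, 2),
                                              semi_axes = c(10, 8, 6),
                                              contrast = 30)),
               "outside the head")
  expect_error(generate_phantom(lesion = list(center = c(32, 32, 12),
                                              semi_axes = c(4, 4, 3),
                                              contrast = -1)),
               "contrast")
})

test_that("detection cohorts have the requested composition", {
  co <- generate_detection_cohort(n_pos = 5, n_neg = 4, seed = 3)
  expect_equal(nrow(co), 9)
  expect_equal(sum(co$label == "patient"), 5)
  has_lesion <- vapply(co$lesion_mask, any, logical(1))
  expect_identical(has_lesion, co$label == "patient")
  expect_identical(levels(co$label), c("patient", "control"))
  co2 <- generate_detection_cohort(n_pos = 5, n_neg = 4, seed = 3)
  expect_identical(co$volume[[1]]$data, co2$volume[[1]]$data)
  expect_error(generate_detection_cohort(n_pos = 1, n_neg = 4), "n_pos")
})

test_that("zero contrast leaves patients indistinguishable from controls", {
  co <- generate_detection_cohort(n_pos = 4, n_neg = 4, contrast = 1e-9,
                                  seed = 5)
  pooled <- function(rows) {
    unlist(lapply(rows, function(i)
      co$volume[[i]]$data[co$brain_mask[[i]]]))
  }
  set.seed(1)
  ks <- suppressWarnings(
    stats::ks.test(sample(pooled(1:4), 1500), sample(pooled(5:8), 1500)))
  expect_gt(ks$p.value, 0.01)
})

test_that("high contrast moves lesion-cell HOG descriptors specifically", {
  lesion <- list(center = c(32, 32, 12), semi_axes = c(10, 8, 6),
                 contrast = 30)                    # 6x noise sd
  pat <- generate_phantom(lesion = lesion, seed = 9)
  ctl <- generate_phantom(seed = 9)                # same background field
  np <- zscore_normalize(pat$volume, pat$brain_mask)
  nc <- zscore_normalize(ctl$volume, ctl$brain_mask)
  g <- partition_cells(np, 16)
  dp <- gliohbm:::descriptor_matrix(extract_subject_features(np, g))
  dc <- gliohbm:::descriptor_matrix(extract_subject_features(nc, g))
  dist <- sqrt(rowSums((dp - dc)^2))
  # which cells intersect the lesion?
  idx <- expand.grid(col = 1:4, row = 1:4, slice = 1:24)
  in_lesion <- vapply(seq_len(nrow(idx)), function(i) {
    rr <- (idx$row[i] - 1) * 16 + 1:16
    cc <- (idx$col[i] - 1) * 16 + 1:16
    any(pat$lesion_mask[rr, cc, idx$slice[i]])
  }, logical(1))
  expect_gt(mean(dist[in_lesion]), 5 * mean(dist[!in_lesion]))
})

test_that("grading tiers are ordered and validated", {
  co <- generate_grading_cohort(n_high = 4, n_low = 4, seed = 7)
  expect_true(all(vapply(co$lesion_mask, any, logical(1))))
  vol_high <- mean(vapply(which(co$label == "high"),
                          function(i) sum(co$lesion_mask[[i]]), numeric(1)))
  vol_low <- mean(vapply(which(co$label == "low"),
                         function(i) sum(co$lesion_mask[[i]]), numeric(1)))
  expect_gt(vol_high, vol_low)
  expect_error(generate_grading_cohort(4, 4, contrast_high = 20,
                                       contrast_low = 20,
                                       semiaxes_high = c(8, 7, 5),
                                       semiaxes_low = c(8, 7, 5)),
               "strictly ordered")
  expect_error(generate_grading_cohort(4, 4, contrast_high = 10,
                                       contrast_low = 20),
               "at least as severe")
})

test_that("cohorts round-trip through manifest files", {
  co <- generate_detection_cohort(n_pos = 2, n_neg = 2,
                                  shape = c(24, 24, 8),
                                  lesion_semiaxes = c(4, 3, 2),
                                  location_jitter = c(1, 1, 0), seed = 11)
  dir <- file.path(tempdir(), "cohort_rt")
  manifest <- write_cohort(co, dir)
  back <- read_cohort(manifest, positive = "patient")
  expect_equal(back$subject_id, co$subject_id)
  expect_equal(as.character(back$label), as.character(co$label))
  expect_lt(max(abs(back$volume[[1]]$data - co$volume[[1]]$data)), 1e-6)
  expect_identical(levels(back$label), c("patient", "control"))
})
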