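# A tiny synthetic feature world: 3 cell positions x 9 bins, class signal
# planted at position 2 only.
toy_features <- function(n_per_class = 6, seed = 1, delta = 1) {
  set.seed(seed)
  mk <- function(diseased) lapply(seq_len(n_per_class), function(i) {
    m <- matrix(abs(rnorm(3 * 9, 0.3, 0.05)), 3, 9)
    if (diseased) m[2, ] <- m[2, ] + delta
    m
  })
  list(features = c(mk(TRUE), mk(FALSE)),
       diseased = rep(c(TRUE, FALSE), each = n_per_class))
}

toy_grid <- function() {
  g <- partition_cells(glio_volume(array(0.5, c(8, 24, 1))), 8)
  stopifnot(g$n_cells == 3)
  g
}

test_that("codebooks separate the planted position and flag the rest", {
  tw <- toy_features()
  cb <- fit_codebooks(tw$features, tw$diseased, toy_grid(), seed = 1)
  expect_false(cb$degenerate[2])
  expect_gt(cb$separation[2], 5 * max(cb$separation[-2], na.rm = TRUE))
  expect_false(cb$low_confidence[2])
  # disease centroid is the brighter one at the planted position
  expect_gt(mean(cb$centroid_disease[2, ]), mean(cb$centroid_health[2, ]))
})

test_that("identical subjects in both classes refuse to train", {
  m <- matrix(0.3, 3, 9)
  feats <- list(m, m, m, m)
  expect_error(fit_codebooks(feats, c(TRUE, TRUE, FALSE, FALSE),
                             toy_grid(), seed = 1),
               "degenerate")
})

test_that("high-level transform hits its fixed points", {
  tw <- toy_features()
  cb <- fit_codebooks(tw$features, tw$diseased, toy_grid(), seed = 1)
  x <- tw$features[[1]]
  x[2, ] <- cb$centroid_disease[2, ]
  u <- transform_high_level(x, cb)
  expect_length(u, 3)
  expect_equal(u[2], 1)
  x[2, ] <- cb$centroid_health[2, ]
  expect_equal(transform_high_level(x, cb)[2], 0)
  mid <- (cb$centroid_disease[2, ] + cb$centroid_health[2, ]) / 2
  x[2, ] <- mid
  expect_equal(transform_high_level(x, cb)[2], 0.5, tolerance = 1e-9)
  expect_true(all(u >= 0 & u <= 1))
})

test_that("degenerate positions always emit 0.5", {
  tw <- toy_features()
  cb <- fit_codebooks(tw$features, tw$diseased, toy_grid(), seed = 1)
  if (!any(cb$degenerate)) {
    cb$degenerate[3] <- TRUE
  }
  u <- transform_high_level(tw$features[[1]], cb)
  expect_equal(u[cb$degenerate], rep(0.5, sum(cb$degenerate)))
})

test_that("a separable cohort trains to perfect accuracy and round-trips", {
  tw <- toy_features(n_per_class = 8, delta = 2)
  labels <- factor(ifelse(tw$diseased, "patient", "control"),
                   levels = c("patient", "control"))
  model <- gliohbm:::hbm_fit_core(tw$features, labels, toy_grid(),
                                  n_bins = 9, seed = 1)
  expect_equal(glance(model)$train_accuracy, 1)
  expect_true(all(model$train_scores >= 0 & model$train_scores <= 1))
  p <- file.path(tempdir(), "model.ghm")
  write_hbm(model, p)
  m2 <- read_hbm(p)
  probe <- toy_features(n_per_class = 3, seed = 99, delta = 2)$features
  expect_identical(gliohbm:::predict_core(model, probe),
                   gliohbm:::predict_core(m2, probe))
})

test_that("codebook fitting is invariant to subject order", {
  tw <- toy_features(n_per_class = 5, seed = 4)
  cb1 <- fit_codebooks(tw$features, tw$diseased, toy_grid(), seed = 1)
  perm <- c(7, 2, 9, 4, 1, 6, 3, 10, 5, 8)
  cb2 <- fit_codebooks(tw$features[perm], tw$diseased[perm], toy_grid(),
                       seed = 1)
  expect_equal(cb1$centroid_disease, cb2$centroid_disease,
               tolerance = 1e-8)
  expect_equal(cb1$centroid_health, cb2$centroid_health, tolerance = 1e-8)
})

test_that("end-to-end volume training predicts held-out phantoms", {
  cohort <- small_cohort(n = 5, seed = 31)
  model <- hbm_fit(cohort, cell_size = 16, seed = 1)
  # training subjects come back with their own labels (separable cohort)
  pr <- predict(model, cohort)
  expect_equal(as.character(pr$label), as.character(cohort$label))
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  held <- normalize_cohort(generate_detection_cohort(2, 2, seed = 77))
  pr2 <- predict(model, held)
  expect_true(all(pr2$score >= 0 & pr2$score <= 1))
  expect_error(predict(model, glio_volume(array(0.4, c(16, 16, 4)))),
               "re-register")
  # tidy/glance surfaces
  td <- tidy(model)
  expect_equal(nrow(td), model$grid$n_cells)
  expect_equal(glance(model)$n_subjects, 10)
})

test_that("single-class cohorts are rejected", {
  tw <- toy_features(n_per_class = 4)
  labels <- factor(rep("patient", 8), levels = c("patient", "control"))
  expect_error(gliohbm:::hbm_fit_core(tw$features, labels, toy_grid(),
                                      n_bins = 9),
               "two classes|per class")
})
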