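# Flat two-level test slice: bright disk on dark background plus noise,
# the regime the voxel classifier is specified against.
disk_slice <- function(radius = 12, center = c(32, 32), dim2 = c(64, 64),
                       fg = 0.8, bg = 0.2, noise = 0.02, seed = 1) {
  set.seed(seed)
  d <- sqrt(outer((seq_len(dim2[1]) - center[1])^2,
                  (seq_len(dim2[2]) - center[2])^2, `+`))
  sl <- matrix(bg, dim2[1], dim2[2]) + rnorm(prod(dim2), sd = noise)
  sl[d <= radius] <- fg + rnorm(sum(d <= radius), sd = noise)
  list(slice = sl, truth = d <= radius)
}

test_that("convex seed polygons rasterize exactly", {
  sq <- tibble::tibble(row = c(10, 10, 20, 20), col = c(10, 20, 10, 20),
                       label = factor(rep("glioma", 4),
                                      levels = c("glioma", "normal")))
  norm <- tibble::tibble(row = c(40, 40, 50), col = c(40, 50, 40),
                         label = factor(rep("normal", 3),
                                        levels = c("glioma", "normal")))
  reg <- build_seed_regions(rbind(sq, norm), c(64, 64))
  expect_equal(sum(reg$G), 121)            # 11 x 11 lattice square
  # oracle: count lattice points inside the hull directly
  expect_equal(sum(reg$G),
               sum(outer(1:64, 1:64, function(r, c)
                 r >= 10 & r <= 20 & c >= 10 & c <= 20)))
  tri <- reg$N
  expect_true(tri[40, 40] && tri[40, 50] && tri[50, 40])
  expect_equal(sum(tri), 66)               # triangular number 11*12/2
})

test_that("degenerate seed sets rasterize to voxels and segments", {
  one <- tibble::tibble(row = 5, col = 7,
                        label = factor("glioma",
                                       levels = c("glioma", "normal")))
  norm <- tibble::tibble(row = c(20, 20, 26), col = c(20, 26, 20),
                         label = factor(rep("normal", 3),
                                        levels = c("glioma", "normal")))
  reg <- build_seed_regions(rbind(one, norm), c(32, 32))
  expect_equal(which(reg$G), which(matrix(seq_len(32 * 32), 32) ==
                                     (7 - 1) * 32 + 5))
  expect_error(build_seed_regions(norm, c(32, 32)), "glioma seed")
  # collinear glioma seeds become a segment
  col3 <- tibble::tibble(row = c(5, 5, 5), col = c(3, 6, 9),
                         label = factor(rep("glioma", 3),
                                        levels = c("glioma", "normal")))
  reg2 <- build_seed_regions(rbind(col3, norm), c(32, 32))
  expect_equal(sum(reg2$G), 7)
  expect_true(all(reg2$G[5, 3:9]))
  # overlapping hulls are rejected
  overlap <- tibble::tibble(row = c(20, 21, 22), col = c(20, 21, 22),
                            label = factor(rep("glioma", 3),
                                           levels = c("glioma", "normal")))
  expect_error(build_seed_regions(rbind(overlap, norm), c(32, 32)),
               "overlap")
})

test_that("voxel classifier thresholds at the intensity midpoint", {
  ds <- disk_slice(noise = 0.05)
  G <- matrix(FALSE, 64, 64); G[28:36, 28:36] <- TRUE
  N <- matrix(FALSE, 64, 64); N[4:12, 4:12] <- TRUE
  clf <- train_voxel_classifier(G, N, ds$slice)
  probe <- function(val) {
    sl2 <- ds$slice; sl2[1, 1] <- val
    fm <- gliohbm:::voxel_features(sl2, 1)
    clf$classify(fm[1, , drop = FALSE])
  }
  expect_true(probe(0.75))                  # oracle: above midpoint 0.5
  expect_false(probe(0.25))
  expect_error(train_voxel_classifier(matrix(FALSE, 8, 8), N, ds$slice),
               "at least 5")
  # determinism on a probe grid
  fm <- gliohbm:::voxel_features(ds$slice, 1)
  c2 <- train_voxel_classifier(G, N, ds$slice)
  expect_identical(clf$classify(fm), c2$classify(fm))
})

test_that("expansion ring follows 8-connectivity and respects masks", {
  G <- matrix(FALSE, 9, 9); G[5, 5] <- TRUE
  N <- matrix(FALSE, 9, 9)
  brain <- matrix(TRUE, 9, 9)
  E <- expand_region(G, N, brain)
  expect_equal(sum(E), 8)
  expect_true(all(which(E) %in%
                    which(outer(1:9, 1:9, function(r, c)
                      abs(r - 5) <= 1 & abs(c - 5) <= 1) & !G)))
  # N voxels excluded; brain clipping
  N[4, 4:6] <- TRUE
  expect_equal(sum(expand_region(G, N, brain)), 5)
  brain[, 6:9] <- FALSE
  expect_equal(sum(expand_region(G, N, brain)), 3)
})

test_that("slice segmentation recovers a disk and honors the stop rule", {
  ds <- disk_slice(seed = 2)
  seeds <- tibble::tibble(
    slice = 1L, row = c(32, 29, 35, 6, 6, 12), col = c(32, 29, 35, 6, 12, 6),
    label = factor(c(rep("glioma", 3), rep("normal", 3)),
                   levels = c("glioma", "normal")))
  init <- build_seed_regions(seeds, c(64, 64))
  seg <- slice_segment(ds$slice, init$G, init$N,
                       brain = matrix(TRUE, 64, 64), threshold = 0.05,
                       store_states = TRUE)
  expect_gte(dice(seg$G_f, ds$truth), 0.95)
  expect_identical(seg$N_f, init$N)        # N never changes
  expect_false(any(seg$G_f & seg$N_f))
  # monotone growth across stored iterations
  for (j in seq_along(seg$states)[-1])
    expect_true(all(seg$states[[j - 1]] <= seg$states[[j]]))
  expect_true(all(seg$states[[1]] >= init$G))
  # stop-rule soundness
  if (seg$stopped_by == "ratio")
    expect_lte(seg$trace$ratio[nrow(seg$trace)], 0.05)
  expect_error(slice_segment(ds$slice, init$G, init$N, threshold = 0.2),
               "threshold")
  expect_error(slice_segment(ds$slice, matrix(FALSE, 64, 64), init$N),
               "empty")
})

test_that("a glioma-free ring terminates immediately at threshold 0.1", {
  # background-only 'lesion': seeds in plain background, classifier learns
  # the seed contrast, first ring is all background -> one iteration
  ds <- disk_slice(seed = 4)
  G <- matrix(FALSE, 64, 64); G[30:34, 30:34] <- ds$truth[30:34, 30:34]
  N <- matrix(FALSE, 64, 64); N[4:12, 4:12] <- TRUE
  # make the entire image background except the tiny G square
  sl <- matrix(0.2, 64, 64); sl[G] <- 0.8
  set.seed(5); sl <- sl + rnorm(64 * 64, sd = 0.01)
  seg <- slice_segment(sl, G, N, brain = matrix(TRUE, 64, 64),
                       threshold = 0.1)
  expect_equal(seg$iterations, 1L)
  expect_identical(seg$G_f, G)
  expect_equal(seg$stopped_by, "ratio")
})

test_that("iteration count and final size are monotone in the threshold", {
  ds <- disk_slice(seed = 6)
  seeds <- tibble::tibble(
    slice = 1L, row = c(32, 29, 35, 6, 6, 12), col = c(32, 29, 35, 6, 12, 6),
    label = factor(c(rep("glioma", 3), rep("normal", 3)),
                   levels = c("glioma", "normal")))
  init <- build_seed_regions(seeds, c(64, 64))
  sizes <- iters <- numeric(0)
  for (thr in c(0, 0.02, 0.05, 0.1)) {
    seg <- slice_segment(ds$slice, init$G, init$N,
                         brain = matrix(TRUE, 64, 64), threshold = thr)
    sizes <- c(sizes, sum(seg$G_f))
    iters <- c(iters, seg$iterations)
  }
  expect_true(all(diff(sizes) <= 0))
  expect_gte(iters[1], iters[4])
})

test_that("propagation onto an identical slice reduces to erosion", {
  ds <- disk_slice(seed = 8)
  G_f <- ds$truth
  N_f <- matrix(FALSE, 64, 64); N_f[2:14, 2:14] <- TRUE
  pr <- propagate_to_adjacent(G_f, N_f, ds$slice, ds$slice,
                              brain_next = matrix(TRUE, 64, 64))
  ero <- EBImage::erode(matrix(as.numeric(G_f), 64),
                        EBImage::makeBrush(3, "diamond")) > 0
  expect_gte(dice(pr$G_b, ero), 0.95)
  # a lesion-free adjacent slice kills the projection
  flat <- matrix(0.2, 64, 64) + matrix(rnorm(64 * 64, sd = 0.02), 64)
  pr2 <- propagate_to_adjacent(G_f, N_f, ds$slice, flat,
                               brain_next = matrix(TRUE, 64, 64))
  expect_equal(sum(pr2$G_b), 0)
  # erosion of a 1-voxel-thin region vanishes
  thin <- matrix(FALSE, 64, 64); thin[20, 10:40] <- TRUE
  sl_thin <- matrix(0.2, 64, 64); sl_thin[thin] <- 0.8
  set.seed(9); sl_thin <- sl_thin + rnorm(64 * 64, sd = 0.01)
  pr3 <- propagate_to_adjacent(thin, N_f, sl_thin, sl_thin,
                               brain_next = matrix(TRUE, 64, 64))
  expect_equal(sum(pr3$G_b), 0)
})

test_that("3D segmentation recovers an ellipsoid phantom", {
  ph <- seg_phantom(seed = 3)
  nv <- zscore_normalize(ph$volume, ph$brain_mask)
  res <- segment_volume(nv, seg_seeds(), brain_mask = ph$brain_mask,
                        threshold = 0.05, seed = 1)
  expect_gte(dice(res$mask, ph$lesion_mask), 0.85)
  expect_gte(dice(res$mask[, , 12], ph$lesion_mask[, , 12]), 0.95)
  # confinement: truth spans slices 6-18; allow 1 slice of bleed
  occupied <- which(apply(res$mask, 3, any))
  truth_span <- range(which(apply(ph$lesion_mask, 3, any)))
  expect_true(all(occupied >= truth_span[1] - 1 &
                    occupied <= truth_span[2] + 1))
  expect_true(all(res$mask <= ph$brain_mask))
  # per-slice masks equal the union invariant by construction; tidy output
  expect_equal(sum(tidy(res)$n_glioma), sum(res$mask))
  expect_equal(glance(res)$n_voxels, sum(res$mask))
  # determinism: bitwise-identical rerun
  res2 <- segment_volume(nv, seg_seeds(), brain_mask = ph$brain_mask,
                         threshold = 0.05, seed = 1)
  expect_identical(res$mask, res2$mask)
})

test_that("seed files round-trip the 0-based TSV convention", {
  p <- file.path(tempdir(), "seeds.tsv")
  write.table(data.frame(slice = 11, row = c(31, 29, 33, 15, 15, 23),
                         col = c(31, 27, 35, 15, 25, 15),
                         label = c(rep("glioma", 3), rep("normal", 3))),
              p, sep = "\t", row.names = FALSE, quote = FALSE)
  s <- read_seeds(p)
  expect_equal(unique(s$slice), 12L)
  expect_equal(s$row[1], 32L)
  write.table(data.frame(slice = 1, row = 1, col = 1, label = "tumor"),
              p, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_seeds(p), "glioma")
})
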