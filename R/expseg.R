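#' Read a seed-label file
#'
#' Seeds are clinician-labeled voxels on the representative slice (the one
#' containing the most tumor). The TSV has columns `slice`, `row`, `col`,
#' `label` with `label` in `{glioma, normal}` and 0-based indices; they are
#' converted to R's 1-based convention on read.
#'
#' @param path Path to the seeds TSV.
#' @return Tibble with 1-based `slice`, `row`, `col` and factor `label`.
#' @export
read_seeds <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("slice", "row", "col", "label") %in% names(tab)))
  if (!all(tab$label %in% c("glioma", "normal")))
    stop("seed labels must be 'glioma' or 'normal'", call. = FALSE)
  tibble(slice = tab$slice + 1L, row = tab$row + 1L, col = tab$col + 1L,
         label = factor(tab$label, levels = c("glioma", "normal")))
}

# Rasterize the filled convex hull of 2D points (rows x cols) into a
# logical matrix of dimension dim2. Degenerate inputs fall back to point /
# segment rasterization.
rasterize_hull <- function(pts, dim2) {
  m <- matrix(FALSE, dim2[1], dim2[2])
  pts <- unique(round(pts))
  if (nrow(pts) == 1) {
    m[pts[1, 1], pts[1, 2]] <- TRUE
    return(m)
  }
  hull_area <- function(p) {
    h <- p[grDevices::chull(p[, 2], p[, 1]), , drop = FALSE]
    if (nrow(h) < 3) return(0)
    x <- h[, 1]; y <- h[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  if (nrow(pts) == 2 || hull_area(pts) < 1e-9) {
    # collinear: rasterize the segment between the two extreme points
    o <- order(pts[, 1], pts[, 2])
    a <- pts[o[1], ]; b <- pts[o[nrow(pts)], ]
    nstep <- max(abs(b - a)) + 1
    rr <- round(seq(a[1], b[1], length.out = nstep))
    cc <- round(seq(a[2], b[2], length.out = nstep))
    m[cbind(rr, cc)] <- TRUE
    return(m)
  }
  h <- pts[grDevices::chull(pts[, 2], pts[, 1]), , drop = FALSE]
  rr <- max(1, min(pts[, 1])):min(dim2[1], max(pts[, 1]))
  cc <- max(1, min(pts[, 2])):min(dim2[2], max(pts[, 2]))
  grid <- expand.grid(row = rr, col = cc)
  inside <- pracma::inpolygon(grid$row, grid$col, h[, 1], h[, 2],
                              boundary = TRUE)
  m[cbind(grid$row, grid$col)[inside, , drop = FALSE]] <- TRUE
  m
}

#' Build initial glioma and normal regions from seed points
#'
#' The initial glioma region is the filled convex polygon of the glioma
#' seed voxels; the initial normal region is built the same way from the
#' normal seeds. Fewer than three points rasterize to a voxel or a
#' segment. Seeds outside the brain mask are dropped with a warning;
#' overlapping hulls are an error.
#'
#' @param seeds Seed tibble (1-based, as from [read_seeds()]) restricted to
#'   one slice, with >= 1 glioma and >= 3 normal points.
#' @param dim2 In-plane dimensions `c(rows, cols)` of the slice.
#' @param brain2 Optional 2D logical brain mask for the slice.
#' @return List with logical matrices `G` (initial glioma region) and `N`
#'   (initial normal region).
#' @export
build_seed_regions <- function(seeds, dim2, brain2 = NULL) {
  stopifnot(all(c("row", "col", "label") %in% names(seeds)))
  if (!is.null(brain2)) {
    inside <- brain2[cbind(seeds$row, seeds$col)]
    if (any(!inside)) {
      warning(sum(!inside), " seed(s) outside the brain mask dropped",
              call. = FALSE)
      seeds <- seeds[inside, ]
    }
  }
  g <- seeds[seeds$label == "glioma", ]
  n <- seeds[seeds$label == "normal", ]
  if (nrow(g) < 1) stop("need at least 1 glioma seed", call. = FALSE)
  if (nrow(n) < 3)
    stop("need at least 3 normal seeds (the normal polygon needs area)",
         call. = FALSE)
  if (any(seeds$row < 1 | seeds$row > dim2[1] |
          seeds$col < 1 | seeds$col > dim2[2]))
    stop("seed coordinates outside the image", call. = FALSE)
  G <- rasterize_hull(as.matrix(g[, c("row", "col")]), dim2)
  N <- rasterize_hull(as.matrix(n[, c("row", "col")]), dim2)
  if (any(G & N))
    stop("glioma and normal seed polygons overlap", call. = FALSE)
  list(G = G, N = N)
}

# Per-pixel voxel features of a 2D slice: intensity, mean and SD of the
# (2r+1)^2 neighborhood, windows clipped at the image border. Computed with
# integral images.
voxel_features <- function(sl, r = 1) {
  nr <- nrow(sl); nc <- ncol(sl)
  box <- function(a) {
    # (nr+1) x (nc+1) integral image; window sums via the 4-corner rule
    cs <- cbind(0, t(apply(rbind(0, apply(a, 2, cumsum)), 1, cumsum)))
    i1 <- pmax(seq_len(nr) - r, 1); i2 <- pmin(seq_len(nr) + r, nr)
    j1 <- pmax(seq_len(nc) - r, 1); j2 <- pmin(seq_len(nc) + r, nc)
    cs[i2 + 1, j2 + 1] - cs[i1, j2 + 1] - cs[i2 + 1, j1] + cs[i1, j1]
  }
  cnt <- box(matrix(1, nr, nc))
  s1 <- box(sl)
  s2 <- box(sl^2)
  mu <- s1 / cnt
  va <- pmax(s2 / cnt - mu^2, 0)
  cbind(intensity = as.vector(sl), nbhd_mean = as.vector(mu),
        nbhd_sd = as.vector(sqrt(va)))
}

#' Train a voxel classifier from glioma and normal regions
#'
#' Fits a binary linear classifier distinguishing glioma from normal
#' voxels from their environmental features. The feature map offers the
#' normalized intensity and the mean and SD of the (2r+1)^2 in-plane
#' neighborhood (border-clipped); the default uses the intensity alone,
#' because during iterative growth the window statistics of voxels just
#' outside a bright region inherit its brightness, which shifts the
#' recovered boundary outward by about the window radius and can make the
#' expansion self-sustaining. Window features can be switched on for
#' textured lesions.
#'
#' The default family is a balanced linear discriminant (equal priors):
#' its decision boundary is set by the class bulk statistics, so it stays
#' put as the growing glioma region absorbs boundary voxels. A
#' maximum-margin SVM places the boundary midway between the *closest*
#' points of the classes, which chases absorbed outliers during region
#' growth; it and a logistic alternative remain available. All families
#' are deterministic given the masks.
#'
#' @param G,N 2D logical masks of glioma / normal voxels (each >= 5
#'   voxels).
#' @param sl 2D numeric slice the masks live on.
#' @param r Neighborhood radius (default 1, i.e. 3x3).
#' @param seed Unused by the deterministic families; kept for interface
#'   stability.
#' @param family `"lda"` (balanced linear discriminant, default), `"svm"`
#'   (linear kernel, balanced class weights), or `"logistic"`.
#' @param features Columns of the feature map to use; default
#'   `"intensity"`.
#' @return A `voxel_classifier` with a `$classify(features)` function
#'   returning `TRUE` for glioma. Its input must have the columns named in
#'   `features` (as produced by the internal feature map).
#' @export
train_voxel_classifier <- function(G, N, sl, r = 1, seed = 1,
                                   family = c("lda", "svm", "logistic"),
                                   features = "intensity") {
  family <- match.arg(family)
  if (sum(G) < 5 || sum(N) < 5)
    stop("each class needs at least 5 voxels (glioma: ", sum(G),
         ", normal: ", sum(N), ")", call. = FALSE)
  fmap <- voxel_features(sl, r)[, features, drop = FALSE]
  X <- rbind(fmap[as.vector(G), , drop = FALSE],
             fmap[as.vector(N), , drop = FALSE])
  y <- factor(rep(c("glioma", "normal"), c(sum(G), sum(N))),
              levels = c("glioma", "normal"))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  # balanced classes: the glioma region grows across iterations while the
  # normal region is fixed, so raw class frequencies are not informative
  n <- length(y)
  cw <- c(glioma = n / (2 * sum(G)), normal = n / (2 * sum(N)))
  if (family == "lda") {
    fit <- suppressWarnings(MASS::lda(Xs, y, prior = c(0.5, 0.5)))
    classify <- function(feat) {
      fs <- scale(feat[, features, drop = FALSE], ctr, scl)
      as.character(stats::predict(fit, fs)$class) == "glioma"
    }
  } else if (family == "svm") {
    fit <- e1071::svm(x = Xs, y = y, kernel = "linear", cost = 1,
                      scale = FALSE, class.weights = cw)
    classify <- function(feat) {
      fs <- scale(feat[, features, drop = FALSE], ctr, scl)
      as.character(stats::predict(fit, fs)) == "glioma"
    }
  } else {
    w <- ifelse(y == "glioma", cw["glioma"], cw["normal"])
    fit <- suppressWarnings(stats::glm.fit(cbind(1, Xs), y == "glioma",
                                           weights = w,
                                           family = stats::binomial()))
    classify <- function(feat) {
      fs <- scale(feat[, features, drop = FALSE], ctr, scl)
      as.vector(stats::plogis(cbind(1, fs) %*% fit$coefficients)) >= 0.5
    }
  }
  structure(list(classify = classify, family = family, r = r,
                 features = features),
            class = "voxel_classifier")
}

#' Expand a glioma region by one morphological step
#'
#' One dilation of `G` with the 8-connected 3x3 structuring element, minus
#' `G`, the normal region, and anything outside the brain: the candidate
#' ring the voxel classifier will judge next.
#'
#' @param G Current glioma mask (2D logical, non-empty).
#' @param N Normal mask.
#' @param brain 2D logical brain mask.
#' @return Logical matrix `E`; may be empty, which terminates the
#'   iteration.
#' @export
expand_region <- function(G, N, brain) {
  stopifnot(any(G))
  dil <- EBImage::dilate(matrix(as.numeric(G), nrow = nrow(G)),
                         EBImage::makeBrush(3, "box")) > 0
  dil & !G & !N & brain
}

#' Expansion-segmentation of one slice
#'
#' Starting from the initial regions, iterates: expand the glioma region by
#' one morphological step ([expand_region()]), train a voxel classifier on
#' the current glioma region vs the initial normal region
#' ([train_voxel_classifier()]), keep the ring voxels classified glioma
#' (EG), and absorb them into the glioma region. Iteration stops when the
#' glioma fraction of the ring `count(EG)/count(E)` drops to `threshold`
#' or below (inclusive, so threshold 0 still terminates once EG is empty),
#' when the ring is empty, or at `max_iter`. The glioma region only ever
#' grows; the normal region never changes (N_f = N_b).
#'
#' @param sl 2D numeric slice (normalized intensities).
#' @param G_b,N_b Initial glioma / normal masks (disjoint; `G_b`
#'   non-empty).
#' @param brain 2D logical brain mask (defaults to `sl > 0`).
#' @param threshold Stop-rule hyperparameter in \[0, 0.1\].
#' @param max_iter Safety cap on expansion-segmentation iterations.
#' @param r,seed,family,features Passed to [train_voxel_classifier()].
#' @param store_states Keep a list of the glioma mask after every
#'   iteration (for growth audits).
#' @return List with `G_f`, `N_f`, `iterations`, `stopped_by` (one of
#'   `"ratio"`, `"empty_ring"`, `"max_iter"`), `trace` (tibble of per-
#'   iteration ring/glioma counts and ratios), and optionally `states`.
#' @export
slice_segment <- function(sl, G_b, N_b, brain = NULL, threshold = 0.05,
                          max_iter = 50, r = 1, seed = 1, family = "lda",
                          features = "intensity", store_states = FALSE) {
  if (!any(G_b)) stop("initial glioma region is empty", call. = FALSE)
  if (any(G_b & N_b)) stop("G_b and N_b overlap", call. = FALSE)
  if (threshold < 0 || threshold > 0.1)
    stop("`threshold` must be in [0, 0.1]", call. = FALSE)
  if (is.null(brain)) brain <- sl > 0
  G <- G_b
  trace <- list()
  states <- list()
  stopped_by <- "max_iter"
  j <- 0L
  while (j < max_iter) {
    j <- j + 1L
    E <- expand_region(G, N_b, brain)
    if (!any(E)) {
      stopped_by <- "empty_ring"
      j <- j - 1L
      break
    }
    clf <- train_voxel_classifier(G, N_b, sl, r = r, seed = seed,
                                  family = family, features = features)
    feat <- voxel_features(sl, r)[as.vector(E), , drop = FALSE]
    is_glioma <- clf$classify(feat)
    EG <- E
    EG[EG] <- is_glioma
    ratio <- sum(EG) / sum(E)
    G <- G | EG
    trace[[j]] <- tibble(iter = j, n_ring = sum(E), n_ring_glioma = sum(EG),
                         ratio = ratio, n_glioma = sum(G))
    if (store_states) states[[j]] <- G
    if (ratio <= threshold) {
      stopped_by <- "ratio"
      break
    }
  }
  out <- list(G_f = G, N_f = N_b, iterations = j, stopped_by = stopped_by,
              trace = if (length(trace)) dplyr::bind_rows(trace)
                      else tibble(iter = integer(), n_ring = integer(),
                                  n_ring_glioma = integer(),
                                  ratio = numeric(), n_glioma = integer()))
  if (store_states) out$states <- states
  out
}

#' Propagate final regions to an adjacent slice
#'
#' The final glioma and normal masks of slice i are projected voxel-for-
#' voxel onto slice i+1 (restricted to its brain region). A voxel
#' classifier trained on slice i's final regions then filters the
#' projections: voxels of the projected glioma region classified
#' non-glioma are removed, and voxels of the projected normal region
#' classified non-normal are removed. The filtered glioma region is
#' finally eroded once with a 3x3 cross to shed misclassified boundary
#' voxels, yielding the next slice's initial glioma region. An empty
#' result is a valid stop signal for that direction.
#'
#' @param G_f,N_f Final masks on the source slice.
#' @param sl_prev,sl_next 2D slices i and i+1 (normalized intensities).
#' @param brain_next Brain mask of slice i+1 (defaults to `sl_next > 0`).
#' @param r,seed,family,features Passed to [train_voxel_classifier()].
#' @param erosion_radius Erosion radius applied to the filtered glioma
#'   projection (default 1).
#' @return List with `G_b` and `N_b` for slice i+1 (possibly empty).
#' @export
propagate_to_adjacent <- function(G_f, N_f, sl_prev, sl_next,
                                  brain_next = NULL, r = 1, seed = 1,
                                  family = "lda", features = "intensity",
                                  erosion_radius = 1) {
  if (is.null(brain_next)) brain_next <- sl_next > 0
  empty <- matrix(FALSE, nrow(G_f), ncol(G_f))
  if (sum(G_f) < 5 || sum(N_f) < 5)
    return(list(G_b = empty, N_b = empty))
  G_p <- G_f & brain_next
  N_p <- N_f & brain_next
  clf <- train_voxel_classifier(G_f, N_f, sl_prev, r = r, seed = seed,
                                family = family, features = features)
  feat_next <- voxel_features(sl_next, r)
  if (any(G_p)) {
    keep <- clf$classify(feat_next[as.vector(G_p), , drop = FALSE])
    G_p[G_p] <- keep
  }
  if (any(N_p)) {
    keep <- !clf$classify(feat_next[as.vector(N_p), , drop = FALSE])
    N_p[N_p] <- keep
  }
  if (any(G_p) && erosion_radius > 0) {
    G_p <- EBImage::erode(matrix(as.numeric(G_p), nrow = nrow(G_p)),
                          EBImage::makeBrush(2 * erosion_radius + 1,
                                             "diamond")) > 0
  }
  list(G_b = G_p & !N_p, N_b = N_p)
}

#' Exp-seg: semi-automatic 3D lesion segmentation
#'
#' Segments the seeded representative slice with [slice_segment()], then
#' propagates the final regions slice by slice in both directions
#' ([propagate_to_adjacent()] followed by [slice_segment()]), stopping in a
#' direction when the propagated glioma region empties (or becomes too
#' small to train on) or the volume ends. The representative slice should
#' be the one containing the most tumor, which is interior, hence the
#' bidirectional sweep. Deterministic given the inputs. The result's 3D
#' lesion mask is the union of the per-slice final glioma regions.
#'
#' @param v Normalized [glio_volume()].
#' @param seeds Seed tibble (1-based `slice`, `row`, `col`, `label`), all
#'   on one slice; see [read_seeds()].
#' @param brain_mask Optional 3D logical brain mask (default: `v > 0`).
#' @param threshold Stop-rule hyperparameter in \[0, 0.1\] (default 0.05).
#' @param max_iter Per-slice iteration cap.
#' @param r Voxel-feature neighborhood radius.
#' @param erosion_radius Erosion applied during propagation.
#' @param seed RNG seed (interface stability; the pipeline is
#'   deterministic).
#' @param family Voxel classifier family, `"lda"` (default), `"svm"` or
#'   `"logistic"`.
#' @param features Voxel features used, see [train_voxel_classifier()].
#' @return An `expseg_result`: `mask` (3D logical lesion mask), `slices`
#'   (per-slice tibble with iteration counts, voxel counts and stop
#'   reasons), `seed_slice`, and `params`.
#' @export
segment_volume <- function(v, seeds, brain_mask = NULL, threshold = 0.05,
                           max_iter = 50, r = 1, erosion_radius = 1,
                           seed = 1, family = "lda",
                           features = "intensity") {
  stopifnot(inherits(v, "glio_volume"))
  if (length(unique(seeds$slice)) != 1)
    stop("all seeds must lie on one representative slice", call. = FALSE)
  s0 <- unique(seeds$slice)
  d <- dim(v$data)
  if (s0 < 1 || s0 > d[3]) stop("seed slice outside the volume", call. = FALSE)
  if (is.null(brain_mask)) brain_mask <- v$data > 0
  mask <- array(FALSE, dim = d)
  rows <- list()
  init <- build_seed_regions(seeds, d[1:2], brain_mask[, , s0])
  seg0 <- slice_segment(v$data[, , s0], init$G, init$N,
                        brain = brain_mask[, , s0], threshold = threshold,
                        max_iter = max_iter, r = r, seed = seed,
                        family = family, features = features)
  mask[, , s0] <- seg0$G_f
  rows[[1]] <- tibble(slice = s0, iterations = seg0$iterations,
                      n_glioma = sum(seg0$G_f), n_normal = sum(seg0$N_f),
                      stopped_by = seg0$stopped_by)
  for (step in c(1L, -1L)) {
    G_f <- seg0$G_f; N_f <- seg0$N_f
    i <- s0
    while (i + step >= 1 && i + step <= d[3]) {
      nxt <- i + step
      prop <- propagate_to_adjacent(G_f, N_f, v$data[, , i],
                                    v$data[, , nxt],
                                    brain_next = brain_mask[, , nxt],
                                    r = r, seed = seed, family = family,
                                    features = features,
                                    erosion_radius = erosion_radius)
      if (sum(prop$G_b) < 1 || sum(prop$N_b) < 5) break
      seg <- tryCatch(
        slice_segment(v$data[, , nxt], prop$G_b, prop$N_b,
                      brain = brain_mask[, , nxt], threshold = threshold,
                      max_iter = max_iter, r = r, seed = seed,
                      family = family, features = features),
        error = function(e) NULL)
      if (is.null(seg)) break
      mask[, , nxt] <- seg$G_f
      rows[[length(rows) + 1L]] <-
        tibble(slice = nxt, iterations = seg$iterations,
               n_glioma = sum(seg$G_f), n_normal = sum(seg$N_f),
               stopped_by = seg$stopped_by)
      G_f <- seg$G_f; N_f <- seg$N_f
      i <- nxt
    }
  }
  slices <- dplyr::arrange(dplyr::bind_rows(rows), .data$slice)
  structure(list(mask = mask, slices = slices, seed_slice = s0,
                 params = list(threshold = threshold, max_iter = max_iter,
                               r = r, erosion_radius = erosion_radius,
                               seed = seed, family = family,
                               features = features),
                 id = v$id,
                 version = as.character(utils::packageVersion("gliohbm"))),
            class = "expseg_result")
}

#' @export
print.expseg_result <- function(x, ...) {
  cat(sprintf("<expseg_result '%s'> %d lesion voxels on %d slice(s) (seed slice %d, threshold %g)\n",
              x$id, sum(x$mask), nrow(x$slices), x$seed_slice,
              x$params$threshold))
  invisible(x)
}

#' Tidy an Exp-seg result
#'
#' @param x An `expseg_result`.
#' @param ... Unused.
#' @return The per-slice tibble: `slice`, `iterations`, `n_glioma`,
#'   `n_normal`, `stopped_by`.
#' @export
tidy.expseg_result <- function(x, ...) x$slices

#' Glance at an Exp-seg result
#'
#' @param x An `expseg_result`.
#' @param ... Unused.
#' @return One-row tibble: lesion voxel total, slice span, seed slice,
#'   threshold.
#' @export
glance.expseg_result <- function(x, ...) {
  tibble(n_voxels = sum(x$mask),
         n_slices = nrow(x$slices),
         first_slice = min(x$slices$slice),
         last_slice = max(x$slices$slice),
         seed_slice = x$seed_slice,
         threshold = x$params$threshold)
}

#' Write an Exp-seg result
#'
#' Emits the lesion mask as a uint8 NIfTI plus a JSON report with the
#' per-slice counts and the parameters used.
#'
#' @param x An `expseg_result`.
#' @param path Output path without extension.
#' @param spacing Voxel spacing for the mask file.
#' @return Invisibly, the two paths.
#' @export
write_segmentation <- function(x, path, spacing = c(1, 1, 1)) {
  nii <- paste0(path, ".nii.gz"); json <- paste0(path, ".json")
  write_volume(x$mask, nii, spacing = spacing)
  jsonlite::write_json(list(subject = x$id, seed_slice = x$seed_slice,
                            params = x$params, version = x$version,
                            slices = x$slices, n_voxels = sum(x$mask)),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(nii, json))
}
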