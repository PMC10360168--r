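#' Fit per-position FCM codebooks
#'
#' For every cell position of the grid, pools that position's HOG
#' descriptors across the training subjects, clusters them into two fuzzy
#' clusters, and tags the clusters disease-/health-related from the labels
#' ([assign_cluster_roles()]). Clustering is initialized from the two
#' class-conditional descriptor means (deterministic, role-aligned starts),
#' falling back to a seeded farthest-point start when the class means
#' coincide. Positions where clustering degenerates (fewer than two
#' distinct descriptors, or coincident centroids) are flagged and later
#' emit a constant membership of 0.5 so the feature length stays stable.
#'
#' @param features_list List of descriptor matrices (cells x bins), one per
#'   training subject, all on the same grid and in the same cell order.
#' @param diseased Logical vector, one per subject.
#' @param grid The shared [partition_cells()] grid.
#' @param m Fuzzifier (> 1).
#' @param tol,max_iter FCM convergence controls.
#' @param seed Master seed for degenerate-initialization fallbacks.
#' @return An `fcm_codebooks` object: centroid matrices
#'   `centroid_disease` / `centroid_health` (positions x bins), logical
#'   `degenerate` and `low_confidence` flags, `mass_ratio`, `separation`
#'   (centroid distance), plus `grid` and `m`.
#' @export
fit_codebooks <- function(features_list, diseased, grid, m = 2,
                          tol = 1e-6, max_iter = 100, seed = 1) {
  stopifnot(length(features_list) == length(diseased))
  if (all(diseased) || !any(diseased))
    stop("training cohort must contain both classes", call. = FALSE)
  dims <- vapply(features_list, dim, integer(2))
  if (any(dims[1, ] != grid$n_cells) || length(unique(dims[2, ])) != 1)
    stop("inconsistent feature matrices across subjects", call. = FALSE)
  P <- grid$n_cells
  d <- dims[2, 1]
  cd <- matrix(NA_real_, P, d)
  ch <- matrix(NA_real_, P, d)
  degenerate <- logical(P)
  low_conf <- logical(P)
  mass_ratio <- rep(NA_real_, P)
  # positions x subjects arrangement: big array for speed
  arr <- array(unlist(features_list, use.names = FALSE),
               dim = c(P, d, length(features_list)))
  for (p in seq_len(P)) {
    pts <- t(arr[p, , ])                      # subjects x bins
    upts <- unique(pts)
    if (nrow(upts) < 2) { degenerate[p] <- TRUE; next }
    mu_d <- colMeans(pts[diseased, , drop = FALSE])
    mu_h <- colMeans(pts[!diseased, , drop = FALSE])
    init <- rbind(mu_d, mu_h)
    if (sqrt(sum((mu_d - mu_h)^2)) < 1e-12)
      init <- fcm_farthest_init(pts, 2, derive_seed(seed, p))
    fit <- fcm_cluster(pts, c = 2, m = m, tol = tol, max_iter = max_iter,
                       init = init)
    sep <- sqrt(sum((fit$centroids[1, ] - fit$centroids[2, ])^2))
    if (sep < 1e-8) { degenerate[p] <- TRUE; next }
    roles <- assign_cluster_roles(fit$memberships, diseased)
    cd[p, ] <- fit$centroids[roles$disease, ]
    ch[p, ] <- fit$centroids[roles$health, ]
    low_conf[p] <- roles$low_confidence
    mass_ratio[p] <- roles$mass_ratio
  }
  if (all(degenerate))
    stop("all cell positions degenerate: classes are indistinguishable",
         call. = FALSE)
  separation <- sqrt(rowSums((cd - ch)^2))
  structure(list(centroid_disease = cd, centroid_health = ch,
                 degenerate = degenerate, low_confidence = low_conf,
                 mass_ratio = mass_ratio, separation = separation,
                 grid = grid, m = m),
            class = "fcm_codebooks")
}

#' Transform a subject's descriptors into high-level features
#'
#' Per cell position, the high-level feature is the subject's fuzzy
#' membership to the disease-related centroid under the codebook's
#' fuzzifier: u = 1 / (1 + (d_disease/d_health)^(2/(m-1))). A descriptor
#' equal to the disease centroid yields 1, one equidistant from both
#' centroids yields 0.5, and degenerate positions always emit 0.5. The two
#' memberships sum to 1, so the disease membership alone carries the full
#' information and keeps the feature length equal to the number of cells.
#'
#' @param features A descriptor matrix (cells x bins) or a `cell_hog`
#'   tibble from [extract_subject_features()].
#' @param codebooks An [fit_codebooks()] object covering the same grid.
#' @return Numeric vector of disease memberships in \[0, 1\], ordered by
#'   (slice, row, col).
#' @export
transform_high_level <- function(features, codebooks) {
  x <- if (is.matrix(features)) features else descriptor_matrix(features)
  P <- codebooks$grid$n_cells
  if (nrow(x) != P)
    stop("feature matrix has ", nrow(x), " cells but codebooks cover ", P,
         call. = FALSE)
  expo <- 2 / (codebooks$m - 1)
  out <- rep(0.5, P)
  ok <- !codebooks$degenerate
  dd <- rowSums((x[ok, , drop = FALSE] -
                   codebooks$centroid_disease[ok, , drop = FALSE])^2)
  dh <- rowSums((x[ok, , drop = FALSE] -
                   codebooks$centroid_health[ok, , drop = FALSE])^2)
  u <- ifelse(dd == 0 & dh == 0, 0.5,
       ifelse(dd == 0, 1,
       ifelse(dh == 0, 0, 1 / (1 + (dd / dh)^(expo / 2)))))
  out[ok] <- u
  out
}

# Platt sigmoid calibration: fit p = plogis(a*f + b) to labels by
# regularized maximum likelihood (smoothed targets), deterministically.
platt_fit <- function(f, positive) {
  np <- sum(positive); nn <- sum(!positive)
  t <- ifelse(positive, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    p <- stats::plogis(par[1] * f + par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  grad <- function(par) {
    p <- stats::plogis(par[1] * f + par[2])
    r <- p - t
    c(sum(r * f), sum(r))
  }
  fit <- stats::optim(c(1, 0), nll, grad, method = "BFGS",
                      control = list(maxit = 200))
  list(a = fit$par[1], b = fit$par[2])
}

# Core trainer on precomputed descriptor matrices. Returns an hbm_model
# without volume data.
hbm_fit_core <- function(features_list, labels, grid, n_bins, m = 2,
                         cost = 1, kernel = "linear", seed = 1,
                         tol = 1e-6, max_iter = 100) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("labels must have exactly two classes", call. = FALSE)
  positive <- levels(labels)[1]
  diseased <- labels == positive
  if (sum(diseased) < 2 || sum(!diseased) < 2)
    stop("need at least 2 subjects per class", call. = FALSE)
  codebooks <- fit_codebooks(features_list, diseased, grid, m = m,
                             tol = tol, max_iter = max_iter, seed = seed)
  X <- t(vapply(features_list, transform_high_level, numeric(grid$n_cells),
                codebooks = codebooks))
  svm_fit <- e1071::svm(x = X, y = labels, kernel = kernel, cost = cost,
                        scale = FALSE)
  dec <- as.numeric(attr(stats::predict(svm_fit, X, decision.values = TRUE),
                         "decision.values"))
  flip <- mean(dec[diseased]) < mean(dec[!diseased])
  if (flip) dec <- -dec
  platt <- platt_fit(dec, diseased)
  score <- stats::plogis(platt$a * dec + platt$b)
  structure(list(grid = grid, codebooks = codebooks, svm = svm_fit,
                 platt = platt, flip = flip,
                 positive = positive, negative = levels(labels)[2],
                 n_bins = n_bins, m = m, cost = cost, kernel = kernel,
                 seed = seed, n_subjects = length(labels),
                 train_scores = score, train_labels = labels,
                 version = as.character(utils::packageVersion("gliohbm"))),
            class = "hbm_model")
}

#' Train the two-level HBM classifier
#'
#' Full first- and second-level training: partitions each (normalized)
#' volume into cells, extracts one HOG descriptor per cell, fits one
#' two-cluster FCM codebook per cell position ([fit_codebooks()]),
#' transforms every subject into the vector of per-position
#' disease-membership features, and trains a linear-kernel SVM on those
#' vectors. Decision values are mapped to \[0, 1\] scores by a Platt-style
#' sigmoid fitted on the training set, so a score >= 0.5 predicts the
#' positive class. Deterministic for a fixed seed.
#'
#' The first factor level of `label` is the positive (disease / high-grade)
#' class.
#'
#' @param cohort Tibble with columns `label` (two-level factor) and
#'   `volume` (list of normalized [glio_volume()]s of identical shape),
#'   e.g. from [generate_detection_cohort()] after [normalize_cohort()].
#' @param cell_size Cell side in voxels (classification sweeps 10-20;
#'   default 16).
#' @param n_bins,epsilon HOG parameters, see [compute_cell_hog()].
#' @param m FCM fuzzifier.
#' @param cost,kernel SVM parameters (default linear kernel, C = 1).
#' @param seed Seed for degenerate-initialization fallbacks.
#' @return An `hbm_model` object; see [predict.hbm_model()],
#'   [tidy.hbm_model()], [glance.hbm_model()].
#' @export
hbm_fit <- function(cohort, cell_size = 16, n_bins = 9, epsilon = 1e-6,
                    m = 2, cost = 1, kernel = "linear", seed = 1) {
  stopifnot(is.data.frame(cohort), all(c("label", "volume") %in% names(cohort)))
  vols <- cohort$volume
  ref_mask <- Reduce(`|`, lapply(vols, function(v) v$data > 0))
  grid <- partition_cells(vols[[1]], cell_size, mask = ref_mask)
  feats <- lapply(vols, function(v)
    descriptor_matrix(extract_subject_features(v, grid, n_bins, epsilon)))
  model <- hbm_fit_core(feats, cohort$label, grid, n_bins, m = m,
                        cost = cost, kernel = kernel, seed = seed)
  model$epsilon <- epsilon
  model
}

# Score precomputed descriptor matrices with a fitted model.
predict_core <- function(model, features_list) {
  X <- t(vapply(features_list, transform_high_level,
                numeric(model$grid$n_cells), codebooks = model$codebooks))
  dec <- as.numeric(attr(stats::predict(model$svm, X,
                                        decision.values = TRUE),
                         "decision.values"))
  if (model$flip) dec <- -dec
  stats::plogis(model$platt$a * dec + model$platt$b)
}

#' Predict glioma status for new volumes
#'
#' Runs the fitted pipeline (cell partition, HOG, codebook transform,
#' calibrated SVM) on new normalized volumes. A score of exactly 0.5 is
#' called positive: in a screening context a tie goes to sensitivity.
#'
#' @param object An `hbm_model` from [hbm_fit()].
#' @param newdata A cohort tibble with a `volume` list-column, a single
#'   [glio_volume()], or a list of volumes. Shapes must match the model's
#'   grid (volumes are assumed co-registered).
#' @param ... Unused.
#' @return Tibble with `subject_id`, `score` (positive-class confidence in
#'   \[0, 1\]) and `label`.
#' @export
predict.hbm_model <- function(object, newdata, ...) {
  vols <- if (inherits(newdata, "glio_volume")) list(newdata)
    else if (is.data.frame(newdata)) newdata$volume
    else newdata
  for (v in vols)
    if (!identical(dim(v$data), object$grid$dim))
      stop("volume '", v$id, "' has dimensions ",
           paste(dim(v$data), collapse = "x"),
           " but the model expects ", paste(object$grid$dim, collapse = "x"),
           "; re-register the input to the training grid", call. = FALSE)
  eps <- if (is.null(object$epsilon)) 1e-6 else object$epsilon
  feats <- lapply(vols, function(v)
    descriptor_matrix(extract_subject_features(v, object$grid,
                                               object$n_bins, eps)))
  score <- predict_core(object, feats)
  tibble(subject_id = vapply(vols, function(v) v$id, character(1)),
         score = score,
         label = factor(ifelse(score >= 0.5, object$positive,
                               object$negative),
                        levels = c(object$positive, object$negative)))
}

#' @export
print.hbm_model <- function(x, ...) {
  cat(sprintf(paste0("<hbm_model> %s vs %s | %d subjects | cell %d, %d bins, ",
                     "m = %g, %s SVM C = %g\n"),
              x$positive, x$negative, x$n_subjects, x$grid$cell_size,
              x$n_bins, x$m, x$kernel, x$cost))
  cat(sprintf("  %d cell positions (%d degenerate, %d low-confidence)\n",
              x$grid$n_cells, sum(x$codebooks$degenerate),
              sum(x$codebooks$low_confidence)))
  invisible(x)
}

#' Tidy a fitted HBM model
#'
#' One row per cell position with the codebook diagnostics: centroid
#' separation, disease-mass ratio, and degeneracy/low-confidence flags.
#'
#' @param x An `hbm_model`.
#' @param ... Unused.
#' @return A tibble with columns `slice`, `row`, `col`, `separation`,
#'   `mass_ratio`, `degenerate`, `low_confidence`.
#' @export
tidy.hbm_model <- function(x, ...) {
  g <- x$grid
  idx <- expand.grid(col = seq_len(g$n_cols), row = seq_len(g$n_rows),
                     slice = g$slices)
  tibble(slice = idx$slice, row = idx$row, col = idx$col,
         separation = x$codebooks$separation,
         mass_ratio = x$codebooks$mass_ratio,
         degenerate = x$codebooks$degenerate,
         low_confidence = x$codebooks$low_confidence)
}

#' Glance at a fitted HBM model
#'
#' @param x An `hbm_model`.
#' @param ... Unused.
#' @return One-row tibble: subjects, cell geometry, degenerate-position
#'   count, and training accuracy.
#' @export
glance.hbm_model <- function(x, ...) {
  pred_pos <- x$train_scores >= 0.5
  truth_pos <- x$train_labels == x$positive
  tibble(n_subjects = x$n_subjects,
         n_positions = x$grid$n_cells,
         n_degenerate = sum(x$codebooks$degenerate),
         cell_size = x$grid$cell_size,
         n_bins = x$n_bins, m = x$m, cost = x$cost,
         train_accuracy = mean(pred_pos == truth_pos))
}

#' Save / load a fitted HBM model
#'
#' The archive holds the grid, all codebooks, the SVM parameters, the Platt
#' calibration, and a format version; reloading reproduces predictions
#' exactly.
#'
#' @param model An `hbm_model`.
#' @param path Archive path (`.ghm` by convention).
#' @return `write_hbm` returns `path` invisibly; `read_hbm` returns the
#'   model.
#' @export
write_hbm <- function(model, path) {
  stopifnot(inherits(model, "hbm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_hbm
#' @export
read_hbm <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hbm_model"))
    stop("'", path, "' is not an HBM model archive", call. = FALSE)
  model
}

#' Normalize every volume of a cohort
#'
#' Applies [zscore_normalize()] subject by subject, using the cohort's
#' `brain_mask` column when present and [compute_brain_mask()] otherwise.
#'
#' @param cohort Cohort tibble with a `volume` list-column.
#' @param quantile Mask quantile for [compute_brain_mask()] fallback.
#' @return The cohort with `volume` replaced by normalized volumes.
#' @export
normalize_cohort <- function(cohort, quantile = 0.5) {
  has_mask <- "brain_mask" %in% names(cohort)
  cohort$volume <- lapply(seq_len(nrow(cohort)), function(i)
    zscore_normalize(cohort$volume[[i]],
                     mask = if (has_mask) cohort$brain_mask[[i]]
                            else compute_brain_mask(cohort$volume[[i]],
                                                    quantile)))
  cohort
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
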