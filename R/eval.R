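#' Build a stratified repeated cross-validation plan
#'
#' Each run shuffles the cohort with a run-specific seed derived from the
#' master seed, then deals each class round-robin into the k folds, so the
#' class proportion of every fold matches the cohort's to within one
#' subject. Folds partition the cohort within each run; the plan is fully
#' deterministic given `seed`.
#'
#' @param labels Class label per subject (factor or vector).
#' @param k Number of folds (>= 2; every class must have >= k members).
#' @param runs Number of shuffled repetitions.
#' @param seed Master seed.
#' @return A `cv_plan` tibble with columns `run`, `index` (subject index),
#'   `fold`, and attributes `k`, `runs`, `seed`.
#' @export
make_cv_plan <- function(labels, k = 10, runs = 10, seed = 1) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  counts <- table(labels)
  if (any(counts < k))
    stop("every class needs >= k members; class '",
         names(counts)[which.min(counts)], "' has ", min(counts),
         " < k = ", k, call. = FALSE)
  plan <- lapply(seq_len(runs), function(r) {
    perm <- with_seed(derive_seed(seed, r), sample.int(n))
    fold <- integer(n)
    for (cl in levels(labels)) {
      members <- perm[labels[perm] == cl]
      fold[members] <- rep_len(seq_len(k), length(members))
    }
    tibble(run = r, index = seq_len(n), fold = fold)
  })
  out <- dplyr::bind_rows(plan)
  attr(out, "k") <- as.integer(k)
  attr(out, "runs") <- as.integer(runs)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("cv_plan", class(out))
  out
}

#' Classification metrics from confusion counts
#'
#' ACC = (TP + TN) / n, SEN = TP / (TP + FN), SPE = TN / (TN + FP). A zero
#' denominator raises an error naming the undefined metric.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return One-row tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n == 0) stop("accuracy undefined: no subjects", call. = FALSE)
  if (tp + fn == 0)
    stop("sensitivity undefined: no positive subjects", call. = FALSE)
  if (tn + fp == 0)
    stop("specificity undefined: no negative subjects", call. = FALSE)
  tibble(accuracy = (tp + tn) / n,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney probability that a
#' random positive outscores a random negative, with ties counting 1/2.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param positive Logical vector (or two-level factor whose first level is
#'   positive).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, positive) {
  if (is.factor(positive)) positive <- positive == levels(positive)[1]
  positive <- as.logical(positive)
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)           # midranks handle ties as 1/2
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Run a repeated stratified cross-validation experiment
#'
#' Mirrors the published evaluation design at phantom scale: for each run
#' of the plan, the two-level HBM pipeline is refit from scratch on every
#' training fold — grid slice selection, FCM codebooks, and the SVM all see
#' training-fold subjects only, so no information leaks from the test fold
#' — and out-of-fold scores are pooled per run into ACC/SEN/SPE/AUC.
#' Supports sweeping the cell size as the published experiments do.
#' Per-subject HOG descriptors depend only on the image, never on labels
#' or fold membership, so they are computed once and reused across folds.
#'
#' @param cohort Cohort tibble (`label` + `volume` list-column). Volumes
#'   should already be normalized (see [normalize_cohort()]); the first
#'   factor level of `label` is the positive class.
#' @param k,runs,seed Passed to [make_cv_plan()] (defaults 5 x 5 at phantom
#'   scale; the published design is 10 x 10).
#' @param cell_sizes Integer vector of cell sizes to sweep (default 16).
#' @param n_bins,epsilon,m,cost,kernel Pipeline parameters, as in
#'   [hbm_fit()].
#' @param keep_models Keep the per-fold codebooks (for audits); stored in
#'   `attr(result, "fold_models")`.
#' @return A `cv_report` tibble: one row per (cell_size, run) with
#'   `accuracy`, `sensitivity`, `specificity`, `auc`. [glance.cv_report()]
#'   reduces it to mean (SD) per cell size.
#' @export
run_cv_experiment <- function(cohort, k = 5, runs = 5, seed = 1,
                              cell_sizes = 16, n_bins = 9, epsilon = 1e-6,
                              m = 2, cost = 1, kernel = "linear",
                              keep_models = FALSE) {
  stopifnot(is.data.frame(cohort), all(c("label", "volume") %in% names(cohort)))
  labels <- droplevels(as.factor(cohort$label))
  stopifnot(nlevels(labels) == 2)
  positive <- levels(labels)[1]
  plan <- make_cv_plan(labels, k = k, runs = runs, seed = seed)
  vols <- cohort$volume
  support <- lapply(vols, function(v) apply(v$data > 0, 3, any))
  rows <- list()
  fold_models <- list()
  for (cs in cell_sizes) {
    full_grid <- partition_cells(vols[[1]], cs)
    feats <- lapply(vols, function(v)
      descriptor_matrix(extract_subject_features(v, full_grid, n_bins,
                                                 epsilon)))
    slice_of_row <- rep(full_grid$slices,
                        each = full_grid$n_rows * full_grid$n_cols)
    for (r in seq_len(runs)) {
      fold <- plan$fold[plan$run == r][order(plan$index[plan$run == r])]
      score <- numeric(length(labels))
      pred_pos <- logical(length(labels))
      for (f in seq_len(k)) {
        tr <- which(fold != f)
        te <- which(fold == f)
        keep_slices <- which(Reduce(`|`, support[tr]))
        rows_keep <- slice_of_row %in% keep_slices
        grid_f <- full_grid
        grid_f$slices <- intersect(full_grid$slices, keep_slices)
        grid_f$n_cells <- grid_f$n_rows * grid_f$n_cols *
          length(grid_f$slices)
        sub <- function(i) feats[[i]][rows_keep, , drop = FALSE]
        model <- hbm_fit_core(lapply(tr, sub), labels[tr], grid_f, n_bins,
                              m = m, cost = cost, kernel = kernel,
                              seed = derive_seed(seed, 1000 * r + f))
        s <- predict_core(model, lapply(te, sub))
        score[te] <- s
        pred_pos[te] <- s >= 0.5
        if (keep_models)
          fold_models[[sprintf("cs%d_run%d_fold%d", cs, r, f)]] <-
            model$codebooks
      }
      truth_pos <- labels == positive
      cm <- confusion_metrics(tp = sum(pred_pos & truth_pos),
                              fp = sum(pred_pos & !truth_pos),
                              tn = sum(!pred_pos & !truth_pos),
                              fn = sum(!pred_pos & truth_pos))
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble(cell_size = cs, run = r), cm,
                         tibble(auc = compute_auc(score, truth_pos)))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "k") <- as.integer(k)
  attr(out, "runs") <- as.integer(runs)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "positive") <- positive
  if (keep_models) attr(out, "fold_models") <- fold_models
  class(out) <- c("cv_report", class(out))
  out
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Long tibble: `cell_size`, `run`, `metric`, `value`.
#' @export
tidy.cv_report <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x),
                      c("accuracy", "sensitivity", "specificity", "auc"),
                      names_to = "metric", values_to = "value")
}

#' Summarize a cross-validation report
#'
#' Mean and SD of each metric over runs, one row per cell size, mirroring
#' the usual "mean (SD)" table layout. The SD is the population SD over
#' runs.
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with columns `cell_size`, `<metric>_mean`, `<metric>_sd`.
#' @export
glance.cv_report <- function(x, ...) {
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$cell_size) |>
    dplyr::summarise(dplyr::across(
      c("accuracy", "sensitivity", "specificity", "auc"),
      list(mean = mean, sd = pop_sd), .names = "{.col}_{.fn}"),
      .groups = "drop")
}

#' Write a CV report to TSV and JSON
#'
#' @param x A `cv_report`.
#' @param path Output path without extension; `.tsv` and `.json` files are
#'   written.
#' @return Invisibly, the two paths.
#' @export
write_cv_report <- function(x, path) {
  summ <- glance(x)
  tsv <- paste0(path, ".tsv"); json <- paste0(path, ".json")
  utils::write.table(summ, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(summary = summ,
                            per_run = tibble::as_tibble(x),
                            k = attr(x, "k"), runs = attr(x, "runs"),
                            seed = attr(x, "seed")),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, json))
}
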