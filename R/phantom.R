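#' @importFrom tibble tibble
#' @importFrom rlang .data
NULL

# Derive a reproducible child seed from a master seed and an index, kept
# inside 32-bit integer range.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1103515245 + as.numeric(index) * 12345 +
                12345) %% 2147483647)
}

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Separable Gaussian smoothing of a 3D array, edge kernels renormalized.
smooth3d <- function(a, sigma) {
  stopifnot(length(sigma) == 3L)
  smooth_axis <- function(arr, axis, s) {
    if (s <= 0) return(arr)
    n <- dim(arr)[axis]
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- (i - r):(i + r)
      keep <- idx >= 1 & idx <= n
      m[i, idx[keep]] <- k[keep] / sum(k[keep])
    }
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(arr, perm)
    d <- dim(ap)
    out <- array(m %*% matrix(ap, nrow = d[1]), dim = d)
    aperm(out, order(perm))
  }
  a <- smooth_axis(a, 1L, sigma[1])
  a <- smooth_axis(a, 2L, sigma[2])
  smooth_axis(a, 3L, sigma[3])
}

# Normalized ellipsoid distance field: value <= 1 inside the ellipsoid.
ellipsoid_distance <- function(shape, center, semi_axes) {
  gx <- (seq_len(shape[1]) - center[1]) / semi_axes[1]
  gy <- (seq_len(shape[2]) - center[2]) / semi_axes[2]
  gz <- (seq_len(shape[3]) - center[3]) / semi_axes[3]
  d2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  sqrt(d2)
}

#' Generate one phantom MRI subject
#'
#' Builds a T2-FLAIR-like phantom: an ellipsoidal "head" of smooth tissue
#' intensity (a low-frequency Gaussian random field) with additive Gaussian
#' noise, and optionally a hyperintense ellipsoidal lesion whose edge is
#' softened by a sigmoid over the normalized distance to the ellipsoid
#' surface, so segmentation faces a nontrivial boundary. The emitted
#' `lesion_mask` is rasterized from exactly the same ellipsoid predicate used
#' to paint the intensities. Deterministic given `seed`.
#'
#' @param shape 3D dimensions, default `c(64, 64, 24)` (desk-scale stand-in
#'   for a whole-brain axial acquisition).
#' @param head_semiaxes,head_center Ellipsoid defining the brain region, in
#'   voxels; defaults scale with `shape`.
#' @param background_mean Mean tissue intensity (arbitrary units).
#' @param texture_sd Standard deviation of the smooth background texture.
#' @param texture_sigma Per-axis Gaussian smoothing scale of the texture
#'   field, in voxels.
#' @param noise_sd Additive white Gaussian noise SD. Lesion contrast is
#'   naturally expressed in multiples of this.
#' @param lesion `NULL` for a control, or a list with elements `center`,
#'   `semi_axes` (voxels), `contrast` (intensity increase, > 0: tumors are
#'   hyperintense on T2-FLAIR), and optional `softness` (sigmoid edge width
#'   in normalized distance units, default 0.08).
#' @param seed Integer RNG seed.
#' @param id Subject identifier.
#' @return A list with `volume` ([glio_volume()]), `brain_mask`,
#'   `lesion_mask` (logical arrays; the lesion mask is all-`FALSE` for
#'   controls), and `label` (`"patient"` or `"control"`).
#' @export
generate_phantom <- function(shape = c(64, 64, 24),
                             head_semiaxes = pmax(3, round(shape * c(0.42, 0.42, 0.46))),
                             head_center = (shape + 1) / 2,
                             background_mean = 100,
                             texture_sd = 8,
                             texture_sigma = c(3, 3, 1.5),
                             noise_sd = 5,
                             lesion = NULL,
                             seed = 1,
                             id = "phantom") {
  stopifnot(length(shape) == 3L, all(shape >= 8))
  head_d <- ellipsoid_distance(shape, head_center, head_semiaxes)
  brain_mask <- head_d <= 1
  lesion_mask <- array(FALSE, dim = shape)
  bump <- NULL
  if (!is.null(lesion)) {
    stopifnot(is.list(lesion), !is.null(lesion$center),
              !is.null(lesion$semi_axes), !is.null(lesion$contrast))
    if (lesion$contrast <= 0)
      stop("lesion contrast must be > 0 (hyperintense on T2-FLAIR)",
           call. = FALSE)
    softness <- if (is.null(lesion$softness)) 0.08 else lesion$softness
    ld <- ellipsoid_distance(shape, lesion$center, lesion$semi_axes)
    lesion_mask <- ld <= 1
    if (any(lesion_mask & !brain_mask))
      stop("lesion extends outside the head region", call. = FALSE)
    if (!any(lesion_mask))
      stop("lesion rasterizes to zero voxels", call. = FALSE)
    bump <- lesion$contrast * stats::plogis((1 - ld) / softness)
  }
  img <- with_seed(seed, {
    field <- smooth3d(array(stats::rnorm(prod(shape)), dim = shape),
                      texture_sigma)
    field <- field / stats::sd(field) * texture_sd
    x <- array(0, dim = shape)
    x[brain_mask] <- background_mean + field[brain_mask]
    if (!is.null(bump)) x[brain_mask] <- x[brain_mask] + bump[brain_mask]
    x[brain_mask] <- x[brain_mask] +
      stats::rnorm(sum(brain_mask), sd = noise_sd)
    x
  })
  list(volume = glio_volume(img, id = id),
       brain_mask = brain_mask,
       lesion_mask = lesion_mask,
       label = if (is.null(lesion)) "control" else "patient")
}

# Jitter a lesion center/size deterministically under the current RNG,
# shrinking the offset until the lesion fits inside the head ellipsoid.
jitter_lesion <- function(head_center, head_semiaxes, base_semiaxes,
                          size_jitter, location_jitter) {
  s <- stats::runif(1, 1 - size_jitter, 1 + size_jitter)
  semi <- pmax(2, base_semiaxes * s)
  off <- stats::runif(3, -1, 1) * location_jitter
  fits <- function(o) sum(((abs(o) + semi) / head_semiaxes)^2) <= 1
  while (!fits(off) && max(abs(off)) > 1e-3) off <- off * 0.8
  if (!fits(off)) off <- c(0, 0, 0)
  list(center = head_center + off, semi_axes = semi)
}

#' Generate a detection cohort of phantoms
#'
#' Emulates a glioma-detection dataset: `n_pos` patients carrying a
#' hyperintense lesion (location and size jittered per subject) and `n_neg`
#' lesion-free controls. Per-subject seeds are derived from the master seed,
#' so the whole cohort is reproducible.
#'
#' @param n_pos,n_neg Number of patients / controls (each >= 2).
#' @param contrast Lesion intensity increase over background, same units as
#'   `background_mean`; the default of 30 is six times the default noise SD.
#' @param lesion_semiaxes Base lesion ellipsoid semi-axes in voxels.
#' @param size_jitter Relative lesion size jitter (uniform in
#'   `1 +/- size_jitter`).
#' @param location_jitter Per-axis lesion center jitter in voxels.
#' @param shape,noise_sd,... Passed to [generate_phantom()].
#' @param seed Master seed.
#' @return A tibble with columns `subject_id`, `label` (factor with levels
#'   `patient`, `control`; `patient` is the positive class), and list-columns
#'   `volume`, `brain_mask`, `lesion_mask`.
#' @export
generate_detection_cohort <- function(n_pos = 20, n_neg = 20,
                                      contrast = 30,
                                      lesion_semiaxes = c(10, 8, 6),
                                      size_jitter = 0.2,
                                      location_jitter = c(5, 5, 2),
                                      shape = c(64, 64, 24),
                                      noise_sd = 5,
                                      seed = 1, ...) {
  stopifnot(n_pos >= 2, n_neg >= 2)
  head_semiaxes <- pmax(3, round(shape * c(0.42, 0.42, 0.46)))
  head_center <- (shape + 1) / 2
  make_one <- function(i, diseased) {
    s <- derive_seed(seed, i)
    lesion <- NULL
    if (diseased) {
      jit <- with_seed(derive_seed(seed, 10000 + i),
                       jitter_lesion(head_center, head_semiaxes,
                                     lesion_semiaxes, size_jitter,
                                     location_jitter))
      lesion <- list(center = jit$center, semi_axes = jit$semi_axes,
                     contrast = contrast)
    }
    generate_phantom(shape = shape, noise_sd = noise_sd, lesion = lesion,
                     seed = s, id = sprintf("S%03d", i), ...)
  }
  subjects <- c(lapply(seq_len(n_pos), make_one, diseased = TRUE),
                lapply(n_pos + seq_len(n_neg), make_one, diseased = FALSE))
  tibble(
    subject_id = vapply(subjects, function(s) s$volume$id, character(1)),
    label = factor(vapply(subjects, `[[`, character(1), "label"),
                   levels = c("patient", "control")),
    volume = lapply(subjects, `[[`, "volume"),
    brain_mask = lapply(subjects, `[[`, "brain_mask"),
    lesion_mask = lapply(subjects, `[[`, "lesion_mask")
  )
}

#' Generate a grading cohort of phantoms
#'
#' Emulates a glioma-grading dataset: every subject carries a lesion, and
#' the two classes differ only in lesion severity (contrast and/or size),
#' with high-grade lesions at least as severe in both and strictly more
#' severe in one. Grading cohorts are harder than detection cohorts by
#' construction, mirroring the clinical observation that grade differences
#' are subtler than presence/absence.
#'
#' @param n_high,n_low Number of high-grade / lower-grade subjects.
#' @param contrast_high,contrast_low Lesion contrasts per tier.
#' @param semiaxes_high,semiaxes_low Lesion semi-axes per tier (voxels).
#' @param seed Master seed.
#' @inheritParams generate_detection_cohort
#' @return A tibble like [generate_detection_cohort()]'s, with `label`
#'   levels `high`, `low` (`high` is the positive class); all lesion masks
#'   non-empty.
#' @export
generate_grading_cohort <- function(n_high = 20, n_low = 20,
                                    contrast_high = 30, contrast_low = 22,
                                    semiaxes_high = c(11, 9, 6),
                                    semiaxes_low = c(8, 7, 5),
                                    size_jitter = 0.2,
                                    location_jitter = c(5, 5, 2),
                                    shape = c(64, 64, 24),
                                    noise_sd = 5,
                                    seed = 1, ...) {
  stopifnot(n_high >= 2, n_low >= 2)
  if (contrast_high < contrast_low || any(semiaxes_high < semiaxes_low))
    stop("high-grade tier must be at least as severe in contrast and size",
         call. = FALSE)
  if (contrast_high == contrast_low && all(semiaxes_high == semiaxes_low))
    stop("tiers must be strictly ordered in contrast or size", call. = FALSE)
  head_semiaxes <- pmax(3, round(shape * c(0.42, 0.42, 0.46)))
  head_center <- (shape + 1) / 2
  make_one <- function(i, high) {
    jit <- with_seed(derive_seed(seed, 20000 + i),
                     jitter_lesion(head_center, head_semiaxes,
                                   if (high) semiaxes_high else semiaxes_low,
                                   size_jitter, location_jitter))
    generate_phantom(
      shape = shape, noise_sd = noise_sd,
      lesion = list(center = jit$center, semi_axes = jit$semi_axes,
                    contrast = if (high) contrast_high else contrast_low),
      seed = derive_seed(seed, i), id = sprintf("G%03d", i), ...)
  }
  subjects <- c(lapply(seq_len(n_high), make_one, high = TRUE),
                lapply(n_high + seq_len(n_low), make_one, high = FALSE))
  lab <- c(rep("high", n_high), rep("low", n_low))
  tibble(
    subject_id = vapply(subjects, function(s) s$volume$id, character(1)),
    label = factor(lab, levels = c("high", "low")),
    volume = lapply(subjects, `[[`, "volume"),
    brain_mask = lapply(subjects, `[[`, "brain_mask"),
    lesion_mask = lapply(subjects, `[[`, "lesion_mask")
  )
}

#' Write a phantom cohort to disk
#'
#' Emits one NIfTI volume (and lesion mask, for subjects that have one) per
#' subject plus a `manifest.tsv` with columns `subject_id`, `path`, `label`
#' compatible with the evaluation tooling.
#'
#' @param cohort A cohort tibble from [generate_detection_cohort()] or
#'   [generate_grading_cohort()].
#' @param dir Output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    v <- cohort$volume[[i]]
    paths[i] <- file.path(dir, paste0(v$id, ".nii.gz"))
    write_volume(v, paths[i])
    if (any(cohort$lesion_mask[[i]]))
      write_volume(cohort$lesion_mask[[i]],
                   file.path(dir, paste0(v$id, "_lesion.nii.gz")),
                   spacing = v$spacing)
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(
    data.frame(subject_id = cohort$subject_id, path = paths,
               label = as.character(cohort$label)),
    manifest, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' Loads volumes listed in a `manifest.tsv` (columns `subject_id`, `path`,
#' `label`) into a cohort tibble.
#'
#' @param manifest Path to the manifest TSV.
#' @param positive Label value to treat as the positive class (first factor
#'   level); defaults to the first label encountered.
#' @return A tibble with `subject_id`, `label`, and a `volume` list-column.
#' @export
read_cohort <- function(manifest, positive = NULL) {
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "path", "label") %in% names(tab)))
  base <- dirname(manifest)
  paths <- ifelse(file.exists(tab$path), tab$path, file.path(base, tab$path))
  vols <- mapply(read_volume, paths, tab$subject_id, SIMPLIFY = FALSE)
  lv <- unique(tab$label)
  if (!is.null(positive)) lv <- c(positive, setdiff(lv, positive))
  tibble(subject_id = tab$subject_id,
         label = factor(tab$label, levels = lv),
         volume = unname(vols))
}
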