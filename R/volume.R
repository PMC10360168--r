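#' Construct a brain volume object
#'
#' A `glio_volume` is the unit every pipeline stage consumes: a 3D intensity
#' array plus per-axis voxel spacing and a subject identifier. Axial slices
#' run along the last array axis; in-plane axes are (row, col) of each slice.
#'
#' @param data Numeric 3D array. All values must be finite; non-finite voxels
#'   are replaced by 0 with a warning (robustness to masked exports).
#' @param spacing Numeric length-3 vector of voxel sizes in mm.
#' @param id Subject identifier string.
#' @return An object of class `glio_volume` with fields `data`, `spacing`,
#'   `id`.
#' @export
glio_volume <- function(data, spacing = c(1, 1, 1), id = "subject") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (got ", length(dim(data)), " dimensions)",
         call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be positive", call. = FALSE)
  storage.mode(data) <- "double"
  bad <- !is.finite(data)
  if (any(bad)) {
    warning(sum(bad), " non-finite voxel(s) replaced by 0 in '", id, "'",
            call. = FALSE)
    data[bad] <- 0
  }
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing), id = id),
            class = "glio_volume")
}

#' @export
print.glio_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<glio_volume '%s'> %d x %d x %d voxels, spacing %s mm%s\n",
              x$id, d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = " x "),
              if (isTRUE(attr(x, "normalized"))) " (normalized to [0,1])" else ""))
  invisible(x)
}

#' @export
dim.glio_volume <- function(x) dim(x$data)

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 image (`.nii` / `.nii.gz`) into a [glio_volume()].
#' 2D or 4D images are rejected: the pipeline assumes single-modality 3D
#' scans with axial slices along the last axis. Non-finite voxels are
#' replaced by 0 with a warning.
#'
#' @param path Path to a readable NIfTI file.
#' @param id Subject identifier; defaults to the file name without extension.
#' @return A [glio_volume()].
#' @export
read_volume <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  nd <- length(dim(img))
  if (nd != 3L)
    stop("expected a 3D volume, got ", nd, "D image in '", path, "'",
         call. = FALSE)
  if (is.null(id))
    id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  glio_volume(array(as.numeric(img), dim = dim(img)),
              spacing = RNifti::pixdim(img), id = id)
}

#' Write a volume or mask to NIfTI
#'
#' Round-trips through [read_volume()] to within storage precision. Logical
#' masks are written as uint8.
#'
#' @param v A [glio_volume()] or a 3D logical/numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing, used when `v` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, spacing = c(1, 1, 1)) {
  if (inherits(v, "glio_volume")) {
    arr <- v$data
    spacing <- v$spacing
  } else {
    arr <- v
  }
  if (is.logical(arr)) {
    arr <- array(as.integer(arr), dim = dim(arr))
    dtype <- "uint8"
  } else {
    dtype <- "double"
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  tryCatch(RNifti::writeNifti(img, path, datatype = dtype),
           error = function(e) stop("failed to write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Estimate a brain mask by intensity thresholding
#'
#' Voxels above the given intensity quantile are kept; the largest
#' 3D-connected component is retained and interior holes are filled slice by
#' slice. Masking an already-masked volume reproduces the same mask
#' (idempotence).
#'
#' @param v A [glio_volume()].
#' @param quantile Intensity quantile in (0, 1) separating tissue from
#'   background; default 0.5.
#' @return A 3D logical array with the volume's dimensions.
#' @export
compute_brain_mask <- function(v, quantile = 0.5) {
  stopifnot(inherits(v, "glio_volume"))
  if (quantile <= 0 || quantile >= 1)
    stop("`quantile` must be in (0, 1)", call. = FALSE)
  x <- v$data
  thr <- stats::quantile(x, quantile, names = FALSE)
  if (max(x) == min(x))
    stop("degenerate input: constant volume has no tissue/background contrast",
         call. = FALSE)
  m <- x > thr
  if (!any(m))
    stop("degenerate input: empty mask at quantile ", quantile, call. = FALSE)
  lab <- EBImage::bwlabel(array(as.numeric(m), dim = dim(m)))
  tab <- tabulate(lab[lab > 0])
  m <- lab == which.max(tab)
  # fill interior holes per axial slice
  for (k in seq_len(dim(m)[3])) {
    sl <- m[, , k]
    if (any(sl))
      m[, , k] <- EBImage::fillHull(matrix(as.numeric(sl), nrow = nrow(sl))) > 0
  }
  m
}

#' Z-score intensity standardization with clipping
#'
#' Standardizes a volume so intensities are comparable across subjects:
#' subtract the mean and divide by the standard deviation of the brain
#' region, clip the z-score at \[-4, 4\], and map linearly to \[0, 1\] via
#' (z + 4) / 8. A voxel at the brain mean maps to 0.5. Out-of-mask voxels
#' are written as 0 so the mean and SD never depend on the field of view.
#'
#' @param v A [glio_volume()].
#' @param mask 3D logical array delimiting the brain; defaults to
#'   [compute_brain_mask()] at quantile 0.5.
#' @param clip Symmetric z-score clipping bound (fixed at 4 in the standard
#'   pipeline).
#' @return A [glio_volume()] with in-mask values in \[0, 1\], background 0,
#'   and attributes `normalized = TRUE`, `mu`, `sigma` recording the
#'   standardization provenance.
#' @export
zscore_normalize <- function(v, mask = NULL, clip = 4) {
  stopifnot(inherits(v, "glio_volume"))
  if (is.null(mask)) mask <- compute_brain_mask(v)
  stopifnot(is.logical(mask), identical(dim(mask), dim(v$data)))
  if (!any(mask)) stop("brain mask has no voxels", call. = FALSE)
  xs <- v$data[mask]
  mu <- mean(xs)
  sigma <- stats::sd(xs)
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate input: zero intensity variance over the brain mask",
         call. = FALSE)
  z <- (v$data - mu) / sigma
  z <- pmin(pmax(z, -clip), clip)
  out <- (z + clip) / (2 * clip)
  out[!mask] <- 0
  nv <- glio_volume(array(out, dim = dim(v$data)), spacing = v$spacing, id = v$id)
  attr(nv, "normalized") <- TRUE
  attr(nv, "mu") <- mu
  attr(nv, "sigma") <- sigma
  nv
}

# Dice coefficient between two masks: 2|A.B| / (|A|+|B|)
#' Dice overlap coefficient
#'
#' @param a,b Logical arrays of identical dimension.
#' @return 2|A∩B| / (|A| + |B|); 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
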