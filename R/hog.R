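#' Partition a volume into a grid of square cells
#'
#' Tiles every included axial slice with axis-aligned, non-overlapping
#' square cells of side `cell_size` voxels. Trailing rows/columns that do
#' not fill a whole cell are truncated (padding would create artificial
#' edges at the image boundary). Slices with no in-mask voxels can be
#' excluded — the exclusion must be decided once, from a training-set
#' reference mask, so the grid is identical for every subject.
#'
#' @param v A [glio_volume()] (typically normalized) or a 3D array; only
#'   its dimensions are used.
#' @param cell_size Cell side length in voxels (>= 2, at most the smaller
#'   in-plane dimension). The classification experiments sweep 10-20.
#' @param mask Optional reference brain mask; slices with no `TRUE` voxel
#'   are dropped from the grid.
#' @return A `cell_grid` object: `cell_size`, `n_rows`, `n_cols` (cells per
#'   slice), `slices` (included slice indices), `dim` (expected volume
#'   dimensions), and `n_cells`.
#' @export
partition_cells <- function(v, cell_size, mask = NULL) {
  d <- if (inherits(v, "glio_volume")) dim(v$data) else dim(v)
  stopifnot(length(d) == 3L)
  cell_size <- as.integer(cell_size)
  if (cell_size < 2L)
    stop("`cell_size` must be >= 2", call. = FALSE)
  if (cell_size > min(d[1:2]))
    stop("`cell_size` (", cell_size, ") exceeds the in-plane dimensions ",
         d[1], "x", d[2], call. = FALSE)
  slices <- seq_len(d[3])
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), d))
    slices <- which(apply(mask, 3, any))
    if (length(slices) == 0L)
      stop("reference mask is empty on every slice", call. = FALSE)
  }
  n_rows <- d[1] %/% cell_size
  n_cols <- d[2] %/% cell_size
  structure(list(cell_size = cell_size, n_rows = n_rows, n_cols = n_cols,
                 slices = slices, dim = d,
                 n_cells = n_rows * n_cols * length(slices)),
            class = "cell_grid")
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf("<cell_grid> %d x %d cells of %d voxels on %d slice(s) = %d cells\n",
              x$n_rows, x$n_cols, x$cell_size, length(x$slices), x$n_cells))
  invisible(x)
}

# Image gradients of a 2D patch/slice by centered differences with
# replicated borders. Returns list(gx = d/dcol, gy = d/drow).
patch_gradients <- function(p) {
  nr <- nrow(p); nc <- ncol(p)
  rp <- p[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]  # replicate borders
  gy <- (rp[3:(nr + 2), 2:(nc + 1)] - rp[1:nr, 2:(nc + 1)]) / 2
  gx <- (rp[2:(nr + 1), 3:(nc + 2)] - rp[2:(nr + 1), 1:nc]) / 2
  list(gx = gx, gy = gy)
}

# Bin unsigned gradient orientations into n_bins over [0, 180) with
# magnitude weighting and linear interpolation between the two adjacent
# bin centers (centers at (b-1)*180/n_bins, circular over 180 degrees).
hog_bin <- function(gx, gy, n_bins) {
  mag <- sqrt(gx^2 + gy^2)
  keep <- mag > 0
  if (!any(keep)) return(numeric(n_bins))
  theta <- (atan2(gy[keep], gx[keep]) * 180 / pi) %% 180
  w <- mag[keep]
  width <- 180 / n_bins
  pos <- theta / width                    # continuous bin coordinate
  lo <- floor(pos)
  frac <- pos - lo
  b1 <- (lo %% n_bins) + 1
  b2 <- ((lo + 1) %% n_bins) + 1
  h <- numeric(n_bins)
  acc1 <- tapply(w * (1 - frac), b1, sum)
  acc2 <- tapply(w * frac, b2, sum)
  h[as.integer(names(acc1))] <- h[as.integer(names(acc1))] + acc1
  h[as.integer(names(acc2))] <- h[as.integer(names(acc2))] + acc2
  h
}

#' Histogram-of-gradients descriptor of one cell
#'
#' Computes image gradients of the patch by centered differences (borders
#' replicated), bins the unsigned orientation into `n_bins` over \[0, 180)
#' degrees weighted by gradient magnitude with linear interpolation between
#' adjacent bins, and L2-normalizes the histogram with an additive epsilon.
#' A patch with zero total gradient magnitude (e.g. constant intensity)
#' yields an all-zero descriptor.
#'
#' @param patch 2D numeric matrix, typically `cell_size` x `cell_size` with
#'   values in \[0, 1\].
#' @param n_bins Number of orientation bins (default 9).
#' @param epsilon Normalization constant (default 1e-6).
#' @return Numeric vector of length `n_bins`, entries >= 0, L2 norm <= 1.
#' @export
compute_cell_hog <- function(patch, n_bins = 9, epsilon = 1e-6) {
  if (!all(is.finite(patch)))
    stop("patch contains non-finite values", call. = FALSE)
  g <- patch_gradients(patch)
  h <- hog_bin(g$gx, g$gy, n_bins)
  n <- sqrt(sum(h^2))
  if (n == 0) return(h)
  h / (n + epsilon)
}

# All cell descriptors of one slice as an (n_rows*n_cols) x n_bins matrix,
# rows ordered by (row, col) with col fastest.
slice_hog <- function(sl, grid, n_bins, epsilon) {
  cs <- grid$cell_size
  out <- matrix(0, grid$n_rows * grid$n_cols, n_bins)
  i <- 0L
  for (r in seq_len(grid$n_rows)) {
    rr <- ((r - 1) * cs + 1):(r * cs)
    for (cc in seq_len(grid$n_cols)) {
      i <- i + 1L
      patch <- sl[rr, ((cc - 1) * cs + 1):(cc * cs)]
      out[i, ] <- compute_cell_hog(patch, n_bins, epsilon)
    }
  }
  out
}

#' Extract per-cell HOG descriptors for one subject
#'
#' Applies [compute_cell_hog()] to every cell of every included slice.
#' Deterministic for fixed input.
#'
#' @param v A normalized [glio_volume()].
#' @param grid A [partition_cells()] grid built from the same volume shape.
#' @param n_bins,epsilon Passed to [compute_cell_hog()].
#' @return A tibble of class `cell_hog` with one row per cell: `subject_id`,
#'   `slice`, `row`, `col`, and descriptor columns `bin_1` ... `bin_n`.
#'   The grid is attached as attribute `cell_grid`.
#' @export
extract_subject_features <- function(v, grid, n_bins = 9, epsilon = 1e-6) {
  stopifnot(inherits(v, "glio_volume"), inherits(grid, "cell_grid"))
  if (!identical(dim(v$data), grid$dim))
    stop("volume dimensions ", paste(dim(v$data), collapse = "x"),
         " do not match the grid's ", paste(grid$dim, collapse = "x"),
         call. = FALSE)
  per_slice <- lapply(grid$slices, function(k)
    slice_hog(v$data[, , k], grid, n_bins, epsilon))
  desc <- do.call(rbind, per_slice)
  idx <- expand.grid(col = seq_len(grid$n_cols), row = seq_len(grid$n_rows),
                     slice = grid$slices)
  out <- tibble(subject_id = v$id, slice = idx$slice, row = idx$row,
                col = idx$col)
  colnames(desc) <- paste0("bin_", seq_len(n_bins))
  out <- dplyr::bind_cols(out, tibble::as_tibble(desc))
  attr(out, "cell_grid") <- grid
  class(out) <- c("cell_hog", class(out))
  out
}

# Extract the descriptor matrix (cells x bins) from a cell_hog tibble,
# rows in (slice, row, col) order as produced.
descriptor_matrix <- function(features) {
  as.matrix(features[grep("^bin_", names(features))])
}
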