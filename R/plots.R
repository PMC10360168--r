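#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_col geom_raster facet_wrap labs scale_fill_viridis_c theme_minimal
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cross-validation report
#'
#' Metric means over runs against cell size, with a +/- 1 SD ribbon —
#' the usual way a cell-size sweep is read.
#'
#' @param object A `cv_report` from [run_cv_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_report <- function(object, ...) {
  summ <- glance(object) |>
    tidyr::pivot_longer(-"cell_size",
                        names_to = c("metric", "stat"),
                        names_pattern = "(.*)_(mean|sd)") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  ggplot(summ, aes(x = .data$cell_size, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd,
                    ymax = .data$mean + .data$sd), alpha = 0.2) +
    geom_line() + geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "cell size (voxels)", y = "mean over runs (± 1 SD)",
         title = "Repeated stratified cross-validation") +
    theme_minimal()
}

#' Plot an Exp-seg result
#'
#' Per-slice glioma voxel counts, colored by how the slice's
#' expansion-segmentation terminated.
#'
#' @param object An `expseg_result` from [segment_volume()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.expseg_result <- function(object, ...) {
  ggplot(object$slices,
         aes(x = .data$slice, y = .data$n_glioma, fill = .data$stopped_by)) +
    geom_col() +
    labs(x = "axial slice", y = "glioma voxels",
         title = sprintf("Exp-seg '%s' (seed slice %d, threshold %g)",
                         object$id, object$seed_slice,
                         object$params$threshold),
         fill = "stop reason") +
    theme_minimal()
}

#' Plot a fitted HBM model's codebook separation map
#'
#' Tile map of the disease/health centroid separation per cell position,
#' one facet per slice: where the model found class structure.
#'
#' @param object An `hbm_model` from [hbm_fit()].
#' @param slices Optional subset of slices to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hbm_model <- function(object, slices = NULL, ...) {
  d <- tidy(object)
  if (!is.null(slices)) d <- dplyr::filter(d, .data$slice %in% slices)
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$separation)) +
    geom_raster() +
    facet_wrap(~slice) +
    scale_fill_viridis_c(na.value = "grey85") +
    labs(x = "cell column", y = "cell row", fill = "centroid\nseparation",
         title = "Per-position codebook separation") +
    theme_minimal()
}

#' Plot one axial slice with optional mask overlay
#'
#' @param v A [glio_volume()].
#' @param slice Slice index (default: middle slice).
#' @param mask Optional 3D logical mask to outline.
#' @return A ggplot.
#' @export
plot_slice <- function(v, slice = NULL, mask = NULL) {
  stopifnot(inherits(v, "glio_volume"))
  d <- dim(v$data)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$intensity <- as.vector(v$data[, , slice])
  p <- ggplot(df, aes(x = .data$col, y = .data$row)) +
    geom_raster(aes(fill = .data$intensity)) +
    scale_fill_viridis_c(option = "magma") +
    labs(title = sprintf("%s, slice %d", v$id, slice)) +
    theme_minimal()
  if (!is.null(mask)) {
    df$m <- as.vector(mask[, , slice])
    p <- p + geom_point(data = df[df$m, ], color = "cyan", size = 0.3)
  }
  p
}
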