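config_defaults <- function() {
  list(
    "preprocess.mask_quantile" = 0.5,
    "features.cell_size"       = 16L,
    "features.n_bins"          = 9L,
    "features.epsilon"         = 1e-6,
    "fcm.m"                    = 2,
    "fcm.tol"                  = 1e-6,
    "fcm.max_iter"             = 100L,
    "classifier.kernel"        = "linear",
    "classifier.cost"          = 1,
    "expseg.threshold"         = 0.05,
    "expseg.erosion_radius"    = 1L,
    "expseg.neighborhood_r"    = 1L,
    "expseg.max_iter"          = 50L,
    "expseg.family"            = "lda",
    "expseg.features"          = "intensity",
    "cv.k"                     = 10L,
    "cv.runs"                  = 10L,
    "cv.seed"                  = 1L
  )
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config validation: ", msg,
                                         call. = FALSE)
  chk(cfg[["preprocess.mask_quantile"]] > 0 &&
        cfg[["preprocess.mask_quantile"]] < 1,
      "preprocess.mask_quantile must be in (0, 1)")
  chk(cfg[["features.cell_size"]] >= 2,
      "features.cell_size must be >= 2")
  chk(cfg[["features.n_bins"]] >= 2, "features.n_bins must be >= 2")
  chk(cfg[["features.epsilon"]] > 0, "features.epsilon must be > 0")
  chk(cfg[["fcm.m"]] > 1, "fcm.m must be > 1")
  chk(cfg[["fcm.tol"]] > 0, "fcm.tol must be > 0")
  chk(cfg[["fcm.max_iter"]] >= 1, "fcm.max_iter must be >= 1")
  chk(cfg[["classifier.kernel"]] %in% c("linear", "radial"),
      "classifier.kernel must be 'linear' or 'radial'")
  chk(cfg[["classifier.cost"]] > 0, "classifier.cost must be > 0")
  chk(cfg[["expseg.threshold"]] >= 0 && cfg[["expseg.threshold"]] <= 0.1,
      "expseg.threshold must be in [0, 0.1]")
  chk(cfg[["expseg.erosion_radius"]] >= 0,
      "expseg.erosion_radius must be >= 0")
  chk(cfg[["expseg.neighborhood_r"]] >= 1,
      "expseg.neighborhood_r must be >= 1")
  chk(cfg[["expseg.family"]] %in% c("lda", "svm", "logistic"),
      "expseg.family must be 'lda', 'svm' or 'logistic'")
  chk(all(cfg[["expseg.features"]] %in%
            c("intensity", "nbhd_mean", "nbhd_sd")),
      "expseg.features must be among intensity, nbhd_mean, nbhd_sd")
  chk(cfg[["cv.k"]] >= 2, "cv.k must be >= 2")
  chk(cfg[["cv.runs"]] >= 1, "cv.runs must be >= 1")
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Merges, in increasing precedence: package defaults, a YAML file of flat
#' dotted keys (e.g. `expseg.threshold: 0.05`), and programmatic
#' overrides. Unknown keys raise an error listing the valid ones; values
#' are range-checked (notably the Exp-seg stop threshold, constrained to
#' \[0, 0.1\], and the z-score clip, fixed at +/-4 and therefore not a
#' key). The resolved configuration is what pipeline entry points embed in
#' their outputs.
#'
#' @param path Optional YAML file path.
#' @param overrides Named list of key overrides (e.g. from CLI flags).
#' @return A validated named list of class `gliohbm_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  apply_layer <- function(cfg, layer, origin) {
    if (length(layer) == 0) return(cfg)
    unknown <- setdiff(names(layer), names(cfg))
    if (length(unknown))
      stop("unknown config key(s) from ", origin, ": ",
           paste(unknown, collapse = ", "), "\nvalid keys: ",
           paste(names(cfg), collapse = ", "), call. = FALSE)
    for (k in names(layer)) {
      v <- layer[[k]]
      if (is.numeric(cfg[[k]]) && !is.numeric(v))
        stop("config key '", k, "' must be numeric", call. = FALSE)
      cfg[[k]] <- if (is.integer(cfg[[k]])) as.integer(v) else v
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    cfg <- apply_layer(cfg, yaml::read_yaml(path), path)
  }
  cfg <- apply_layer(cfg, overrides, "overrides")
  validate_config(cfg)
  structure(cfg, class = "gliohbm_config")
}

#' @export
print.gliohbm_config <- function(x, ...) {
  cat("<gliohbm_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
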