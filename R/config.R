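#' Study configuration
#'
#' Bundles every tunable pipeline constant with its default. Defaults follow
#' the analysis protocol implemented by this package: a 0.01--0.10 Hz
#' temporal band-pass, five slicewise principal components per noise mask,
#' second-order RETROICOR, summaries over the central 10 slices, a 5-slice
#' crop for ICA at 50 (cord mask) or 10 (gray-matter mask) components,
#' component maps thresholded at z >= 4 and seed maps at r = 0.4.
#'
#' @param bandpass_lo_hz,bandpass_hi_hz band-pass cut-offs in Hz.
#' @param n_pca_nuisance principal components kept per noise mask and slice.
#' @param retroicor_order Fourier expansion order for cardiac and
#'   respiratory phase regressors.
#' @param central_slices number of central slices over which subject
#'   summaries (TSNR, network correlations) are averaged.
#' @param ica_crop_slices slices kept around the lumbar enlargement for ICA.
#' @param ica_dims_high,ica_dims_low ICA model orders for the cord-mask and
#'   gray-matter-mask analyses.
#' @param z_thresh component z-map threshold.
#' @param seed_r_thresh seed-map correlation threshold (positive tail).
#' @param moco_reg_width moving-average width (slices) for rostro-caudal
#'   regularisation of slicewise motion estimates.
#' @param peak_min_interval_s refractory period for cardiac peak detection.
#' @param collinearity_cond condition-number limit above which nuisance
#'   design columns are dropped as collinear.
#' @param subject_pca_dims subject-level PCA order retained before group
#'   ICA.
#' @param gm_occupancy_frac fraction of suprathreshold voxels that must lie
#'   in gray matter for a component to be labelled GM.
#' @param bilateral_frac minimum per-side fraction of suprathreshold voxels
#'   for a "bilateral" side label.
#' @param match_dice_floor Dice below which matched component pairs are
#'   reported unmatched.
#' @param noise_extent_frac in-plane extent, as a fraction of cord width,
#'   beyond which a single-slice component is labelled noise.
#' @param fisher_z average network correlations on the Fisher-z scale
#'   instead of raw r (off by default).
#' @param rng_seed integer seed recorded in results for reproducibility.
#' @return an object of class `study_config` (a named list).
#' @export
study_config <- function(bandpass_lo_hz = 0.01,
                         bandpass_hi_hz = 0.10,
                         n_pca_nuisance = 5L,
                         retroicor_order = 2L,
                         central_slices = 10L,
                         ica_crop_slices = 5L,
                         ica_dims_high = 50L,
                         ica_dims_low = 10L,
                         z_thresh = 4.0,
                         seed_r_thresh = 0.4,
                         moco_reg_width = 3L,
                         peak_min_interval_s = 0.25,
                         collinearity_cond = 1e8,
                         subject_pca_dims = 75L,
                         gm_occupancy_frac = 0.5,
                         bilateral_frac = 0.25,
                         match_dice_floor = 0.1,
                         noise_extent_frac = 1.0,
                         fisher_z = FALSE,
                         rng_seed = 1L) {
  cfg <- list(bandpass_lo_hz = bandpass_lo_hz,
              bandpass_hi_hz = bandpass_hi_hz,
              n_pca_nuisance = as.integer(n_pca_nuisance),
              retroicor_order = as.integer(retroicor_order),
              central_slices = as.integer(central_slices),
              ica_crop_slices = as.integer(ica_crop_slices),
              ica_dims_high = as.integer(ica_dims_high),
              ica_dims_low = as.integer(ica_dims_low),
              z_thresh = z_thresh,
              seed_r_thresh = seed_r_thresh,
              moco_reg_width = as.integer(moco_reg_width),
              peak_min_interval_s = peak_min_interval_s,
              collinearity_cond = collinearity_cond,
              subject_pca_dims = as.integer(subject_pca_dims),
              gm_occupancy_frac = gm_occupancy_frac,
              bilateral_frac = bilateral_frac,
              match_dice_floor = match_dice_floor,
              noise_extent_frac = noise_extent_frac,
              fisher_z = isTRUE(fisher_z),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg, tr_s = NULL) {
  stopifnot(cfg$bandpass_lo_hz > 0,
            cfg$bandpass_lo_hz < cfg$bandpass_hi_hz)
  if (!is.null(tr_s)) {
    nyq <- 1 / (2 * tr_s)
    if (cfg$bandpass_hi_hz >= nyq)
      stop("band-pass upper cut-off ", cfg$bandpass_hi_hz,
           " Hz is at or above the Nyquist frequency ",
           signif(nyq, 4), " Hz", call. = FALSE)
  }
  counts <- c(cfg$n_pca_nuisance, cfg$retroicor_order, cfg$central_slices,
              cfg$ica_crop_slices, cfg$ica_dims_high, cfg$ica_dims_low,
              cfg$moco_reg_width, cfg$subject_pca_dims)
  if (any(counts < 1L)) stop("all count parameters must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Read or write a study configuration as YAML
#'
#' Unknown keys in the file are rejected; missing keys take their defaults.
#'
#' @param path YAML file path.
#' @param cfg a `study_config` object.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(study_config, vals)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
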