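#' Denoise one subject
#'
#' Runs the full slicewise denoising chain: motion estimation and
#' correction, RETROICOR + slicewise PCA + motion nuisance regression, and
#' temporal band-pass filtering, with TSNR maps computed after motion
#' correction and after full denoising.
#'
#' @param v the raw [volume_series()].
#' @param masks a [mask_set()].
#' @param physio a [physio_recording()].
#' @param config a [study_config()].
#' @return a list of class `denoise_result`: `moco` and `denoised` series,
#'   the `motion` trace, the per-slice `design`, and `tsnr_moco` /
#'   `tsnr_denoise` maps.
#' @export
denoise_subject <- function(v, masks, physio, config = study_config()) {
  validate_study_config(config, tr_s = v$tr_s)
  motion <- estimate_motion_slicewise(v, reg_width = config$moco_reg_width)
  moco <- apply_motion_correction(v, motion)
  design <- build_nuisance_design(moco, physio, masks, motion, config)
  resid <- regress_nuisance(moco, design, config$collinearity_cond)
  denoised <- bandpass(resid, config$bandpass_lo_hz, config$bandpass_hi_hz)
  t_moco <- tsnr(moco, moco, masks, "after_moco", config$central_slices)
  t_den <- tsnr(moco, denoised, masks, "after_denoise",
                config$central_slices)
  structure(list(moco = moco, denoised = denoised, motion = motion,
                 design = design, tsnr_moco = t_moco, tsnr_denoise = t_den),
            class = "denoise_result")
}

#' Denoising + quadrant connectivity for one subject
#'
#' @param subject a `phantom_subject` from [render_subject()], or a list
#'   with elements `series`, `physio` and a mask set under
#'   `truth$masks`/`masks`.
#' @param config a [study_config()].
#' @return a list with the `denoise_result`, the data-driven `quadrants`,
#'   and the `network_correlations`.
#' @export
analyze_subject <- function(subject, config = study_config()) {
  masks <- if (!is.null(subject$truth)) subject$truth$masks else subject$masks
  den <- denoise_subject(subject$series, masks, subject$physio, config)
  quads <- partition_gm_quadrants(masks$gm)
  rts <- roi_timeseries(den$denoised, quads)
  net <- network_correlations(rts, config)
  list(denoise = den, quadrants = quads, networks = net)
}

#' Run the denoising + connectivity pipeline over a synthetic cohort
#'
#' Renders each subject of the cohort in turn, runs the full denoising and
#' quadrant-ROI connectivity chain, and collects per-subject network
#' summaries and gray-matter TSNR at both stages. Subjects are rendered
#' and discarded one at a time to bound memory.
#'
#' @param cohort a `cohort_spec` from [make_cohort()].
#' @param config a [study_config()].
#' @param keep_subjects if `TRUE`, also return each subject's full
#'   analysis output (memory-heavy).
#' @param progress print one line per subject.
#' @return a list of class `cohort_result`: `networks` (subjects x 6
#'   matrix of central-slice network means), `tsnr_moco`, `tsnr_denoise`
#'   (per-subject GM summaries), `group` (named vector of group means) and
#'   the cohort `manifest`.
#' @export
run_cohort_pipeline <- function(cohort, config = study_config(),
                                keep_subjects = FALSE, progress = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n <- cohort$n_subjects
  nets <- matrix(NA_real_, n, nrow(NETWORKS),
                 dimnames = list(NULL, NETWORKS$network))
  t_moco <- t_den <- numeric(n)
  kept <- if (keep_subjects) vector("list", n) else NULL
  for (i in seq_len(n)) {
    subj <- render_subject(cohort$specs[[i]])
    res <- analyze_subject(subj, config)
    nets[i, ] <- res$networks$summary
    t_moco[i] <- res$denoise$tsnr_moco$summary
    t_den[i] <- res$denoise$tsnr_denoise$summary
    if (keep_subjects) kept[[i]] <- list(subject = subj, analysis = res)
    if (progress)
      message(sprintf("subject %2d/%d: VV=%.3f DD=%.3f TSNR %.2f -> %.2f",
                      i, n, nets[i, "VV"], nets[i, "DD"], t_moco[i],
                      t_den[i]))
  }
  structure(list(networks = nets, tsnr_moco = t_moco, tsnr_denoise = t_den,
                 group = c(colMeans(nets, na.rm = TRUE),
                           tsnr_moco = mean(t_moco),
                           tsnr_denoise = mean(t_den)),
                 manifest = cohort$manifest,
                 subjects = kept),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects\n", nrow(x$networks)))
  print(round(x$group, 3))
  invisible(x)
}
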