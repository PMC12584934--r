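# Intensity preprocessing ahead of BEV extraction. Fixed order:
# mask -> clip -> normalize. MRI volumes get patient-specific maximum
# normalization; dose volumes share one global maximum fitted on the
# training beams and persisted, so validation/test doses may exceed 1
# (no re-fit, no clipping).

#' Zero a volume outside the body
#'
#' @param v a `volume_grid`.
#' @param body body `mask` on the same grid.
#' @return `v` with out-of-body voxels set to 0.
#' @export
apply_body_mask <- function(v, body) {
  stop_if_grid_mismatch(v, body)
  out <- v
  out$values <- v$values * body$values
  out
}

#' Clip MRI intensities at a high percentile
#'
#' The percentile is computed over in-body voxels only (background zeros
#' would distort it) with linear interpolation between order statistics;
#' values above it are set to the percentile, per volume.
#'
#' @param mri MRI `volume_grid`.
#' @param body body `mask`.
#' @param q percentile in (0, 100], default 99.5.
#' @return Clipped `volume_grid`.
#' @export
clip_high_percentile <- function(mri, body, q = 99.5) {
  stop_if_grid_mismatch(mri, body)
  if (q <= 0 || q > 100) stop("q must lie in (0, 100]")
  inside <- body$values == 1
  if (!any(inside)) stop("empty body mask: percentile undefined")
  cap <- quantile(mri$values[inside], q / 100, type = 7, names = FALSE)
  out <- mri
  out$values <- pmin(mri$values, cap)
  out
}

#' Patient-specific maximum normalization of an MRI volume
#'
#' @param mri MRI `volume_grid` (already body-masked and clipped).
#' @return List with the normalized volume (`volume`, max exactly 1) and
#'   the per-case maximum (`per_case_max`).
#' @export
normalize_patient_max <- function(mri) {
  m <- max(mri$values)
  if (m <= 0) stop("all-zero MRI volume: patient maximum undefined")
  out <- mri
  out$values <- mri$values / m
  list(volume = out, per_case_max = m)
}

#' Fit the global dose normalization on training beams
#'
#' @param training_doses list of dose `volume_grid`s / `bev_cuboid`s, or
#'   a numeric vector of per-beam maxima.
#' @param mri_clip_percentile recorded alongside for provenance.
#' @return A `normalization_state` with the persisted training-set
#'   maximum.
#' @export
fit_global_max <- function(training_doses, mri_clip_percentile = 99.5) {
  maxima <- if (is.numeric(training_doses)) {
    training_doses
  } else {
    vapply(training_doses, function(d) max(d$values), numeric(1))
  }
  if (length(maxima) == 0 || max(maxima) <= 0)
    stop("cannot fit global maximum: no positive training dose values")
  structure(list(global_dose_max = max(maxima),
                 mri_clip_percentile = mri_clip_percentile),
            class = "normalization_state")
}

#' Globally normalize a dose volume
#'
#' Divides by the persisted training-set maximum; linear, applied
#' identically to training, validation and test doses.
#'
#' @param dose dose `volume_grid` or `bev_cuboid`.
#' @param state a `normalization_state` from [fit_global_max()].
#' @return Normalized object of the same class.
#' @export
normalize_global <- function(dose, state) {
  if (!inherits(state, "normalization_state"))
    stop("state must come from fit_global_max()")
  out <- dose
  out$values <- dose$values / state$global_dose_max
  if (!is.null(out$quantity) && out$quantity == "DOSE_GY")
    out$quantity <- "DOSE_NORM"
  out
}

#' Save / load a normalization state
#'
#' Persisting the state to the run manifest guarantees inference never
#' recomputes it.
#'
#' @param state a `normalization_state`.
#' @param path JSON file.
#' @return `path` / the restored state.
#' @export
save_normalization_state <- function(state, path) {
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_normalization_state
#' @export
load_normalization_state <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "normalization_state")
}
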