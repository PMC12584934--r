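# Dose evaluation: 3D global gamma index, profile comparison with the
# symmetric relative difference, dose-through-cavity flagging, and
# cumulative DVH with D_x% / V_xGy indices.

#' Gamma evaluation criteria
#'
#' @param dose_diff_pct global dose-difference criterion (% of the
#'   reference maximum).
#' @param dta_mm distance-to-agreement criterion.
#' @param threshold_frac evaluate only reference voxels at or above this
#'   fraction of the reference maximum.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff_pct = 2, dta_mm = 2,
                           threshold_frac = 0.10) {
  if (dose_diff_pct <= 0 || dta_mm <= 0)
    stop("criteria must be positive")
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must lie in (0, 1)")
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 threshold_frac = threshold_frac, mode = "global"),
            class = "gamma_criteria")
}

vals_and_spacing <- function(v) {
  if (inherits(v, "volume_grid")) {
    list(values = v$values, spacing = v$grid$spacing)
  } else if (inherits(v, "bev_cuboid")) {
    list(values = v$values, spacing = rep(v$spacing_mm, 3))
  } else {
    stop("expected a volume_grid or bev_cuboid")
  }
}

#' 3D global gamma passing rate
#'
#' Gamma at each reference voxel above the dose threshold is the
#' minimum over evaluated-dose sample positions of
#' sqrt(dist^2/dta^2 + ddose^2/tol^2); the evaluated distribution is
#' interpolated trilinearly at 1/3-voxel steps inside a search ball of
#' `search_mult * dta` (offsets are scanned in increasing distance with
#' an exact early stop, so within the ball the minimum is exact).
#' `search_mult = Inf` searches the whole grid (exhaustive reference
#' mode).
#'
#' @param ref reference dose (`volume_grid` or `bev_cuboid`); defines
#'   Dmax for both the dose tolerance and the threshold.
#' @param eval evaluated (predicted) dose on the same grid.
#' @param crit a [gamma_criteria()].
#' @param search_mult search radius in units of `dta_mm`.
#' @param step_div subvoxel interpolation steps per voxel.
#' @return A `gamma_result`: `gamma_map` (NA below threshold),
#'   `passing_rate_pct`, `n_evaluated`.
#' @export
gamma_passing_rate <- function(ref, eval, crit = gamma_criteria(),
                               search_mult = 3, step_div = 3) {
  r <- vals_and_spacing(ref)
  e <- vals_and_spacing(eval)
  if (!identical(dim(r$values), dim(e$values)) ||
      max(abs(r$spacing - e$spacing)) > 1e-9)
    stop("reference and evaluated dose must share a grid; resample first")
  dmax <- max(r$values)
  if (dmax <= 0) stop("reference dose is empty")
  thr <- crit$threshold_frac * dmax
  if (!any(r$values >= thr))
    stop("no reference voxels at or above the dose threshold")
  radius <- if (is.finite(search_mult)) {
    search_mult * crit$dta_mm
  } else {
    sqrt(sum((r$spacing * dim(r$values))^2))
  }
  g <- cpp_gamma_map(as.numeric(r$values), as.numeric(e$values),
                     dim(r$values), r$spacing,
                     crit$dose_diff_pct / 100 * dmax, crit$dta_mm, thr,
                     radius, as.integer(step_div))
  gm <- array(g, dim(r$values))
  n_eval <- sum(!is.na(gm))
  structure(list(gamma_map = gm,
                 passing_rate_pct = 100 * sum(gm <= 1, na.rm = TRUE) /
                   n_eval,
                 n_evaluated = n_eval, criteria = crit),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result %g%%/%g mm, thr %g%%: pass %.2f%% (n=%d)>\n",
              x$criteria$dose_diff_pct, x$criteria$dta_mm,
              100 * x$criteria$threshold_frac, x$passing_rate_pct,
              x$n_evaluated))
  invisible(x)
}

#' Symmetric relative dose difference (percent)
#'
#' `200 * (d_pred - d_mc) / (d_pred + d_mc)`, bounded in \[-200, 200\].
#' Points where the sum is zero are undefined and returned as NA, never
#' as 0.
#'
#' @param d_pred,d_mc numeric series (nonnegative doses).
#' @return Numeric series in percent.
#' @export
relative_difference <- function(d_pred, d_mc) {
  if (length(d_pred) != length(d_mc)) stop("series lengths differ")
  s <- d_pred + d_mc
  out <- ifelse(s == 0, NA_real_, 200 * (d_pred - d_mc) / s)
  out
}

interp_series <- function(xs, ys, x0) {
  stats::approx(xs, ys, xout = x0, rule = 2)$y
}

#' Depth and lateral profiles of a dose cuboid
#'
#' Central-axis depth profile (trilinear at the beam axis y = 0, x = 0)
#' plus lateral x profiles at the distal depths where the central-axis
#' profile falls to 30% and 80% of its maximum (beyond the peak).
#'
#' @param cub a dose `bev_cuboid`.
#' @return List with `depth` (data.frame z_mm, dose) and `lateral_30` /
#'   `lateral_80` (data.frames x_mm, dose, plus attr `depth_mm`).
#' @export
extract_profiles <- function(cub) {
  if (max(cub$values) <= 0) stop("cuboid has no dose")
  ax <- bev_axis_coords(cub)
  d <- dim(cub$values)
  # bilinear interpolation to y = 0, x = 0 for each depth
  central <- vapply(seq_len(d[1]), function(k) {
    plane <- cub$values[k, , ]
    yv <- vapply(seq_len(d[3]), function(i)
      interp_series(ax$y, plane[, i], 0), numeric(1))
    interp_series(ax$x, yv, 0)
  }, numeric(1))
  kmax <- which.max(central)
  cmax <- central[kmax]
  lateral_at <- function(frac) {
    z0 <- NA_real_
    if (kmax < d[1]) {
      distal <- central[kmax:d[1]]
      cross <- which(distal < frac * cmax)[1]
      if (!is.na(cross) && cross > 1) {
        k1 <- kmax + cross - 2
        z0 <- interp_series(central[c(k1, k1 + 1)] / cmax,
                            ax$z[c(k1, k1 + 1)], frac)
      }
    }
    if (is.na(z0)) z0 <- ax$z[d[1]]
    prof <- vapply(seq_len(d[3]), function(i) {
      line <- vapply(seq_len(d[2]), function(j)
        interp_series(ax$z, cub$values[, j, i], z0), numeric(1))
      interp_series(ax$y, line, 0)
    }, numeric(1))
    structure(data.frame(x_mm = ax$x, dose = prof), depth_mm = z0)
  }
  list(depth = data.frame(z_mm = ax$z, dose = central),
       lateral_30 = lateral_at(0.30), lateral_80 = lateral_at(0.80))
}

#' Does the beam dose pass through an air cavity?
#'
#' True iff the dose mask at `frac` of the cuboid maximum intersects
#' the cavity cuboid.
#'
#' @param dose_cub dose array or `bev_cuboid`.
#' @param ac_cub binary cavity array or `bev_cuboid`, same shape.
#' @param frac dose-mask threshold fraction of Dmax, default 0.15.
#' @return Logical flag.
#' @export
dose_through_ac <- function(dose_cub, ac_cub, frac = 0.15) {
  dv <- if (is.list(dose_cub)) dose_cub$values else dose_cub
  av <- if (is.list(ac_cub)) ac_cub$values else ac_cub
  if (!identical(dim(dv), dim(av))) stop("shape mismatch")
  any(dv >= frac * max(dv) & av == 1)
}

#' Cumulative dose-volume histogram of a structure
#'
#' @param dose dose `volume_grid` (Gy).
#' @param structure structure `mask` on the same grid.
#' @param bin_gy dose-axis bin width, default 0.1 Gy.
#' @param name structure name.
#' @return A `dvh_curve` with `dose_gy`, `volume_pct` (monotonically
#'   nonincreasing from 100%), and the raw structure doses for index
#'   queries.
#' @export
dvh_curve <- function(dose, structure, bin_gy = 0.1, name = "structure") {
  stop_if_grid_mismatch(dose, structure)
  doses <- dose$values[structure$values == 1]
  if (length(doses) == 0) stop("empty structure mask")
  axis <- seq(0, max(doses) + bin_gy, by = bin_gy)
  vol <- vapply(axis, function(d) 100 * mean(doses >= d), numeric(1))
  structure(list(dose_gy = axis, volume_pct = vol, doses = doses,
                 name = name),
            class = "dvh_curve")
}

#' DVH dose index D_x%
#'
#' Dose exceeded by x% of the structure volume (the (100-x)th
#' percentile of voxel doses, linear interpolation).
#'
#' @param c a [dvh_curve()].
#' @param x_pct volume percentage.
#' @return Dose in Gy.
#' @export
dvh_D <- function(c, x_pct) {
  quantile(c$doses, 1 - x_pct / 100, type = 7, names = FALSE)
}

#' DVH volume index V_xGy
#'
#' Percent of the structure receiving at least x Gy.
#'
#' @param c a [dvh_curve()].
#' @param x_gy dose level in Gy.
#' @return Volume percentage.
#' @export
dvh_V <- function(c, x_gy) {
  100 * mean(c$doses >= x_gy)
}
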