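# Beam geometry and beam's-eye-view (BEV) cuboid extraction.
#
# Beams are 1 x 1 cm^2 photon fields parallel to the transverse plane
# (the 0.35 T field B is parallel to SI). Gantry convention: 0 deg
# enters from anterior (beam direction -AP); 90 deg enters from the
# patient's right (beam direction -LR, i.e. towards patient right when
# LR points left). The BEV frame is the right-handed orthonormal triple
# (x-hat, y-hat, z-hat) with z-hat the beam direction, x-hat = +SI and
# y-hat = z-hat x B-hat, the mean in-plane Lorentz-drift direction of
# secondary electrons. Rays are sampled parallel (not divergent): at
# SAD 1000 mm with a 10 mm field, divergence across the cuboid is
# sub-voxel.

#' Beam configuration
#'
#' @param isocenter mm triple in the patient frame (SI, AP, LR).
#' @param gantry_deg gantry angle in `[0, 360)`.
#' @param sad_mm source-to-axis distance (default 1000 mm).
#' @param field_mm field width along (y, x) in mm.
#' @param b_field_tesla magnetic flux density along +SI.
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(isocenter, gantry_deg, sad_mm = 1000,
                        field_mm = c(10, 10), b_field_tesla = 0.35) {
  if (gantry_deg < 0 || gantry_deg >= 360)
    stop("gantry_deg must lie in [0, 360)")
  if (any(field_mm <= 0)) stop("field sizes must be positive")
  structure(list(isocenter = as.numeric(isocenter),
                 gantry_deg = as.numeric(gantry_deg),
                 sad_mm = as.numeric(sad_mm),
                 field_mm = as.numeric(field_mm),
                 b_field_tesla = b_field_tesla),
            class = "beam_config")
}

#' Orthonormal BEV frame of a beam
#'
#' @param b a [beam_config()].
#' @return List with unit vectors `ez` (beam direction), `ey` (in-plane
#'   lateral, Lorentz-drift side), `ex` (+SI) and the `source` position
#'   (mm).
#' @export
make_beam_frame <- function(b) {
  g <- b$gantry_deg * pi / 180
  ez <- c(0, -cos(g), -sin(g))           # (SI, AP, LR) components
  ex <- c(1, 0, 0)
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2], # ez x ex
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  list(ez = ez, ey = ey, ex = ex,
       source = b$isocenter - b$sad_mm * ez)
}

#' Distance from the source to the patient surface along the central ray
#'
#' Marched at `step_mm` resolution; the entry depth anchors the z = 0
#' plane of the BEV cuboid.
#'
#' @param body body `mask`.
#' @param b a [beam_config()].
#' @param step_mm ray-marching step.
#' @return Distance in mm from the source to the first body voxel.
#' @export
surface_entry_depth <- function(body, b, step_mm = 2) {
  fr <- make_beam_frame(b)
  g <- body$grid
  half_diag <- sqrt(sum((g$spacing * g$shape)^2)) / 2
  ts <- seq(max(0, b$sad_mm - half_diag - step_mm),
            b$sad_mm + half_diag, by = step_mm)
  pts <- cbind(fr$source[1] + ts * fr$ez[1],
               fr$source[2] + ts * fr$ez[2],
               fr$source[3] + ts * fr$ez[3])
  inside <- cpp_sample_nearest(as.numeric(body$values), g$shape,
                               world_to_index0(g, pts))
  hit <- which(inside > 0.5)
  if (length(hit) == 0)
    stop("beam misses body: central ray does not intersect the body mask")
  ts[hit[1]]
}

# World coordinates (mm) of all cuboid sample points, first axis (z)
# fastest, matching R array linear order for dim (nz, ny, nx).
bev_sample_points <- function(b, entry_depth_mm, shape, spacing_mm,
                              lateral_shift_mm) {
  fr <- make_beam_frame(b)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  z <- (seq_len(nz) - 1) * spacing_mm
  y <- (seq_len(ny) - (ny + 1) / 2) * spacing_mm + lateral_shift_mm
  x <- (seq_len(nx) - (nx + 1) / 2) * spacing_mm
  entry <- fr$source + entry_depth_mm * fr$ez
  zz <- rep(z, times = ny * nx)
  yy <- rep(rep(y, each = nz), times = nx)
  xx <- rep(x, each = nz * ny)
  cbind(entry[1] + zz * fr$ez[1] + yy * fr$ey[1] + xx * fr$ex[1],
        entry[2] + zz * fr$ez[2] + yy * fr$ey[2] + xx * fr$ex[2],
        entry[3] + zz * fr$ez[3] + yy * fr$ey[3] + xx * fr$ex[3])
}

#' Extract a BEV cuboid from a patient-frame volume
#'
#' Samples the volume on a parallel-ray grid in beam coordinates:
#' depth z from the body entry point (`shape[1]` steps), in-plane
#' lateral y centred on the central axis plus `lateral_shift_mm` (the
#' cuboid window follows the Lorentz drift side), and x centred on the
#' isocenter SI position. Out-of-volume samples are 0.
#'
#' @param v patient-frame `volume_grid`.
#' @param b a [beam_config()].
#' @param interp `"trilinear"` or `"nearest"` (masks/labels).
#' @param body body `mask` used to find the entry depth (not needed when
#'   `entry_depth_mm` is given).
#' @param shape cuboid (z, y, x) voxel counts; default 200 x 32 x 32.
#' @param spacing_mm isotropic cuboid resolution, default 2 mm.
#' @param lateral_shift_mm window shift along +y, default 10 mm.
#' @param entry_depth_mm optional precomputed [surface_entry_depth()].
#' @return An object of class `bev_cuboid`.
#' @export
extract_bev_cuboid <- function(v, b, interp = c("trilinear", "nearest"),
                               body = NULL, shape = c(200, 32, 32),
                               spacing_mm = 2, lateral_shift_mm = 10,
                               entry_depth_mm = NULL) {
  interp <- match.arg(interp)
  if (is.null(entry_depth_mm)) {
    if (is.null(body))
      stop("either body or entry_depth_mm must be supplied")
    entry_depth_mm <- surface_entry_depth(body, b)
  }
  pts <- world_to_index0(
    v$grid, bev_sample_points(b, entry_depth_mm, shape, spacing_mm,
                              lateral_shift_mm))
  vals <- if (interp == "trilinear") {
    cpp_sample_trilinear(as.numeric(v$values), v$grid$shape, pts)
  } else {
    cpp_sample_nearest(as.numeric(v$values), v$grid$shape, pts)
  }
  bev_cuboid(array(vals, dim = shape), b, entry_depth_mm,
             spacing_mm = spacing_mm, lateral_shift_mm = lateral_shift_mm,
             quantity = v$quantity)
}

#' BEV cuboid container
#'
#' @param values (nz, ny, nx) array in beam coordinates.
#' @param beam the [beam_config()] defining the frame.
#' @param entry_depth_mm source-to-surface distance along the central
#'   ray.
#' @param spacing_mm isotropic voxel size.
#' @param lateral_shift_mm y-window shift.
#' @param quantity see [volume_grid()].
#' @return An object of class `bev_cuboid`.
#' @export
bev_cuboid <- function(values, beam, entry_depth_mm, spacing_mm = 2,
                       lateral_shift_mm = 10, quantity = "DOSE_NORM") {
  structure(list(values = values, beam = beam,
                 entry_depth_mm = entry_depth_mm,
                 spacing_mm = spacing_mm,
                 lateral_shift_mm = lateral_shift_mm,
                 quantity = quantity),
            class = "bev_cuboid")
}

#' @export
print.bev_cuboid <- function(x, ...) {
  cat(sprintf("<bev_cuboid [%s] %s @ %g mm, gantry %g deg, entry %.1f mm>\n",
              x$quantity, paste(dim(x$values), collapse = "x"),
              x$spacing_mm, x$beam$gantry_deg, x$entry_depth_mm))
  invisible(x)
}

# Cuboid-local coordinates of voxel centres along each axis (mm).
# z: depth from the surface; y: lateral offset from the beam central
# axis (window centre at +lateral_shift); x: SI offset from isocenter.
bev_axis_coords <- function(c) {
  d <- dim(c$values)
  list(z = (seq_len(d[1]) - 1) * c$spacing_mm,
       y = (seq_len(d[2]) - (d[2] + 1) / 2) * c$spacing_mm +
         c$lateral_shift_mm,
       x = (seq_len(d[3]) - (d[3] + 1) / 2) * c$spacing_mm)
}

#' Insert a BEV dose cuboid back into the patient frame
#'
#' Inverse mapping of [extract_bev_cuboid()]: every target voxel is
#' assigned the trilinear interpolation of the cuboid at its beam
#' coordinates; voxels outside the cuboid footprint are 0.
#'
#' @param c a `bev_cuboid`.
#' @param target patient-frame [grid_spec()].
#' @return A `volume_grid` on `target`.
#' @export
insert_bev_dose <- function(c, target) {
  fr <- make_beam_frame(c$beam)
  d <- dim(c$values)
  entry <- fr$source + c$entry_depth_mm * fr$ez
  w <- grid_world_coords(target)
  rel <- sweep(w, 2, entry, "-")
  z <- rel %*% fr$ez
  y <- rel %*% fr$ey
  x <- rel %*% fr$ex
  pts <- cbind(z / c$spacing_mm,
               (y - c$lateral_shift_mm) / c$spacing_mm + (d[2] - 1) / 2,
               x / c$spacing_mm + (d[3] - 1) / 2)
  vals <- cpp_sample_trilinear(as.numeric(c$values), as.integer(d), pts)
  volume_grid(array(vals, dim = target$shape), grid = target,
              quantity = if (c$quantity %in% VOLUME_QUANTITIES)
                c$quantity else "DOSE_NORM")
}

#' Enumerate a beam set over isocenter shifts and gantry angles
#'
#' Cartesian product of SI shifts (outer), AP shifts (middle) and evenly
#' spaced gantry angles (inner, every `gantry_step_deg` from 0).
#'
#' @param iso base isocenter, mm triple.
#' @param ap_shifts_mm shifts along +AP (default 0, +30, -30 mm).
#' @param si_shifts_mm shifts along +SI (default -40, -20, 0, 20, 40 mm).
#' @param gantry_step_deg angle step; must divide 360.
#' @param sad_mm source-to-axis distance.
#' @return List of [beam_config()]s.
#' @export
enumerate_beam_set <- function(iso, ap_shifts_mm = c(0, 30, -30),
                               si_shifts_mm = c(-40, -20, 0, 20, 40),
                               gantry_step_deg = 10, sad_mm = 1000) {
  if (abs(360 / gantry_step_deg - round(360 / gantry_step_deg)) > 1e-9)
    stop("gantry_step_deg must divide 360")
  angles <- seq(0, 360 - gantry_step_deg, by = gantry_step_deg)
  beams <- list()
  for (si in si_shifts_mm)
    for (ap in ap_shifts_mm)
      for (g in angles) {
        iso_b <- iso + c(si, ap, 0)
        beams[[length(beams) + 1]] <- beam_config(iso_b, g, sad_mm)
      }
  beams
}
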