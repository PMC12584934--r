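# Volumetric data model shared by all modules.
#
# Patient frame convention: right-handed, axis 1 = SI (+ superior),
# axis 2 = AP (+ anterior), axis 3 = LR (+ patient left). Voxel indices
# are 0-based in the geometry formulas: the world coordinate of voxel
# centre (i1, i2, i3) is origin + index * spacing, in mm.

VOLUME_QUANTITIES <- c("MRI", "HU", "DOSE_GY", "DOSE_NORM", "PROBABILITY",
                       "LABEL", "MASK")
PATIENT_AXES <- c("SI", "AP", "LR")

#' Grid specification
#'
#' Describes a regular axis-aligned voxel grid in the patient frame.
#'
#' @param shape integer triple of voxel counts (SI, AP, LR order).
#' @param spacing numeric triple, voxel size in mm; all > 0.
#' @param origin numeric triple, world coordinate (mm) of the centre of
#'   the first voxel.
#' @param axis_labels anatomical direction labels per axis.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin = c(0, 0, 0),
                      axis_labels = PATIENT_AXES) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape < 1L))
    stop("invalid grid: shape must be a triple of counts >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid grid: all spacings must be positive")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("invalid grid: origin must be a finite mm triple")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 axis_labels = axis_labels),
            class = "grid_spec")
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("<grid_spec %s @ %s mm, origin (%s)>",
          paste(x$shape, collapse = "x"),
          paste(signif(x$spacing, 4), collapse = "x"),
          paste(signif(x$origin, 4), collapse = ", "))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Scalar volume on a patient-frame grid
#'
#' @param values 3D numeric array; `dim(values)` must equal `grid$shape`
#'   (or `grid` may be omitted and built from `spacing`/`origin`).
#' @param spacing,origin convenience grid parameters when `grid` is NULL.
#' @param quantity one of `r paste(VOLUME_QUANTITIES, collapse = ", ")`.
#' @param grid optional [grid_spec()].
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = NULL, origin = c(0, 0, 0),
                        quantity = "MRI", grid = NULL) {
  if (is.null(grid)) {
    if (is.null(spacing)) stop("either grid or spacing must be given")
    grid <- grid_spec(dim(values), spacing, origin)
  }
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("value count must match the grid shape")
  quantity <- match.arg(quantity, VOLUME_QUANTITIES)
  if (quantity == "PROBABILITY" &&
      (min(values) < 0 || max(values) > 1))
    stop("PROBABILITY values must lie in [0, 1]")
  if (quantity %in% c("LABEL", "MASK")) {
    if (any(values < 0) || any(values != round(values)))
      stop(quantity, " values must be nonnegative integers")
  }
  structure(list(values = values, grid = grid, quantity = quantity),
            class = c(if (quantity == "MASK") "mask", "volume_grid"))
}

#' Binary mask on a patient-frame grid
#'
#' @param values 3D array of 0/1 values.
#' @inheritParams volume_grid
#' @return A `mask` (subclass of `volume_grid`).
#' @export
mask_grid <- function(values, spacing = NULL, origin = c(0, 0, 0),
                      grid = NULL) {
  storage.mode(values) <- "double"
  if (!all(values %in% c(0, 1))) stop("mask values must be 0 or 1")
  volume_grid(values, spacing, origin, quantity = "MASK", grid = grid)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid [%s] %s, range [%.4g, %.4g]>\n", x$quantity,
              paste(x$grid$shape, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- if (inherits(a, "grid_spec")) a else a$grid
  gb <- if (inherits(b, "grid_spec")) b else b$grid
  identical(ga$shape, gb$shape) &&
    all(abs(ga$spacing - gb$spacing) <= tol) &&
    all(abs(ga$origin - gb$origin) <= tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop("grid mismatch between ", what)
  invisible(TRUE)
}

# World coordinates (n x 3 mm) of every voxel centre, first axis fastest
# (R array linear order).
grid_world_coords <- function(g) {
  i1 <- seq_len(g$shape[1]) - 1
  i2 <- seq_len(g$shape[2]) - 1
  i3 <- seq_len(g$shape[3]) - 1
  cbind(g$origin[1] + g$spacing[1] * rep(i1, times = g$shape[2] * g$shape[3]),
        g$origin[2] + g$spacing[2] * rep(rep(i2, each = g$shape[1]),
                                         times = g$shape[3]),
        g$origin[3] + g$spacing[3] * rep(i3, each = g$shape[1] * g$shape[2]))
}

# 0-based fractional voxel indices of world points (n x 3 mm) in grid g.
world_to_index0 <- function(g, pts) {
  sweep(sweep(pts, 2, g$origin, "-"), 2, g$spacing, "/")
}

voxel_volume_cc <- function(g) prod(g$spacing) / 1000

#' Resample a volume onto a target grid
#'
#' Trilinear or nearest-neighbour interpolation in the shared patient
#' frame. Samples falling outside the source extent are 0. Label and
#' mask volumes must use nearest-neighbour interpolation.
#'
#' @param v a [volume_grid()].
#' @param target a [grid_spec()].
#' @param interp `"trilinear"` or `"nearest"`.
#' @return A `volume_grid` on `target`.
#' @export
resample_to_grid <- function(v, target,
                             interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  if (!inherits(target, "grid_spec")) stop("target must be a grid_spec")
  if (v$quantity %in% c("LABEL", "MASK") && interp != "nearest")
    stop("LABEL/MASK volumes must be resampled with nearest interpolation")
  if (same_grid(v$grid, target, tol = 0)) {
    out <- v
    out$grid <- target
    return(out)
  }
  pts <- world_to_index0(v$grid, grid_world_coords(target))
  vals <- if (interp == "trilinear") {
    cpp_sample_trilinear(as.numeric(v$values), v$grid$shape, pts)
  } else {
    cpp_sample_nearest(as.numeric(v$values), v$grid$shape, pts)
  }
  volume_grid(array(vals, dim = target$shape), grid = target,
              quantity = v$quantity)
}
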