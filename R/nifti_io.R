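# NIfTI-1 I/O. Files are reoriented on read to the package's canonical
# (SI, AP, LR) = (S, A, L) axis convention; only axis-aligned
# orientations are supported. World coordinates in NIfTI RAS relate to
# the internal (S, A, L) frame by (x, y, z)_RAS = (-L, A, S).

internal_to_ras_affine <- function(g) {
  sp <- g$spacing
  o <- g$origin
  rbind(c(0, 0, -sp[3], -o[3]),
        c(0, sp[2], 0, o[2]),
        c(sp[1], 0, 0, o[1]),
        c(0, 0, 0, 1))
}

#' Read a volume from a NIfTI file
#'
#' The image is reoriented to the canonical (SI, AP, LR) axis order.
#' Files without a valid qform/sform (no spacing/orientation metadata)
#' are rejected rather than silently assigned a default geometry.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param quantity quantity label to attach, see [volume_grid()].
#' @return A [volume_grid()] (a `mask` when `quantity = "MASK"`).
#' @export
read_volume <- function(path, quantity = "MRI") {
  if (!file.exists(path)) stop("cannot read volume, no such file: ", path)
  img <- RNifti::readNifti(path)
  x <- RNifti::xform(img)
  if (is.null(attr(x, "code")) || attr(x, "code") == 0)
    stop("volume has no spacing/orientation metadata (qform and sform ",
         "codes are zero): ", path)
  RNifti::orientation(img) <- "SAL"
  x <- RNifti::xform(img)
  spacing <- sqrt(colSums(x[1:3, 1:3]^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid grid: non-positive spacing metadata in ", path)
  # after reorientation the affine must be axis-aligned: column i maps
  # voxel axis i to world S/A/-L respectively
  expected <- cbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0))
  aligned <- sweep(x[1:3, 1:3], 2, spacing, "/")
  if (max(abs(aligned - expected)) > 1e-4)
    stop("volume is not axis-aligned after reorientation: ", path)
  origin <- c(x[3, 4], x[2, 4], -x[1, 4])
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  if (quantity == "MASK") vals <- round(vals)
  volume_grid(vals, spacing = spacing, origin = origin, quantity = quantity)
}

#' Write a volume to a NIfTI file
#'
#' @param v a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$values, pixdim = v$grid$spacing)
  RNifti::sform(img) <- structure(internal_to_ras_affine(v$grid), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a case manifest
#'
#' A manifest is one YAML (or JSON) file per case listing the paths of
#' the `mri`, `ct`, `body`, `ptv`, `oar` and `ac` volumes plus any
#' per-beam dose files, relative to the manifest's directory.
#'
#' @param path manifest file.
#' @return Named list with absolute paths.
#' @export
read_case_manifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  m <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  for (k in names(m)) {
    if (is.character(m[[k]])) m[[k]] <- rel(m[[k]])
  }
  m
}
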