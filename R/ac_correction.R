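# Air-cavity (AC) correction of deformed CT. Gas pockets move between
# CT and MRI acquisition, so CT air is first removed (filled with
# tissue-like values) and the cavities contoured on the MRI are then
# stamped in with a fixed density-override HU. The correction is a
# one-shot procedure: inserted voxels fall below the extraction
# threshold by design, so steps are never re-chained implicitly.

#' Extract the air mask of a CT volume
#'
#' A voxel belongs to the mask iff its value is strictly below
#' `threshold_hu` (default -300 HU).
#'
#' @param ct a `volume_grid` with quantity `"HU"`.
#' @param threshold_hu threshold in HU; strict `<` comparison.
#' @return A `mask` on the CT grid.
#' @export
extract_ct_air_mask <- function(ct, threshold_hu = -300) {
  if (ct$quantity != "HU")
    stop("quantity mismatch: extract_ct_air_mask expects an HU volume, got ",
         ct$quantity)
  mask_grid(array(as.numeric(ct$values < threshold_hu), dim(ct$values)),
            grid = ct$grid)
}

#' Label connected components under 18-connectivity
#'
#' Two foreground voxels are connected when they share a face or an
#' edge (6 + 12 neighbours); corner-sharing voxels are not connected.
#' Labels are consecutive 1..n, assigned in ascending order of each
#' component's first voxel in linear array order (first axis fastest),
#' so the labelling is deterministic.
#'
#' @param m a binary `mask`.
#' @param connectivity 18 (default), 6 or 26.
#' @return A list of class `component_labeling` with elements `labels`
#'   (a LABEL `volume_grid`), `n_components`, and `volumes_cc` (physical
#'   component volumes in cm^3).
#' @export
label_components_18 <- function(m, connectivity = 18) {
  if (!all(m$values %in% c(0, 1))) stop("mask must be binary")
  lab <- cpp_label_components(as.integer(m$values), m$grid$shape,
                              as.integer(connectivity))
  n <- attr(lab, "n_components")
  vol <- volume_grid(array(as.numeric(lab), dim(m$values)), grid = m$grid,
                     quantity = "LABEL")
  counts <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else integer(0)
  structure(list(labels = vol, n_components = n,
                 volumes_cc = counts * voxel_volume_cc(m$grid)),
            class = "component_labeling")
}

# Binary dilation by the full 26-neighbourhood, via array shifts.
dilate26 <- function(values) {
  d <- dim(values)
  out <- values
  for (o1 in -1:1) for (o2 in -1:1) for (o3 in -1:1) {
    if (o1 == 0 && o2 == 0 && o3 == 0) next
    s1 <- pmin(pmax(seq_len(d[1]) + o1, 1L), d[1])
    src1 <- seq_len(d[1]) + o1
    k1 <- src1 >= 1L & src1 <= d[1]
    src2 <- seq_len(d[2]) + o2
    k2 <- src2 >= 1L & src2 <= d[2]
    src3 <- seq_len(d[3]) + o3
    k3 <- src3 >= 1L & src3 <= d[3]
    out[which(k1), which(k2), which(k3)] <-
      pmax(out[which(k1), which(k2), which(k3)],
           values[src1[k1], src2[k2], src3[k3]])
  }
  out
}

#' Fill air components of a CT with neighbour-shell medians
#'
#' For every 18-connected component of `m` independently, all component
#' voxels are replaced by the median HU over the component's neighbour
#' shell: the 26-neighbourhood dilation of the component minus the full
#' air mask. Even-sized shells use the mean of the middle pair.
#'
#' @param ct an HU `volume_grid`.
#' @param m air `mask` on the same grid.
#' @return The filled HU `volume_grid`.
#' @export
fill_air_components <- function(ct, m) {
  if (ct$quantity != "HU") stop("quantity mismatch: expected an HU volume")
  stop_if_grid_mismatch(ct, m)
  comp <- label_components_18(m)
  if (comp$n_components == 0) return(ct)
  out <- ct$values
  lab <- comp$labels$values
  for (k in seq_len(comp$n_components)) {
    ck <- lab == k
    shell <- dilate26(array(as.numeric(ck), dim(ck))) > 0 & !ck &
      m$values == 0
    if (!any(shell))
      stop("air component ", k, " has an empty neighbour shell; ",
           "the mask fills its whole surrounding")
    out[ck] <- median(ct$values[shell])
  }
  volume_grid(out, grid = ct$grid, quantity = "HU")
}

#' Insert MRI-contoured air cavities into a filled CT
#'
#' Voxels of `mri_ac` are set exactly to `fill_hu` (default -700 HU, the
#' density override for gas on this system); all other voxels are
#' unchanged. Applied after [fill_air_components()], so MRI cavities win
#' over filled tissue.
#'
#' @param filled_ct an HU `volume_grid`.
#' @param mri_ac cavity `mask` contoured on the registered MRI.
#' @param fill_hu override value in HU.
#' @return Corrected HU `volume_grid`.
#' @export
insert_mri_air <- function(filled_ct, mri_ac, fill_hu = -700) {
  if (filled_ct$quantity != "HU")
    stop("quantity mismatch: expected an HU volume")
  stop_if_grid_mismatch(filled_ct, mri_ac)
  out <- filled_ct$values
  out[mri_ac$values == 1] <- fill_hu
  volume_grid(out, grid = filled_ct$grid, quantity = "HU")
}

#' Full three-step air-cavity correction
#'
#' Threshold CT air (< `threshold_hu`), fill each component with its
#' neighbour-shell median, then stamp the MRI cavity contours in at
#' `fill_hu`.
#'
#' @inheritParams extract_ct_air_mask
#' @inheritParams insert_mri_air
#' @return Corrected HU `volume_grid`.
#' @export
correct_ct_air <- function(ct, mri_ac, threshold_hu = -300,
                           fill_hu = -700) {
  filled <- fill_air_components(ct, extract_ct_air_mask(ct, threshold_hu))
  insert_mri_air(filled, mri_ac, fill_hu)
}

#' Keep components at or above a volume threshold
#'
#' @param c a `component_labeling`.
#' @param min_cc minimum physical volume in cm^3 (inclusive, `>=`).
#' @return A `mask` holding the union of the surviving components.
#' @export
filter_components_by_volume <- function(c, min_cc = 1.0) {
  keep <- which(c$volumes_cc >= min_cc)
  vals <- array(as.numeric(c$labels$values %in% keep),
                dim(c$labels$values))
  mask_grid(vals, grid = c$labels$grid)
}

#' Component volume summary
#'
#' Mean, SD and range of component volumes before and after a volume
#' filter, in the format used for cavity census tables.
#'
#' @param m cavity `mask`.
#' @param min_cc volume filter in cm^3.
#' @return A data.frame with one row per filtering level.
#' @export
ac_volume_stats <- function(m, min_cc = 1.0) {
  comp <- label_components_18(m)
  summarize <- function(v, label) {
    if (length(v) == 0)
      return(data.frame(filtering = label, n = 0L, mean_cc = NA_real_,
                        sd_cc = NA_real_, min_cc = NA_real_,
                        max_cc = NA_real_))
    data.frame(filtering = label, n = length(v), mean_cc = mean(v),
               sd_cc = if (length(v) > 1) sd(v) else 0,
               min_cc = min(v), max_cc = max(v))
  }
  rbind(summarize(comp$volumes_cc, "none"),
        summarize(comp$volumes_cc[comp$volumes_cc >= min_cc],
                  sprintf(">=%g cm3", min_cc)))
}

#' Dice similarity coefficient between two masks
#'
#' `2|a n b| / (|a| + |b|)`; two empty masks agree perfectly and return
#' 1.0 (keeps per-cuboid DSC defined for cavity-free beams).
#'
#' @param a,b binary `mask`s on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$values)
  nb <- sum(b$values)
  if (na + nb == 0) return(1.0)
  2 * sum(a$values * b$values) / (na + nb)
}
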