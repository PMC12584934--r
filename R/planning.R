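# Nine-field beamlet plan machinery: each field is a 9 x 9 grid of
# abutting 1 x 1 cm^2 beamlets (10 mm pitch, lateral extent +/- 40 mm),
# weighted by a convex quadratic objective - a PTV dose-difference term
# against a normal-tissue overdose term - solved by projected gradient
# descent with backtracking. Plans are normalized so that PTV D95%
# equals 95% of the prescription (computed exactly: 0.95 x 74 Gy =
# 70.3 Gy).

#' Plan specification
#'
#' @param gantry_deg field gantry angles.
#' @param beamlets_side beamlets per side of the square field grid.
#' @param pitch_mm beamlet pitch (abutting 1 cm fields: 10 mm).
#' @param prescription_gy prescription dose.
#' @param n_fractions fraction count (bookkeeping only; all evaluation
#'   is on relative dose).
#' @return An object of class `plan_spec`.
#' @export
plan_spec <- function(gantry_deg = c(0, 40, 80, 120, 160, 200, 240, 280,
                                     320),
                      beamlets_side = 9, pitch_mm = 10,
                      prescription_gy = 74, n_fractions = 37) {
  structure(list(gantry_deg = gantry_deg,
                 beamlets_side = as.integer(beamlets_side),
                 pitch_mm = pitch_mm, prescription_gy = prescription_gy,
                 n_fractions = as.integer(n_fractions)),
            class = "plan_spec")
}

#' Beamlet configurations of a multi-field plan
#'
#' Per field, a `beamlets_side`^2 lateral grid of parallel beamlets at
#' `pitch_mm` spacing, centred on the field axis: offsets along the
#' in-plane lateral direction (y) and along SI (x).
#'
#' @param iso plan isocenter (mm triple).
#' @param spec a [plan_spec()].
#' @param sad_mm source-to-axis distance.
#' @return List of [beam_config()]s with attributes `field` and
#'   `offsets` (data.frame).
#' @export
build_plan_beamlets <- function(iso, spec = plan_spec(), sad_mm = 1000) {
  n <- spec$beamlets_side
  offs <- (seq_len(n) - (n + 1) / 2) * spec$pitch_mm
  beams <- list()
  meta <- data.frame(field = integer(), gantry_deg = numeric(),
                     y_off_mm = numeric(), x_off_mm = numeric())
  for (fi in seq_along(spec$gantry_deg)) {
    g <- spec$gantry_deg[fi]
    fr <- make_beam_frame(beam_config(iso, g, sad_mm))
    for (xo in offs) for (yo in offs) {
      beams[[length(beams) + 1]] <-
        beam_config(iso + yo * fr$ey + xo * fr$ex, g, sad_mm)
      meta <- rbind(meta, data.frame(field = fi, gantry_deg = g,
                                     y_off_mm = yo, x_off_mm = xo))
    }
  }
  attr(beams, "meta") <- meta
  beams
}

#' Assemble a beamlet influence operator
#'
#' Sparse linear operator `d(w) = sum_j w_j D_j` over the patient grid;
#' evaluating at a unit vector returns beamlet j's dose exactly (only
#' structural zeros are dropped).
#'
#' @param beamlet_doses list of dose `volume_grid`s on a common grid.
#' @param grid the common [grid_spec()].
#' @return An `influence` object (sparse matrix `A` of dim n_voxels x
#'   n_beamlets plus the grid).
#' @export
assemble_influence <- function(beamlet_doses, grid) {
  nv <- prod(grid$shape)
  ii <- list(); xx <- list(); jj <- list()
  for (j in seq_along(beamlet_doses)) {
    d <- beamlet_doses[[j]]
    if (!same_grid(d$grid, grid)) stop("grid mismatch in beamlet doses")
    nz <- which(d$values != 0)
    ii[[j]] <- nz
    jj[[j]] <- rep(j, length(nz))
    xx[[j]] <- d$values[nz]
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(xx),
                            dims = c(nv, length(beamlet_doses)))
  structure(list(A = A, grid = grid), class = "influence")
}

#' Evaluate an influence operator
#'
#' @param influence an [assemble_influence()] result.
#' @param w beamlet weight vector.
#' @return Dose `volume_grid`.
#' @export
influence_dose <- function(influence, w) {
  v <- as.numeric(influence$A %*% w)
  volume_grid(array(v, influence$grid$shape), grid = influence$grid,
              quantity = "DOSE_GY")
}

#' Plan objectives
#'
#' Quadratic PTV dose-difference objective traded against a quadratic
#' normal-tissue overdose objective:
#' `F(w) = sum_PTV (d_i - p)^2 + beta * sum_NT max(0, d_i - c)^2`.
#'
#' @param ptv_target_gy PTV target dose p (prescription).
#' @param nt_overdose_cap_gy normal-tissue cap c (default: the
#'   prescription).
#' @param nt_weight trade-off weight beta.
#' @return An object of class `plan_objectives`.
#' @export
plan_objectives <- function(ptv_target_gy = 74,
                            nt_overdose_cap_gy = ptv_target_gy,
                            nt_weight = 0.1) {
  if (ptv_target_gy <= 0 || nt_overdose_cap_gy <= 0 || nt_weight < 0)
    stop("objectives must be positive")
  structure(list(ptv_target_gy = ptv_target_gy,
                 nt_overdose_cap_gy = nt_overdose_cap_gy,
                 nt_weight = nt_weight),
            class = "plan_objectives")
}

#' Optimize beamlet weights
#'
#' Projected gradient descent (w >= 0) with Armijo backtracking on the
#' convex objective of [plan_objectives()]; the objective sequence is
#' monotonically nonincreasing.
#'
#' @param influence an [assemble_influence()] result.
#' @param ptv,body masks on the influence grid.
#' @param obj a [plan_objectives()].
#' @param init initial weights (default small uniform).
#' @param tol relative stationarity tolerance.
#' @param max_iter iteration cap.
#' @return A `plan_weights` list: `w`, `scale` (1 until D95
#'   normalization), `objective` trace, `iterations`.
#' @export
optimize_weights <- function(influence, ptv, body, obj = plan_objectives(),
                             init = NULL, tol = 1e-6, max_iter = 2000) {
  A <- influence$A
  idx_ptv <- which(ptv$values == 1)
  idx_nt <- which(body$values == 1 & ptv$values == 0)
  Ap <- A[idx_ptv, , drop = FALSE]
  if (length(idx_ptv) == 0 || sum(Ap) == 0)
    stop("infeasible plan: no beamlet deposits dose in the PTV")
  An <- A[idx_nt, , drop = FALSE]
  p <- obj$ptv_target_gy
  cc <- obj$nt_overdose_cap_gy
  beta <- obj$nt_weight
  nb <- ncol(A)
  fobj <- function(w) {
    rp <- as.numeric(Ap %*% w) - p
    viol <- pmax(as.numeric(An %*% w) - cc, 0)
    sum(rp^2) + beta * sum(viol^2)
  }
  gobj <- function(w) {
    rp <- as.numeric(Ap %*% w) - p
    viol <- pmax(as.numeric(An %*% w) - cc, 0)
    as.numeric(2 * Matrix::crossprod(Ap, rp) +
                 2 * beta * Matrix::crossprod(An, viol))
  }
  w <- if (is.null(init)) rep(p / max(Matrix::colSums(Ap)), nb) else init
  w <- pmax(w, 0)
  f <- fobj(w)
  trace <- f
  step <- 1 / max(2 * Matrix::colSums(Ap^2) +
                    2 * beta * Matrix::colSums(An^2))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- gobj(w)
    stat <- max(abs(w - pmax(w - g, 0))) / (1 + max(abs(w)))
    if (stat <= tol) {
      converged <- TRUE
      break
    }
    s <- step
    repeat {
      w_new <- pmax(w - s * g, 0)
      f_new <- fobj(w_new)
      dec <- sum(g * (w - w_new)) - sum((w - w_new)^2) / (2 * s)
      if (f_new <= f - 1e-4 * max(dec, 0) || s < 1e-18) break
      s <- s / 2
    }
    if (f_new > f) break  # no descent possible at machine precision
    w <- w_new
    f <- f_new
    trace <- c(trace, f)
    step <- s * 2
  }
  structure(list(w = w, scale = 1, objective = trace,
                 iterations = length(trace) - 1, converged = converged),
            class = "plan_weights")
}

#' Normalize a plan so that PTV D95% meets the prescription level
#'
#' `scale = frac * prescription / D95%`; the same factor is meant to be
#' reused for the predicted plan dose of the same case.
#'
#' @param dose plan dose `volume_grid` (Gy).
#' @param ptv PTV `mask`.
#' @param prescription_gy prescription (74 Gy).
#' @param frac coverage fraction (0.95).
#' @return List with `dose` (scaled) and `scale`.
#' @export
normalize_plan_d95 <- function(dose, ptv, prescription_gy = 74,
                               frac = 0.95) {
  cur <- dvh_D(dvh_curve(dose, ptv, name = "PTV"), 95)
  if (cur <= 0) stop("PTV D95% is zero; cannot normalize")
  scale <- frac * prescription_gy / cur
  out <- dose
  out$values <- dose$values * scale
  list(dose = out, scale = scale)
}
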