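# End-to-end experiment orchestration: synthesize phantoms -> correct
# CT air -> preprocess -> BEV cuboids -> train -> predict -> evaluate
# (per-beam gamma split by the dose-through-cavity flag, DSC, cavity
# volume census) -> optional nine-field plan with D95 normalization,
# plan gamma at three criteria and DVH indices.

#' Experiment configuration
#'
#' Desk-scale defaults: 4 training / 1 validation / 2 test phantoms, 60
#' beams per patient, 100 x 16 x 16 cuboids at 2 mm, a reduced-width
#' network pair, and short Adam schedules with a raised learning rate
#' suited to the small dataset.
#'
#' @param seed master seed.
#' @param n_train,n_val,n_test,beams_per_patient dataset size.
#' @param cuboid_shape BEV cuboid (z, y, x) voxel counts.
#' @param variants model variants to train (subset of 0:3).
#' @param lstm_hidden,lstm_fc LSTM sizes.
#' @param unet_filters,unet_bottleneck U-Net sizes.
#' @param lstm_epochs,unet_epochs,lr,batch training schedule.
#' @param unet_crop_depth,unet_val_max U-Net patch-training controls,
#'   see [train_unet_ac()].
#' @param lambda_ac cavity loss weight.
#' @param gamma_pct,gamma_mm,gamma_threshold per-beam gamma criteria.
#' @param run_plan also optimize and evaluate a nine-field plan on the
#'   first test phantom.
#' @param phantom a [phantom_spec()].
#' @param oracle an [oracle_params()].
#' @param verbose print training progress.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(seed = 1, n_train = 4, n_val = 1,
                              n_test = 2, beams_per_patient = 60,
                              cuboid_shape = c(100, 16, 16),
                              variants = 2, lstm_hidden = 192,
                              lstm_fc = 96, unet_filters = c(8, 16),
                              unet_bottleneck = 32, lstm_epochs = 25,
                              unet_epochs = 8, lr = 1e-3, batch = 8,
                              unet_crop_depth = 48, unet_val_max = 24,
                              lambda_ac = 10, gamma_pct = 3,
                              gamma_mm = 3, gamma_threshold = 0.10,
                              run_plan = FALSE,
                              phantom = phantom_spec(),
                              oracle = oracle_params(),
                              verbose = FALSE) {
  structure(as.list(environment()), class = "experiment_config")
}

#' Run a full synthetic experiment
#'
#' @param config an [experiment_config()].
#' @return Report list: `beam_table` (one row per predicted test beam
#'   with gamma passing rates and the cavity flag), `gamma_summary`
#'   (mean/SD/min split by the dose-through-AC flag), `dsc_summary`,
#'   `ac_volumes`, training histories, and when `run_plan` the plan
#'   gamma/DVH tables.
#' @export
run_experiment <- function(config = experiment_config()) {
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e)
      stop("experiment stage '", nm, "' failed: ", conditionMessage(e)))
  }
  dataset <- stage("dataset", build_beam_dataset(
    n_train = config$n_train, n_val = config$n_val,
    n_test = config$n_test,
    beams_per_patient = config$beams_per_patient,
    spec = config$phantom, params = config$oracle,
    shape = config$cuboid_shape, seed = config$seed))
  w <- prod(config$cuboid_shape[2:3])
  sched <- train_schedule(lr = config$lr, batch = config$batch,
                          epochs = config$lstm_epochs,
                          lambda_ac = config$lambda_ac,
                          seed = config$seed)
  usched <- train_schedule(lr = config$lr, batch = config$batch,
                           epochs = config$unet_epochs,
                           seed = config$seed)
  ucfg <- unet_config(encoder_filters = config$unet_filters,
                      bottleneck_filters = config$unet_bottleneck)
  checkpoints <- list()
  for (v in config$variants) {
    lcfg <- lstm_config(
      input_width = if (v == 0) w else 2 * w,
      hidden = config$lstm_hidden, fc_hidden = config$lstm_fc,
      output_width = w)
    ck <- stage(
      paste0("train_model", v),
      train_model(v, dataset, schedule = sched, lstm_cfg = lcfg,
                  unet_cfg = ucfg, unet_schedule = usched,
                  unet_crop_depth = config$unet_crop_depth,
                  unet_val_max = config$unet_val_max,
                  verbose = config$verbose))
    if (!is.null(ck$unet))
      ck$threshold <- as.numeric(select_binarize_threshold(
        ck$unet, dataset$val))
    checkpoints[[as.character(v)]] <- ck
  }
  report <- list(config = config, normalization = dataset$normalization,
                 histories = lapply(checkpoints, function(ck)
                   ck$lstm$history))
  # per-beam evaluation on the test split
  crit <- gamma_criteria(config$gamma_pct, config$gamma_mm,
                         config$gamma_threshold)
  crit22 <- gamma_criteria(2, 2, config$gamma_threshold)
  beam_tables <- list()
  for (v in names(checkpoints)) {
    ck <- checkpoints[[v]]
    rows <- lapply(seq_along(dataset$test), function(i) {
      s <- dataset$test[[i]]
      pred <- predict_checkpoint(ck, s)
      ref <- bev_cuboid(s$dose, s$beam, s$entry_depth_mm)
      ev <- bev_cuboid(pred$dose, s$beam, s$entry_depth_mm)
      data.frame(
        variant = as.integer(v), beam = i, patient = s$patient,
        gantry_deg = s$beam$gantry_deg,
        gamma_pr = gamma_passing_rate(ref, ev, crit)$passing_rate_pct,
        gamma_pr_2_2 = gamma_passing_rate(ref, ev,
                                          crit22)$passing_rate_pct,
        through_ac = dose_through_ac(s$dose, s$ac),
        dsc = if (!is.null(pred$ac))
          dice_local(pred$ac, s$ac) else NA_real_)
    })
    beam_tables[[v]] <- do.call(rbind, rows)
  }
  report$beam_table <- do.call(rbind, beam_tables)
  report$gamma_summary <- gamma_summary_table(report$beam_table)
  dsc <- report$beam_table$dsc[!is.na(report$beam_table$dsc)]
  if (length(dsc) > 0)
    report$dsc_summary <- data.frame(mean = mean(dsc), sd = sd(dsc),
                                     min = min(dsc), n = length(dsc))
  # cavity volume census over the test phantoms
  test_pids <- unique(vapply(dataset$test, `[[`, 0, "patient"))
  vol_rows <- lapply(test_pids, function(pid) {
    case <- generate_phantom(config$phantom,
                             seed = config$seed * 1000 + pid)
    cbind(patient = pid, ac_volume_stats(case$ac))
  })
  report$ac_volumes <- do.call(rbind, vol_rows)
  if (config$run_plan)
    report$plan <- stage("plan", run_plan_stage(
      config, checkpoints[[as.character(config$variants[1])]],
      pid = test_pids[1]))
  report
}

dice_local <- function(a, b) {
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0) return(1.0)
  2 * sum(a * b) / (na + nb)
}

gamma_summary_table <- function(beam_table) {
  do.call(rbind, lapply(split(beam_table, beam_table$variant),
                        function(bt) {
    mk <- function(x, label) data.frame(
      variant = bt$variant[1], subset = label, n = length(x),
      mean = mean(x), sd = if (length(x) > 1) sd(x) else 0, min = min(x))
    rbind(mk(bt$gamma_pr, "all"),
          if (any(bt$through_ac))
            mk(bt$gamma_pr[bt$through_ac], "through_ac"),
          if (any(!bt$through_ac))
            mk(bt$gamma_pr[!bt$through_ac], "not_through_ac"))
  }))
}

# Nine-field beamlet plan on one test phantom: oracle beamlet doses
# form the influence operator and the reference plan; the model
# predicts each beamlet cuboid, reinserted and summed with the same
# optimized weights and the same D95 normalization factor.
run_plan_stage <- function(config, ck, pid,
                           spec = plan_spec(), obj = NULL,
                           beamlets_side = NULL) {
  case <- generate_phantom(config$phantom,
                           seed = config$seed * 1000 + pid)
  case$ct_corr <- correct_ct_air(case$ct, case$ac)
  mri <- normalize_patient_max(
    clip_high_percentile(apply_body_mask(case$mri, case$body),
                         case$body))$volume
  if (!is.null(beamlets_side)) spec$beamlets_side <- beamlets_side
  iso <- ptv_center(case)
  beams <- build_plan_beamlets(iso, spec)
  g <- case$ct$grid
  nv <- prod(g$shape)
  shape <- config$cuboid_shape
  gmax <- ck$normalization$global_dose_max
  ii <- list(); xx <- list(); jj <- list()
  pii <- list(); pxx <- list(); pjj <- list()
  for (j in seq_along(beams)) {
    b <- beams[[j]]
    ed <- surface_entry_depth(case$body, b)
    ref_cub <- oracle_beam_cuboid(case$ct_corr, b, config$oracle,
                                  shape = shape, entry_depth_mm = ed)
    dv <- insert_bev_dose(ref_cub, g)$values
    nz <- which(dv > 1e-6 * max(dv))
    ii[[j]] <- nz; jj[[j]] <- rep(j, length(nz)); xx[[j]] <- dv[nz]
    # extract only the inputs this variant consumes
    sample <- list(dose = array(0, shape))
    if (ck$variant == 0) {
      sample$ct <- extract_bev_cuboid(case$ct_corr, b, shape = shape,
                                      entry_depth_mm = ed)$values /
        (ck$ct_global_max %||% 1)
      sample$mri <- sample$ct
    } else {
      sample$mri <- extract_bev_cuboid(mri, b, shape = shape,
                                       entry_depth_mm = ed)$values
      if (ck$variant == 1)
        sample$ac <- ac_cuboid_analytic(case$ac_info, b, ed,
                                        shape)$values
    }
    pred <- predict_checkpoint(ck, sample)
    pred_cub <- bev_cuboid(pmax(pred$dose, 0) * gmax, b, ed)
    pv <- insert_bev_dose(pred_cub, g)$values
    pnz <- which(pv > 1e-6 * max(max(pv), 1e-12))
    pii[[j]] <- pnz; pjj[[j]] <- rep(j, length(pnz)); pxx[[j]] <- pv[pnz]
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(xx), dims = c(nv, length(beams)))
  Ap <- Matrix::sparseMatrix(i = unlist(pii), j = unlist(pjj),
                             x = unlist(pxx), dims = c(nv, length(beams)))
  infl <- structure(list(A = A, grid = g), class = "influence")
  if (is.null(obj))
    obj <- plan_objectives(ptv_target_gy = spec$prescription_gy)
  wts <- optimize_weights(infl, case$ptv, case$body, obj,
                          tol = 1e-5, max_iter = 300)
  mc_dose <- influence_dose(infl, wts$w)
  nrm <- normalize_plan_d95(mc_dose, case$ptv,
                            prescription_gy = spec$prescription_gy)
  pred_dose <- volume_grid(array(as.numeric(Ap %*% wts$w) * nrm$scale,
                                 g$shape), grid = g,
                           quantity = "DOSE_GY")
  gpr <- function(pct, mm) gamma_passing_rate(
    nrm$dose, pred_dose, gamma_criteria(pct, mm, 0.10))$passing_rate_pct
  structs <- list(PTV = case$ptv, bladder = case$bladder,
                  rectum = case$rectum)
  dvh_rows <- do.call(rbind, lapply(names(structs), function(nm) {
    cm <- dvh_curve(nrm$dose, structs[[nm]], name = nm)
    cp <- dvh_curve(pred_dose, structs[[nm]], name = nm)
    data.frame(structure = nm,
               D2_mc = dvh_D(cm, 2), D2_pred = dvh_D(cp, 2),
               D95_mc = dvh_D(cm, 95), D95_pred = dvh_D(cp, 95),
               V50_mc = dvh_V(cm, 50), V50_pred = dvh_V(cp, 50),
               V60_mc = dvh_V(cm, 60), V60_pred = dvh_V(cp, 60),
               V65_mc = dvh_V(cm, 65), V65_pred = dvh_V(cp, 65))
  }))
  list(weights = wts, scale = nrm$scale,
       gamma_pr = c(`2/2` = gpr(2, 2), `1/2` = gpr(1, 2),
                    `1/1` = gpr(1, 1)),
       dvh = dvh_rows,
       ptv_d95_gy = dvh_D(dvh_curve(nrm$dose, case$ptv), 95))
}

#' Compare per-patient gamma distributions across model variants
#'
#' @param reports list of [run_experiment()] reports (or one report
#'   containing several variants), all on the same test manifest.
#' @return Data.frame of per-patient, per-variant distribution
#'   summaries (mean, median, quartiles, 5th/95th percentiles).
#' @export
compare_models <- function(reports) {
  if (!is.null(reports$beam_table)) reports <- list(reports)
  bt <- do.call(rbind, lapply(reports, `[[`, "beam_table"))
  key <- lapply(reports, function(r)
    r$beam_table[order(r$beam_table$beam),
                 c("beam", "patient", "gantry_deg")])
  if (length(unique(vapply(key, function(k)
    paste(k$patient, k$gantry_deg, collapse = ";"), ""))) > 1)
    stop("reports use mismatched test manifests")
  do.call(rbind, lapply(split(bt, list(bt$variant, bt$patient),
                              drop = TRUE), function(x) {
    q <- quantile(x$gamma_pr, c(0.05, 0.25, 0.5, 0.75, 0.95),
                  names = FALSE)
    data.frame(variant = x$variant[1], patient = x$patient[1],
               n = nrow(x), mean = mean(x$gamma_pr), p5 = q[1],
               q25 = q[2], median = q[3], q75 = q[4], p95 = q[5])
  }))
}
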