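# The dynamic-EF emulator: a generalized additive model with a log link
# trained on the synthetic EF table, plus emission computation for both the
# dynamic and the static (fixed 1 percent) approaches, and validation of the
# emulator against the generating truth surface along aridity and SOC
# gradients.

#' Emulator hyperparameters
#'
#' @param k basis dimension for the main smooth terms (texture and bulk
#'   density get `min(k, 6)`).
#' @param rmse_ceiling training aborts (error `rmse_ceiling`) if the
#'   held-out RMSE exceeds this many EF percentage points.
#' @param ef_max predictions are clipped to `[0, ef_max]` percent.
#' @param holdout_frac fraction of records held out for validation.
#' @return list of class `emulator_control`.
#' @export
emulator_control <- function(k = 10, rmse_ceiling = 1.0, ef_max = 25,
                             holdout_frac = 0.2) {
  structure(list(k = k, rmse_ceiling = rmse_ceiling, ef_max = ef_max,
                 holdout_frac = holdout_frac), class = "emulator_control")
}

check_schema <- function(tab, need = ef_feature_names()) {
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop2("schema_error", "missing feature column(s): %s",
          paste(miss, collapse = ", "))
  for (f in need)
    if (!is.numeric(tab[[f]]))
      stop2("schema_error", "feature '%s' is not numeric", f)
  invisible(TRUE)
}

#' Train the EF emulator
#'
#' Fits a Gaussian GAM with a log link on the feature schema: the truth the
#' synthetic world encodes is a product of positive smooth factors, so on
#' the link scale the surface is additive and the model family is exactly
#' right; more generally the log link enforces positive fitted EF without
#' clipping the fit itself.  An 80/20 seeded split provides a held-out RMSE
#' that must stay below `control$rmse_ceiling`.
#'
#' Fitting is deterministic for a fixed `(training_table, seed)`.
#'
#' @param training_table output of [emit_training_table()] (features +
#'   label column `ef`); at least 500 complete records.
#' @param control an [emulator_control()].
#' @param seed seed for the train/validation split.
#' @return object of class `ef_emulator`.
#' @export
train_emulator <- function(training_table, control = emulator_control(),
                           seed = 1L) {
  feats <- ef_feature_names()
  check_schema(training_table, c(feats, "ef"))
  tab <- as.data.frame(training_table[, c(feats, "ef"), with = FALSE])
  if (nrow(tab) < 500)
    stop2("data_error", "need >= 500 training records, got %d", nrow(tab))
  if (any(!complete.cases(tab)))
    stop2("data_error", "missing values in training table")

  idx <- with_seed(seed, sample.int(nrow(tab)))
  n_hold <- max(1L, floor(control$holdout_frac * nrow(tab)))
  hold <- idx[seq_len(n_hold)]
  train <- tab[-hold, , drop = FALSE]
  test <- tab[hold, , drop = FALSE]

  ksm <- function(x, kk) as.integer(max(3, min(kk, length(unique(x)) - 1)))
  form <- stats::as.formula(paste("ef ~",
    paste(sprintf("s(%s, k = %d)", feats,
                  vapply(feats, function(f)
                    ksm(train[[f]], if (f %in% c("bulk_density", "sand_frac",
                                                 "clay_frac"))
                      min(control$k, 6L) else control$k), integer(1))),
          collapse = " + ")))
  fit <- if (sd(train$ef) < 1e-10) {
    # degenerate (constant-label) table: REML on a full smooth basis is
    # singular; an intercept-only model is the exact fit
    mgcv::gam(ef ~ 1, data = train, family = stats::gaussian(link = "log"),
              mustart = pmax(train$ef, 0.05))
  } else {
    mgcv::gam(form, data = train, family = stats::gaussian(link = "log"),
              method = "REML", mustart = pmax(train$ef, 0.05))
  }
  pred <- pmin(pmax(predict(fit, newdata = test, type = "response"), 0),
               control$ef_max)
  rmse <- sqrt(mean((pred - test$ef)^2))
  if (rmse > control$rmse_ceiling)
    stop2("rmse_ceiling",
          "held-out RMSE %.3f exceeds ceiling %.3f EF points",
          rmse, control$rmse_ceiling)
  structure(list(fit = fit, features = feats, rmse = rmse,
                 n_records = nrow(tab), seed = seed,
                 ef_max = control$ef_max),
            class = "ef_emulator")
}

#' @export
print.ef_emulator <- function(x, ...) {
  cat(sprintf("<ef_emulator> %d records, held-out RMSE %.3f EF points\n",
              x$n_records, x$rmse))
  invisible(x)
}

#' Predict EF on a feature table
#'
#' @param emulator an `ef_emulator`.
#' @param feature_table table containing the feature schema (extra id
#'   columns such as `cell_id`/`year` are ignored).
#' @return EF percent, clipped to `[0, ef_max]`; `numeric(0)` for an empty
#'   table.
#' @export
predict_ef <- function(emulator, feature_table) {
  check_schema(feature_table, emulator$features)
  if (nrow(feature_table) == 0) return(numeric(0))
  p <- predict(emulator$fit, newdata = as.data.frame(feature_table),
               type = "response")
  pmin(pmax(as.numeric(p), 0), emulator$ef_max)
}

#' Compute N2O emissions from EF and fertilizer
#'
#' Emission attributable to fertilizer on each cell is `(EF/100) * n_rate *
#' fertilized area`.  The static approach fixes EF at exactly 1 percent
#' (IPCC Tier-1).  Rates are reported per square metre of fertilized land.
#'
#' @param ef EF percent per cell (recycled if length 1); ignored when
#'   `static = TRUE`.
#' @param n_rate kg N / ha / yr per cell.
#' @param fert_area_ha fertilized hectares per cell.
#' @param static if `TRUE`, use EF = 1 exactly.
#' @return `data.table` with `emission_kg` (kg N2O-N / yr), `emission_tg`,
#'   and `rate_g_m2` (g N2O-N per m2 of fertilized land).
#' @export
compute_emissions <- function(ef = NULL, n_rate, fert_area_ha,
                              static = FALSE) {
  if (any(n_rate < 0)) stop2("invalid_argument", "negative fertilizer rates")
  if (static) ef <- 1
  if (is.null(ef)) stop2("invalid_argument", "ef required unless static")
  kg <- ef / 100 * n_rate * fert_area_ha
  data.table(emission_kg = kg, emission_tg = kg / 1e9,
             rate_g_m2 = ef / 100 * n_rate * 0.1)
}

#' Validate the emulator against the truth surface along gradients
#'
#' Predicts on a probe table, evaluates the noiseless truth surface at the
#' same points, and reports per-bin mean predicted and true EF along the
#' aridity and SOC gradients plus the area-weighted gradient RMSE (the
#' pooled point-wise RMSE, which per-bin MSEs decompose exactly).
#'
#' @param emulator an `ef_emulator`.
#' @param surface the generating `ef_surface`.
#' @param probe feature table spanning the aridity and SOC gradients.
#' @param n_bins number of quantile bins per gradient.
#' @param out_csv optional path; if given, the per-bin tables are written as
#'   one CSV with a `gradient` column.
#' @return list of class `ef_validation`: `aridity`/`soc` bin tables,
#'   `rmse_aridity`, `rmse_soc`, `rmse_pooled`.
#' @export
validate_against_truth <- function(emulator, surface, probe, n_bins = 10,
                                   out_csv = NULL) {
  check_schema(probe, emulator$features)
  pred <- predict_ef(emulator, probe)
  truth <- ef_true(surface, probe$n_rate, probe$tas, probe$aridity_index,
                   probe$soc, probe$ph)
  err2 <- (pred - truth)^2
  bin_table <- function(x) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- if (length(br) > 2)
      cut(x, breaks = br, include.lowest = TRUE) else factor(rep(1, length(x)))
    dt <- data.table(bin = bin, x = x, pred = pred, truth = truth,
                     err2 = err2)
    dt[, .(x_mid = mean(x), n = .N, mean_pred = mean(pred),
           mean_truth = mean(truth), rmse = sqrt(mean(err2))), by = bin][
             order(x_mid)]
  }
  ar <- bin_table(probe$aridity_index)
  so <- bin_table(probe$soc)
  res <- structure(list(
    aridity = ar, soc = so,
    rmse_aridity = sqrt(sum(ar$n * ar$rmse^2) / sum(ar$n)),
    rmse_soc = sqrt(sum(so$n * so$rmse^2) / sum(so$n)),
    rmse_pooled = sqrt(mean(err2))), class = "ef_validation")
  if (!is.null(out_csv)) {
    both <- rbind(cbind(gradient = "aridity", ar), cbind(gradient = "soc", so))
    write.csv(both, out_csv, row.names = FALSE)
  }
  res
}

#' @export
print.ef_validation <- function(x, ...) {
  cat(sprintf(
    "<ef_validation> RMSE: aridity gradient %.3f, SOC gradient %.3f, pooled %.3f EF points\n",
    x$rmse_aridity, x$rmse_soc, x$rmse_pooled))
  invisible(x)
}
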