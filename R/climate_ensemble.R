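# Climate harmonization: delta-method bias correction of pseudo-GCM members
# against observations, a Thornthwaite-style aridity index, and extraction
# of the annual features the EF emulator consumes.

#' Delta-method bias correction
#'
#' For each cell and calendar month, corrects a projected series by removing
#' the model's mean offset from observations over a reference period:
#'
#'   corrected = projected - (mean(model, ref) - mean(obs, ref))
#'
#' applied to temperature (unbounded) and precipitation (floored at zero).
#' Correcting a model whose reference climatology already equals the
#' observations is the identity.
#'
#' @param projected monthly `data.table` (`cell_id`, `year`, `month`, `tas`,
#'   `pr`) to correct.
#' @param historical_model monthly table from the same model covering the
#'   reference period.
#' @param observed monthly observation table covering the reference period.
#' @param reference_period length-2 integer year range, inclusive.
#' @return corrected copy of `projected`, with attributes `member_id` and
#'   `pathway` carried over and `reference_period` recorded.
#' @export
delta_bias_correct <- function(projected, historical_model, observed,
                               reference_period = c(1995, 2014)) {
  if (length(reference_period) != 2 || reference_period[2] < reference_period[1])
    stop2("invalid_argument", "bad reference_period")
  cells <- sort(unique(projected$cell_id))
  if (!setequal(cells, unique(historical_model$cell_id)) ||
      !setequal(cells, unique(observed$cell_id)))
    stop2("domain_mismatch", "cell sets of the three series differ")
  ref <- function(x) {
    r <- x[year >= reference_period[1] & year <= reference_period[2],
           .(tas_ref = mean(tas), pr_ref = mean(pr)),
           by = .(cell_id, month)]
    if (nrow(r) == 0)
      stop2("invalid_argument", "reference period not covered by input")
    r
  }
  hm <- ref(historical_model)
  ob <- ref(observed)
  bias <- hm[ob, on = c("cell_id", "month")]
  bias[, `:=`(tas_bias = tas_ref - i.tas_ref, pr_bias = pr_ref - i.pr_ref)]
  out <- copy(projected)[bias[, .(cell_id, month, tas_bias, pr_bias)],
                         on = c("cell_id", "month")]
  out[, `:=`(tas = tas - tas_bias, pr = pmax(pr - pr_bias, 0))]
  out[, c("tas_bias", "pr_bias") := NULL]
  setkey(out, cell_id, year, month)
  setattr(out, "member_id", attr(projected, "member_id"))
  setattr(out, "pathway", attr(projected, "pathway"))
  setattr(out, "reference_period", as.integer(reference_period))
  out[]
}

#' Bias-correct a whole climate ensemble
#'
#' Applies [delta_bias_correct()] member-wise, using each member's own
#' historical segment as the model reference and the ensemble's OBS series
#' (or a supplied one) as the observational reference.
#'
#' @param ensemble a `climate_ensemble`.
#' @param observed monthly OBS table; defaults to `ensemble$obs`.
#' @param reference_period inclusive year range.
#' @return a `climate_ensemble` with corrected members.
#' @export
bias_correct_ensemble <- function(ensemble, observed = NULL,
                                  reference_period = c(1995, 2014)) {
  observed <- observed %||% ensemble$obs
  if (is.null(observed))
    stop2("invalid_argument", "no observed series available")
  ensemble$members <- lapply(ensemble$members, function(m)
    delta_bias_correct(m, m, observed, reference_period))
  ensemble
}

# Thornthwaite monthly potential evapotranspiration, day length fixed at
# 12 h.  `temp` is an n x 12 matrix of monthly means (degC); returns annual
# PET in mm.
thornthwaite_pet <- function(temp) {
  temp <- rbind(temp)
  tpos <- pmax(temp, 0)
  I <- rowSums((tpos / 5)^1.514)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.7912e-2 * I + 0.49239
  pet <- 16 * (10 * tpos / ifelse(I > 0, I, NA))^a
  pet[!is.finite(pet)] <- 0
  rowSums(pet)
}

#' Annual aridity index
#'
#' AI = annual precipitation / annual potential evapotranspiration, with PET
#' from the Thornthwaite temperature formula (12-hour day length).  Zero
#' precipitation gives AI = 0; zero PET (all months at or below freezing)
#' gives the configured cap instead of an infinite value.
#'
#' @param annual_precip mm / yr, length n.
#' @param monthly_temp n x 12 matrix (or length-12 vector) of monthly mean
#'   temperature, degC.
#' @param cap AI value substituted when PET = 0.
#' @return numeric vector of AI values.
#' @export
aridity_index <- function(annual_precip, monthly_temp, cap = 10) {
  if (any(annual_precip < 0))
    stop2("invalid_argument", "negative precipitation")
  temp <- rbind(monthly_temp)
  if (ncol(temp) != 12)
    stop2("invalid_argument", "need 12 monthly temperatures per cell-year")
  pet <- thornthwaite_pet(temp)
  ai <- ifelse(pet > 0, annual_precip / pet, cap)
  ai[annual_precip == 0] <- 0
  unname(ai)
}

#' Extract annual climate features
#'
#' Collapses a monthly series to per cell-year annual mean temperature,
#' total precipitation, and aridity index.  Every cell-year must have all
#' 12 months.
#'
#' @param series monthly `data.table` with `cell_id`, `year`, `month`,
#'   `tas`, `pr`.
#' @param ai_cap cap passed to [aridity_index()].
#' @return `data.table` with `cell_id`, `year`, `tas` (annual mean degC),
#'   `pr` (annual mm), `aridity_index`.
#' @export
annual_features <- function(series, ai_cap = 10) {
  cnt <- series[, .N, by = .(cell_id, year)]
  if (any(cnt$N != 12))
    stop2("incomplete_year", "cell-years without 12 months present")
  if (!identical(key(series), c("cell_id", "year", "month"))) {
    series <- copy(series)
    setkey(series, cell_id, year, month)
  }
  ann <- series[, .(tas = mean(tas), pr = sum(pr)), by = .(cell_id, year)]
  tm <- matrix(series$tas, ncol = 12, byrow = TRUE)
  ann[, aridity_index := aridity_index(pr, tm, cap = ai_cap)]
  setkey(ann, cell_id, year)
  ann[]
}

#' Join annual climate features with soil and fertilizer into the emulator
#' feature schema
#'
#' Produces exactly the columns in [ef_feature_names] (plus `cell_id`,
#' `year`), guaranteeing that training and prediction tables share one
#' schema.  `fertilizer` may be a baseline table (column `n_rate_2010`,
#' treated as time-invariant) or a per cell-year table with columns
#' `cell_id`, `year`, `n_rate`.
#'
#' @param annual output of [annual_features()].
#' @param soil output of [generate_soil()].
#' @param fertilizer baseline or scenario fertilizer table.
#' @return feature `data.table` keyed by `cell_id`, `year`.
#' @export
assemble_features <- function(annual, soil, fertilizer) {
  tab <- soil[annual, on = "cell_id"]
  if ("n_rate_2010" %in% names(fertilizer)) {
    tab <- fertilizer[tab, on = "cell_id"]
    setnames(tab, "n_rate_2010", "n_rate")
  } else {
    tab <- fertilizer[tab, on = c("cell_id", "year")]
  }
  setcolorder(tab, c("cell_id", "year", ef_feature_names()))
  setkey(tab, cell_id, year)
  tab[]
}
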