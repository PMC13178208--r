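# Scenario projection over the climate-member ensemble, ensemble
# percentile summaries, relative and cumulative change diagnostics,
# reduction-goal timelines, regional aggregation, CO2-equivalent
# conversion, and the static-vs-dynamic gap.

#' Project one scenario over a climate ensemble
#'
#' For each climate member: extract annual features, join soil and the
#' scenario fertilizer field, predict EF with the emulator, and convert to
#' emissions.  A parallel static series (EF = 1 percent exactly) is derived
#' from the same fertilizer field; it does not depend on climate.
#' Cell-level emission fields (median across members) are retained for the
#' years in `keep_cell_years`, for hotspot analysis.
#'
#' @param scenario_id `"INMS1"`..`"INMS7"`, or `NULL` to skip the pathway
#'   check (e.g. historical runs).
#' @param emulator trained [train_emulator()] result.
#' @param climate a `climate_ensemble`; its pathway must match the
#'   scenario's.
#' @param fert a `fert_scenario` field.
#' @param domain,soil world components.
#' @param keep_cell_years years for which per-cell median emission fields
#'   are retained (default all projection years).
#' @return object of class `scenario_projection`: `member_tg` (years x
#'   members matrix, Tg N / yr), `static_tg`, `years`, `scenario`,
#'   `cell_emissions` (cells x kept-years matrix of median kg N / yr),
#'   `cell_id`, `fert_area_ha`.
#' @export
project_scenario <- function(scenario_id, emulator, climate, fert, domain,
                             soil, keep_cell_years = NULL) {
  if (!is.null(scenario_id)) {
    sc <- scenario_table()[scenario == scenario_id]
    if (nrow(sc) != 1)
      stop2("invalid_argument", "unknown scenario '%s'", scenario_id)
    if (sc$pathway != climate$pathway)
      stop2("config_error",
            "scenario %s expects pathway %s but ensemble has %s",
            scenario_id, sc$pathway, climate$pathway)
  }
  years <- intersect(climate$years, fert$years)
  if (length(years) == 0)
    stop2("invalid_argument", "climate and fertilizer years do not overlap")
  keep_cell_years <- sort(intersect(keep_cell_years %||% years, years))
  fa <- fertilized_area(domain)
  rates <- fert_rates_long(fert, years)
  n_mem <- length(climate$members)
  member_tg <- matrix(NA_real_, length(years), n_mem,
                      dimnames = list(years, NULL))
  keep_idx <- match(keep_cell_years, years)
  cell_keep <- array(NA_real_, c(nrow(domain), length(keep_cell_years),
                                 n_mem))
  for (m in seq_len(n_mem)) {
    mon <- climate$members[[m]][year %in% years]
    feat <- assemble_features(annual_features(mon), soil, rates)
    ef <- numeric(nrow(feat))
    fert_rows <- feat$n_rate > 0
    if (any(fert_rows))
      ef[fert_rows] <- predict_ef(emulator, feat[fert_rows])
    em <- compute_emissions(ef, feat$n_rate,
                            fa$fert_area_ha[match(feat$cell_id, fa$cell_id)])
    feat[, emission_kg := em$emission_kg]
    gl <- feat[, .(tg = sum(emission_kg) / 1e9), keyby = year]
    member_tg[, m] <- gl$tg[match(years, gl$year)]
    if (length(keep_cell_years)) {
      wide <- dcast(feat[year %in% keep_cell_years],
                    cell_id ~ year, value.var = "emission_kg")
      cell_keep[, , m] <- as.matrix(wide[match(domain$cell_id, wide$cell_id),
                                         -1, drop = FALSE])
    }
  }
  static_kg <- colSums(fert$rates[, as.character(years), drop = FALSE] *
                         fa$fert_area_ha[match(fert$cell_id, fa$cell_id)]) *
    0.01
  cell_med <- if (length(keep_cell_years))
    apply(cell_keep, c(1, 2), median) else NULL
  if (!is.null(cell_med))
    dimnames(cell_med) <- list(NULL, as.character(keep_cell_years))
  structure(list(scenario = scenario_id, years = years,
                 member_tg = member_tg, static_tg = static_kg / 1e9,
                 cell_emissions = cell_med, cell_id = domain$cell_id,
                 fert_area_ha = fa$fert_area_ha[match(domain$cell_id,
                                                      fa$cell_id)]),
            class = "scenario_projection")
}

#' @export
print.scenario_projection <- function(x, ...) {
  cat(sprintf("<scenario_projection> %s: %d members, %d-%d\n",
              x$scenario %||% "(historical)", ncol(x$member_tg),
              min(x$years), max(x$years)))
  invisible(x)
}

#' Ensemble median and interquartile band
#'
#' Per-year median, 25th and 75th percentiles across members, using the
#' linear-interpolation percentile convention (R quantile type 7).
#'
#' @param member_series years x members matrix (rownames = years) or a
#'   `scenario_projection`.
#' @return `data.table` with `year`, `median`, `p25`, `p75`.
#' @export
ensemble_summary <- function(member_series) {
  if (inherits(member_series, "scenario_projection"))
    member_series <- member_series$member_tg
  if (is.null(dim(member_series)) || ncol(member_series) < 1 ||
      nrow(member_series) < 1)
    stop2("invalid_argument", "empty member series")
  qs <- t(apply(member_series, 1, quantile, probs = c(0.25, 0.5, 0.75),
                type = 7))
  data.table(year = as.integer(rownames(member_series)),
             median = qs[, 2], p25 = qs[, 1], p75 = qs[, 3])
}

#' Relative change versus a baseline year
#'
#' `100 * (x_t - x_base) / x_base`, in percent.
#'
#' @param series named numeric vector (names = years) or `data.table` with
#'   `year` and a value column.
#' @param baseline_year year used as the base (default 2010).
#' @param value_col value column when `series` is a table.
#' @return named numeric vector of percent changes.
#' @export
relative_change <- function(series, baseline_year = 2010,
                            value_col = "median") {
  v <- series_as_vector(series, value_col)
  base <- v[as.character(baseline_year)]
  if (is.na(base))
    stop2("invalid_argument", "baseline year %d not in series", baseline_year)
  if (base == 0)
    stop2("undefined_baseline", "baseline value is zero")
  100 * (v - base) / base
}

series_as_vector <- function(series, value_col = "median") {
  if (is.data.frame(series)) {
    v <- series[[value_col]]
    names(v) <- as.character(series$year)
    v
  } else {
    if (is.null(names(series)))
      stop2("invalid_argument", "series must have year names")
    series
  }
}

#' First year a reduction goal is met
#'
#' Annual basis: first year `t` with `x_t <= (1 - goal) * x_2010`.
#' Cumulative basis: first year `t` with `sum(x_{2011..t}) <=
#' (1 - goal) * (t - 2010) * x_2010`, i.e. the running emission budget
#' beats holding the reduced 2010 level every year.  Attainment is the
#' first crossing, not sustained attainment.
#'
#' @param series named numeric vector or table (years >= baseline).
#' @param goal_fraction reduction goal in (0, 1), e.g. 0.25 or 0.45.
#' @param basis `"annual"` or `"cumulative"`.
#' @param baseline_year base year (default 2010).
#' @param value_col value column when `series` is a table.
#' @return integer year, or `NA` if the goal is never met by the series
#'   end.
#' @export
cumulative_target_year <- function(series, goal_fraction,
                                   basis = c("annual", "cumulative"),
                                   baseline_year = 2010,
                                   value_col = "median") {
  basis <- match.arg(basis)
  if (goal_fraction <= 0 || goal_fraction >= 1)
    stop2("invalid_argument", "goal_fraction must be in (0, 1)")
  v <- series_as_vector(series, value_col)
  yrs <- as.integer(names(v))
  base <- v[as.character(baseline_year)]
  if (is.na(base)) stop2("invalid_argument", "baseline year missing")
  target <- (1 - goal_fraction) * base
  after <- yrs > baseline_year
  if (basis == "annual") {
    hit <- after & v <= target
  } else {
    csum <- cumsum(ifelse(after, v, 0))
    hit <- after & csum <= target * (yrs - baseline_year)
  }
  if (!any(hit)) return(NA_integer_)
  min(yrs[hit])
}

#' Regional emission totals and shares
#'
#' @param cell_emission_kg per-cell emissions (kg N / yr) aligned with
#'   `domain$cell_id`.
#' @param domain the `grid_domain`; every cell must carry a region label.
#' @return `data.table` with `region_id`, `emission_tg`, `share`, sorted by
#'   descending share.
#' @export
regional_totals <- function(cell_emission_kg, domain) {
  if (any(is.na(domain$region_id)))
    stop2("domain_error", "cells without a region label")
  dt <- data.table(region_id = domain$region_id,
                   kg = cell_emission_kg)
  out <- dt[, .(emission_tg = sum(kg) / 1e9), by = region_id]
  out[, share := emission_tg / sum(emission_tg)]
  setorder(out, -share)
  out[]
}

#' Mitigation potential of a policy shift
#'
#' Difference between a business-as-usual and an ambitious series at a
#' given year, as Tg N / yr, percent of the BAU level, Pg CO2-equivalent
#' (via the N2O/N mass ratio 44/28 and a 100-year global warming
#' potential), and Mg CO2e per hectare of cropland if an area is supplied.
#'
#' @param bau_series,ambitious_series named vectors or tables on the same
#'   years.
#' @param year evaluation year.
#' @param gwp100 GWP100 of N2O (mass basis); default 265.
#' @param cropland_area_ha optional global cropland area for the per-ha
#'   intensity.
#' @param value_col value column for table inputs.
#' @return list with `delta_tg`, `percent`, `pg_co2e`, `mg_co2e_per_ha`.
#' @export
mitigation_potential <- function(bau_series, ambitious_series, year,
                                 gwp100 = 265, cropland_area_ha = NULL,
                                 value_col = "median") {
  b <- series_as_vector(bau_series, value_col)[as.character(year)]
  a <- series_as_vector(ambitious_series, value_col)[as.character(year)]
  if (is.na(b) || is.na(a))
    stop2("invalid_argument", "year %s missing from a series", year)
  delta <- unname(b - a)
  pg <- delta * (44 / 28) * gwp100 / 1000
  list(delta_tg = delta,
       percent = if (b != 0) 100 * delta / unname(b) else 0,
       pg_co2e = pg,
       mg_co2e_per_ha = if (!is.null(cropland_area_ha))
         pg * 1e9 / cropland_area_ha else NA_real_)
}

#' Static-vs-dynamic emission gap
#'
#' @param dynamic_series,static_series named vectors or tables on the same
#'   years.
#' @param value_col value column for table inputs.
#' @return `data.table` with `year`, `dynamic_tg`, `static_tg`, `gap_tg`
#'   (dynamic minus static) and `gap_pct` (percent of the dynamic value).
#' @export
static_dynamic_gap <- function(dynamic_series, static_series,
                               value_col = "median") {
  d <- series_as_vector(dynamic_series, value_col)
  s <- series_as_vector(static_series, value_col)
  yrs <- intersect(names(d), names(s))
  if (length(yrs) == 0) stop2("invalid_argument", "no common years")
  d <- d[yrs]; s <- s[yrs]
  data.table(year = as.integer(yrs), dynamic_tg = unname(d),
             static_tg = unname(s), gap_tg = unname(d - s),
             gap_pct = unname(ifelse(d != 0, 100 * (d - s) / d, 0)))
}
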