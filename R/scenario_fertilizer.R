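# Scenario fertilizer inputs: the seven policy x climate combinations,
# country-level nitrogen-use-efficiency (NUE) trajectories, fertilizer
# totals derived from crop N demand / NUE, and grid-level scaling that
# preserves the baseline spatial pattern.

#' The seven policy-by-climate scenarios
#'
#' INMS1 (business as usual) pairs no nitrogen regulation with SSP5-8.5;
#' INMS2 (low ambition) with SSP2-4.5; INMS3 (moderate) and INMS4-6 (high,
#' best-case, best-case plus) with SSP2-4.5; INMS7 (bioenergy, high
#' ambition) with SSP1-2.6.  The best-case / best-case-plus / bioenergy
#' variants differ from INMS4 only by an additional fertilizer-demand
#' reduction reached linearly by 2050 (defaults -10 / -20 / -15 percent),
#' standing in for dietary-shift and food-waste mechanisms that are out of
#' scope here.
#'
#' @return `data.table` with columns `scenario`, `ambition` (`BAU`, `low`,
#'   `moderate`, `high`), `pathway`, `demand_mult_2050`.
#' @export
scenario_table <- function() {
  data.table(
    scenario = paste0("INMS", 1:7),
    ambition = c("BAU", "low", "moderate", "high", "high", "high", "high"),
    pathway = c("SSP5-8.5", "SSP2-4.5", "SSP2-4.5", "SSP2-4.5", "SSP2-4.5",
                "SSP2-4.5", "SSP1-2.6"),
    demand_mult_2050 = c(1, 1, 1, 1, 0.90, 0.80, 0.85)
  )
}

#' Default per-country NUE policy parameters
#'
#' Target NUE is 0.75 for the EU and USA, 0.60 for China and much of Asia
#' (CHN, SAS, SEAS, CAS, KAJ, MIDE), and 0.70 elsewhere.  2010 NUE and crop
#' N demand growth are set once per region at values a nitrogen-budget
#' analyst would call plausible (low NUE / fast demand growth in South and
#' Southeast Asia and Africa, high NUE / slow growth in the OECD); they are
#' stated-world constants, not fitted quantities.  OECD countries reach the
#' target by 2030 under high ambition, 2050 under moderate; non-OECD by
#' 2035 / 2050.
#'
#' @param domain a `grid_domain`; one row per country is produced.
#' @return `data.table` with `country_id`, `region_id`, `nue_2010`,
#'   `nue_target`, `oecd`, `demand_growth`.
#' @export
default_country_policy <- function(domain) {
  nue0 <- c(BRA = 0.50, CAM = 0.45, CAN = 0.65, CAS = 0.45, CHN = 0.35,
            EQAF = 0.55, EU = 0.62, KAJ = 0.55, MIDE = 0.45, NAF = 0.40,
            NSA = 0.50, OCE = 0.60, RUS = 0.50, SAF = 0.50, SAS = 0.40,
            SEAS = 0.45, SSA = 0.55, USA = 0.65)
  asia <- c("CHN", "SAS", "SEAS", "CAS", "KAJ", "MIDE")
  oecd <- c("EU", "USA", "CAN", "OCE", "KAJ")
  growth <- c(EQAF = 0.020, NAF = 0.020, SAF = 0.018, SAS = 0.015,
              SEAS = 0.015, CHN = 0.005)
  cp <- unique(domain[, .(country_id, region_id)])
  cp[, nue_2010 := nue0[region_id]]
  cp[, nue_target := fifelse(region_id %in% c("EU", "USA"), 0.75,
                             fifelse(region_id %in% asia, 0.60, 0.70))]
  cp[, oecd := region_id %in% oecd]
  cp[, demand_growth := fifelse(region_id %in% names(growth),
                                growth[region_id], fifelse(oecd, 0.003, 0.010))]
  setkey(cp, country_id)
  cp[]
}

#' Build a yearly NUE trajectory for one country
#'
#' High and moderate ambition interpolate linearly from `nue_2010` to
#' `nue_target`, reaching it in `target_year` (then flat).  BAU holds NUE at
#' its 2010 value; low ambition drifts linearly toward the target but closes
#' only half the gap by 2050, so the target is never met.
#'
#' @param country_spec list or one-row table with `nue_2010`, `nue_target`,
#'   and optionally `target_year`.
#' @param policy one of `"BAU"`, `"low"`, `"moderate"`, `"high"`.
#' @param years integer years starting at 2010.
#' @param low_gap_close fraction of the gap closed by 2050 under low
#'   ambition.
#' @return numeric NUE path, one value per year.
#' @export
build_nue_trajectory <- function(country_spec, policy, years,
                                 low_gap_close = 0.5) {
  if (years[1] != 2010)
    stop2("invalid_argument", "years must start at 2010")
  n0 <- country_spec$nue_2010
  nt <- country_spec$nue_target
  ty <- country_spec$target_year %||%
    switch(policy, high = 2030, moderate = 2050, 2050)
  if (!is.null(country_spec$target_year) && country_spec$target_year < 2010)
    stop2("invalid_argument", "target_year before 2010")
  gap <- nt - n0
  path <- switch(policy,
    BAU = rep(n0, length(years)),
    low = n0 + low_gap_close * gap * pmin(1, (years - 2010) / 40),
    moderate = ,
    high = if (ty == 2010) rep(nt, length(years)) else
      n0 + gap * pmin(1, (years - 2010) / (ty - 2010)),
    stop2("invalid_argument", "unknown policy '%s'", policy))
  path
}

#' Fertilizer totals from demand and NUE paths
#'
#' F(t) = crop N demand(t) / NUE(t): better efficiency lowers the fertilizer
#' needed to meet the same crop nitrogen demand.
#'
#' @param demand_path crop N demand per year (any mass unit).
#' @param nue_path NUE per year, in (0, 1].
#' @return fertilizer totals, same unit and length as `demand_path`.
#' @export
fertilizer_from_nue <- function(demand_path, nue_path) {
  if (length(demand_path) != length(nue_path))
    stop2("invalid_argument", "demand and NUE paths differ in length")
  if (any(nue_path <= 0))
    stop2("invalid_argument", "NUE must be positive")
  demand_path / nue_path
}

#' Country fertilizer trajectories for one scenario
#'
#' Anchors each country's 2010 fertilizer total to the baseline gridded
#' field (so the grid scaling factor is exactly 1 in 2010), back-computes
#' 2010 crop N demand as `F_2010 * NUE_2010`, grows demand at the country's
#' exogenous rate (times the scenario's demand-reduction ramp), builds the
#' policy NUE path, and returns F(t) = demand / NUE.
#'
#' @param scenario_id one of `"INMS1"`..`"INMS7"`.
#' @param baseline baseline fertilizer table ([generate_baseline_fertilizer()]).
#' @param domain the `grid_domain`.
#' @param country_policy [default_country_policy()]-style table.
#' @param years years starting at 2010.
#' @return `data.table` with `scenario`, `country_id`, `year`, `nue`,
#'   `fertilizer_kg` (country total kg N / yr), `fertilizer_tg`.
#' @export
country_fertilizer_trajectories <- function(scenario_id, baseline, domain,
                                            country_policy = default_country_policy(domain),
                                            years = 2010:2050) {
  sc <- scenario_table()[scenario == scenario_id]
  if (nrow(sc) != 1)
    stop2("invalid_argument", "unknown scenario '%s'", scenario_id)
  fa <- fertilized_area(domain)
  base <- baseline[fa, on = "cell_id"]
  base[, country_id := domain$country_id[match(cell_id, domain$cell_id)]]
  f2010 <- base[, .(f2010_kg = sum(n_rate_2010 * fert_area_ha)),
                by = country_id]
  mult <- 1 + (sc$demand_mult_2050 - 1) * pmin(1, (years - 2010) / 40)
  out <- lapply(seq_len(nrow(country_policy)), function(i) {
    cs <- country_policy[i]
    f0 <- f2010[country_id == cs$country_id]$f2010_kg
    if (length(f0) == 0) f0 <- 0
    nue <- build_nue_trajectory(cs, sc$ambition, years)
    demand <- f0 * cs$nue_2010 * (1 + cs$demand_growth)^(years - 2010) * mult
    data.table(scenario = scenario_id, country_id = cs$country_id,
               year = years, nue = nue,
               fertilizer_kg = fertilizer_from_nue(demand, nue))
  })
  out <- rbindlist(out)
  out[, fertilizer_tg := fertilizer_kg / 1e9]
  setkey(out, country_id, year)
  out[]
}

#' Scale the baseline fertilizer grid to country trajectories
#'
#' Each cell's rate is the baseline rate times its country's scaling factor
#' `F_country(t) / F_country(2010)`, so within-country spatial pattern (and
#' the rank order of cells) is preserved and summing the scaled cells
#' reproduces the country trajectory to numerical tolerance.  A country
#' with a nonzero trajectory but zero baseline total cannot be scaled and
#' raises an `undefined_scaling` error; cells with zero baseline stay zero.
#'
#' @param baseline baseline fertilizer table.
#' @param country_totals output of [country_fertilizer_trajectories()].
#' @param domain the `grid_domain`.
#' @return object of class `fert_scenario`: list with `rates` (cells x
#'   years matrix of kg N / ha / yr), `cell_id`, `years`, `scenario`,
#'   `country_totals`.
#' @export
scale_gridded_fertilizer <- function(baseline, country_totals, domain) {
  years <- sort(unique(country_totals$year))
  fa <- fertilized_area(domain)
  base <- baseline[fa, on = "cell_id"]
  base[, country_id := domain$country_id[match(cell_id, domain$cell_id)]]
  f2010 <- base[, .(f2010_kg = sum(n_rate_2010 * fert_area_ha)),
                by = country_id]
  missing <- setdiff(f2010[f2010_kg > 0]$country_id,
                     unique(country_totals$country_id))
  if (length(missing))
    stop2("invalid_argument",
          "no trajectory for fertilized country %s", missing[1])
  traj <- f2010[country_totals, on = "country_id"]
  traj[is.na(f2010_kg), f2010_kg := 0]
  bad <- traj[f2010_kg <= 0 & fertilizer_kg > 0]
  if (nrow(bad))
    stop2("undefined_scaling",
          "country %s has a nonzero trajectory but zero baseline total",
          bad$country_id[1])
  traj[, factor := fifelse(f2010_kg > 0, fertilizer_kg / f2010_kg, 0)]
  fac <- dcast(traj, country_id ~ year, value.var = "factor")
  fmat <- as.matrix(fac[, -1])[match(base$country_id, fac$country_id), ,
                               drop = FALSE]
  rates <- base$n_rate_2010 * fmat
  dimnames(rates) <- list(NULL, as.character(years))
  structure(list(rates = rates, cell_id = base$cell_id, years = years,
                 scenario = country_totals$scenario[1],
                 country_totals = country_totals),
            class = "fert_scenario")
}

#' Per cell-year fertilizer table from a `fert_scenario`
#'
#' @param field a `fert_scenario`.
#' @param years subset of years (default all).
#' @return `data.table` with `cell_id`, `year`, `n_rate`.
#' @export
fert_rates_long <- function(field, years = field$years) {
  cols <- as.character(years)
  out <- data.table(cell_id = rep(field$cell_id, length(cols)),
                    year = rep(as.integer(cols), each = length(field$cell_id)),
                    n_rate = as.vector(field$rates[, cols]))
  setkey(out, cell_id, year)
  out[]
}

#' Build the complete fertilizer scenario field in one call
#'
#' @inheritParams country_fertilizer_trajectories
#' @return a `fert_scenario` (see [scale_gridded_fertilizer()]).
#' @export
build_scenario_fertilizer <- function(scenario_id, baseline, domain,
                                      country_policy = default_country_policy(domain),
                                      years = 2010:2050) {
  ct <- country_fertilizer_trajectories(scenario_id, baseline, domain,
                                        country_policy, years)
  scale_gridded_fertilizer(baseline, ct, domain)
}

#' @export
print.fert_scenario <- function(x, ...) {
  cat(sprintf("<fert_scenario> %s: %d cells x %d years (%d-%d)\n",
              x$scenario, nrow(x$rates), length(x$years), min(x$years),
              max(x$years)))
  invisible(x)
}
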