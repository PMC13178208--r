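# Hotspot prioritization and nitrification-inhibitor (NI) mitigation:
# descending ranking of cells by emission rate per unit agricultural area,
# top-fraction emission shares, NI adoption expanding along the ranking,
# minimal adoption area for a reduction goal, and expedited goal timelines.

#' Rank cells by emission rate
#'
#' Cells are ordered by descending N2O emission rate per square metre of
#' fertilized (agricultural) land, ties broken by ascending `cell_id`.
#' Cells with no agricultural area are excluded.  Cumulative agricultural
#' area fraction and cumulative emission share accompany the order.
#'
#' @param emission_kg per-cell emissions (kg N / yr) aligned with
#'   `domain$cell_id`.
#' @param domain the `grid_domain`.
#' @return `data.table` of class `hotspot_ranking` with `cell_id`,
#'   `rate_g_m2`, `fert_area_ha`, `emission_kg`, `cum_area_frac`,
#'   `cum_share`.
#' @export
rank_hotspots <- function(emission_kg, domain) {
  fa <- fertilized_area(domain)
  dt <- data.table(cell_id = domain$cell_id,
                   fert_area_ha = fa$fert_area_ha[match(domain$cell_id,
                                                        fa$cell_id)],
                   emission_kg = emission_kg)
  dt <- dt[fert_area_ha > 0]
  # kg/ha -> g/m2: x1000 g / 1e4 m2
  dt[, rate_g_m2 := emission_kg / fert_area_ha * 0.1]
  setorder(dt, -rate_g_m2, cell_id)
  dt[, cum_area_frac := cumsum(fert_area_ha) / sum(fert_area_ha)]
  tot <- sum(dt$emission_kg)
  dt[, cum_share := if (tot > 0) cumsum(emission_kg) / tot else 0]
  setattr(dt, "class", c("hotspot_ranking", class(dt)))
  dt[]
}

# Cumulative emissions (kg) of the adopted prefix at agricultural-area
# fraction f, counting the boundary cell pro-rata.
prefix_emissions <- function(ranking, fraction) {
  if (fraction <= 0) return(0)
  if (fraction >= 1) return(sum(ranking$emission_kg))
  A <- sum(ranking$fert_area_ha)
  target <- fraction * A
  cum_a <- cumsum(ranking$fert_area_ha)
  i <- findInterval(target, cum_a) + 1L  # first cell not fully covered
  full <- if (i > 1) cumsum(ranking$emission_kg)[i - 1L] else 0
  a_before <- if (i > 1) cum_a[i - 1L] else 0
  partial <- if (i <= nrow(ranking))
    ranking$emission_kg[i] * (target - a_before) / ranking$fert_area_ha[i]
  else 0
  full + partial
}

#' Emission share of the top area fraction
#'
#' Share of total emissions coming from the smallest prefix of the
#' descending ranking that covers `fraction` of the agricultural area,
#' counting the boundary cell pro-rata.
#'
#' @param ranking a [rank_hotspots()] result.
#' @param fraction agricultural-area fraction in `[0, 1]`.
#' @return emission share in `[0, 1]`.
#' @export
top_fraction_share <- function(ranking, fraction) {
  if (fraction < 0 || fraction > 1)
    stop2("invalid_argument", "fraction must be in [0, 1]")
  tot <- sum(ranking$emission_kg)
  if (tot <= 0) return(0)
  prefix_emissions(ranking, fraction) / tot
}

#' Apply nitrification inhibitors along the hotspot ranking
#'
#' Emissions of the adopted prefix (top `adoption_fraction` of agricultural
#' area, boundary cell pro-rata) are scaled by `1 - efficiency`; all other
#' cells are unchanged.  Fertilizer inputs are untouched.  The total falls
#' by exactly `efficiency * prefix_emissions`.
#'
#' @param emission_kg per-cell emissions aligned with `domain$cell_id`.
#' @param ranking a [rank_hotspots()] result for a (possibly different)
#'   reference field.
#' @param adoption_fraction agricultural-area fraction in `[0, 1]`.
#' @param efficiency fractional emission reduction on adopted area
#'   (default 0.34).
#' @param domain the `grid_domain`.
#' @return list with `emission_kg` (reduced per-cell vector aligned with
#'   `domain$cell_id`) and `removed_kg`.
#' @export
apply_ni <- function(emission_kg, ranking, adoption_fraction,
                     efficiency = 0.34, domain) {
  if (adoption_fraction < 0 || adoption_fraction > 1)
    stop2("invalid_argument", "adoption_fraction must be in [0, 1]")
  if (efficiency < 0 || efficiency >= 1)
    stop2("invalid_argument", "efficiency must be in [0, 1)")
  w <- adoption_weights(ranking, adoption_fraction)  # per ranked cell in [0,1]
  out <- emission_kg
  idx <- match(ranking$cell_id, domain$cell_id)
  removed <- efficiency * w * emission_kg[idx]
  out[idx] <- emission_kg[idx] - removed
  list(emission_kg = out, removed_kg = sum(removed))
}

# Fraction of each ranked cell's area adopted at overall area fraction f.
adoption_weights <- function(ranking, fraction) {
  n <- nrow(ranking)
  if (fraction <= 0) return(numeric(n))
  if (fraction >= 1) return(rep(1, n))
  A <- sum(ranking$fert_area_ha)
  target <- fraction * A
  cum_a <- cumsum(ranking$fert_area_ha)
  w <- numeric(n)
  i <- findInterval(target, cum_a) + 1L
  if (i > 1) w[seq_len(i - 1L)] <- 1
  if (i <= n) {
    a_before <- if (i > 1) cum_a[i - 1L] else 0
    w[i] <- (target - a_before) / ranking$fert_area_ha[i]
  }
  w
}

#' Reduction curve along the NI adoption gradient
#'
#' For each adoption fraction `f`, the percent reduction of the post-NI
#' total relative to a 2010 baseline: `100 * (E_2010 - E_NI(f)) / E_2010`.
#' The curve is non-decreasing in `f` and, on a strictly ordered ranking,
#' concave: the steep early gains are the argument for prioritizing
#' hotspots.
#'
#' @param ranking a [rank_hotspots()] result for the current emission field.
#' @param baseline_kg total 2010 emissions (kg N / yr), > 0.
#' @param efficiency NI efficiency (default 0.34).
#' @param fractions grid of adoption fractions.
#' @return `data.table` of class `hotspot_curve` with `fraction`,
#'   `reduction_pct`.
#' @export
ni_reduction_curve <- function(ranking, baseline_kg, efficiency = 0.34,
                               fractions = seq(0, 1, by = 0.01)) {
  if (baseline_kg <= 0) stop2("invalid_argument", "baseline must be > 0")
  E <- sum(ranking$emission_kg)
  red <- vapply(fractions, function(f)
    100 * (baseline_kg - (E - efficiency * prefix_emissions(ranking, f))) /
      baseline_kg, numeric(1))
  out <- data.table(fraction = fractions, reduction_pct = red)
  setattr(out, "efficiency", efficiency)
  setattr(out, "baseline_kg", baseline_kg)
  setattr(out, "class", c("hotspot_curve", class(out)))
  out[]
}

#' Minimal NI adoption fraction to meet a reduction goal
#'
#' Smallest agricultural-area fraction `f` such that the post-NI total is
#' at or below `(1 - goal) * baseline`.  Because the prefix-emission curve
#' is piecewise linear and strictly monotone wherever rates are positive,
#' the crossing is inverted exactly (cell by cell, pro-rata within the
#' boundary cell) rather than by iterative bisection.  For proportional
#' equal-efficiency reductions, the descending-rate prefix removes the most
#' emissions of any cell subset with the same area (continuous-knapsack
#' argument), so this fraction is globally minimal.
#'
#' @param ranking a [rank_hotspots()] result.
#' @param baseline_kg 2010 baseline total, kg N / yr.
#' @param goal reduction goal in (0, 1).
#' @param efficiency NI efficiency (default 0.34).
#' @return smallest fraction in `[0, 1]`, or `NA` if the goal is
#'   unattainable even at full adoption.
#' @export
minimal_adoption_fraction <- function(ranking, baseline_kg, goal,
                                      efficiency = 0.34) {
  if (goal <= 0 || goal >= 1)
    stop2("invalid_argument", "goal must be in (0, 1)")
  E <- sum(ranking$emission_kg)
  need <- (E - (1 - goal) * baseline_kg) / efficiency  # prefix kg required
  if (need <= 0) return(0)
  if (need > E + 1e-9) return(NA_real_)
  cum_e <- cumsum(ranking$emission_kg)
  cum_a <- cumsum(ranking$fert_area_ha)
  A <- sum(ranking$fert_area_ha)
  i <- findInterval(need, cum_e, left.open = FALSE) + 1L
  if (i > nrow(ranking)) return(1)
  e_before <- if (i > 1) cum_e[i - 1L] else 0
  a_before <- if (i > 1) cum_a[i - 1L] else 0
  extra_kg <- need - e_before
  area_i <- if (ranking$emission_kg[i] > 0)
    extra_kg / ranking$emission_kg[i] * ranking$fert_area_ha[i] else 0
  min(1, (a_before + area_i) / A)
}

#' Goal-attainment year as NI adoption expands
#'
#' For each adoption fraction on a grid, recomputes the scenario's annual
#' global series with NI applied from `start_year` onward (adopted cell set
#' fixed by the reference ranking) and returns the first year the annual
#' reduction goal is met.  The year is non-increasing in the adoption
#' fraction.
#'
#' @param projection a `scenario_projection` with cell-level fields kept
#'   for all years (`keep_cell_years` covering the projection window).
#' @param ranking reference [rank_hotspots()] ranking that fixes the
#'   adoption order.
#' @param goal reduction goal in (0, 1).
#' @param fractions adoption-fraction grid.
#' @param efficiency NI efficiency (default 0.34).
#' @param start_year first year NI takes effect (default 2020).
#' @param baseline_year goal baseline year (default 2010).
#' @param domain the `grid_domain`.
#' @return `data.table` with `fraction`, `goal_year` (`NA` when unmet by
#'   the series end).
#' @export
expedited_timeline <- function(projection, ranking, goal,
                               fractions = seq(0, 1, by = 0.02),
                               efficiency = 0.34, start_year = 2020,
                               baseline_year = 2010, domain) {
  ce <- projection$cell_emissions
  if (is.null(ce))
    stop2("invalid_argument", "projection lacks cell-level fields")
  yrs <- as.integer(colnames(ce))
  idx <- match(ranking$cell_id, projection$cell_id)
  gl <- colSums(ce) / 1e9  # Tg, median-member cell fields
  names(gl) <- as.character(yrs)
  out <- lapply(fractions, function(f) {
    w <- adoption_weights(ranking, f)
    removed_tg <- colSums(efficiency * w * ce[idx, , drop = FALSE]) / 1e9
    series <- gl - ifelse(yrs >= start_year, removed_tg, 0)
    data.table(fraction = f,
               goal_year = cumulative_target_year(
                 series, goal, basis = "annual",
                 baseline_year = baseline_year))
  })
  rbindlist(out)
}
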