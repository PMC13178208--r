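# Synthetic world generator: grid domain, soils, climate, baseline
# fertilizer, and the closed-form "true" EF response surface the emulator is
# trained against.  Everything here is a pure function of (config, seed) so
# the downstream pipeline is testable without any external data.

#' Generate a synthetic grid domain
#'
#' Lays `n_cells` cells on a quasi-regular latitude/longitude grid between
#' 55S and 65N, partitions them into `n_countries` spatially contiguous
#' countries (nearest-centre assignment), labels each country with one of the
#' 18 subregions in [N2O_REGIONS], and draws cropland and pasture fractions.
#' A configurable share of cells is non-agricultural (both fractions zero).
#'
#' Cell area is the nominal area of a half-degree cell scaled by
#' `cos(latitude)`; no map projection is attempted because every downstream
#' statistic is an area-weighted sum.
#'
#' @param n_cells number of grid cells (default 2000).
#' @param n_countries number of countries; must not exceed `n_cells`.
#' @param seed integer seed.
#' @param nonag_frac expected fraction of cells with no agricultural land.
#' @return A `data.table` of class `grid_domain` with columns `cell_id`,
#'   `lat`, `lon`, `area_ha`, `country_id`, `region_id`, `cropland_frac`,
#'   `pasture_frac`.
#' @export
generate_domain <- function(n_cells = 2000, n_countries = 18, seed = 1L,
                            nonag_frac = 0.25) {
  if (n_countries > n_cells || n_countries < 1)
    stop2("invalid_argument", "need n_cells >= n_countries >= 1 (got %d, %d)",
          n_cells, n_countries)
  with_seed(seed, {
    nlat <- max(1L, floor(sqrt(n_cells)))
    nlon <- ceiling(n_cells / nlat)
    lat <- if (nlat == 1) 20 else seq(-55, 65, length.out = nlat)
    lon <- if (nlon == 1) 0 else seq(-179.75, 179.75, length.out = nlon)
    grid <- CJ(lat = lat, lon = lon)[seq_len(n_cells)]
    dom <- data.table(cell_id = seq_len(n_cells), lat = grid$lat,
                      lon = grid$lon)
    # nominal 0.5-degree cell: ~3081 km2 at the equator
    dom[, area_ha := 308100 * cos(lat * pi / 180)]

    centres <- dom[sample.int(n_cells, n_countries)]
    d2 <- outer(dom$lat, centres$lat, "-")^2 +
      outer(dom$lon, centres$lon, "-")^2
    dom[, country_id := sprintf("C%02d", max.col(-d2, ties.method = "first"))]
    perm <- sample(N2O_REGIONS)
    reg_map <- data.table(country_id = sprintf("C%02d", seq_len(n_countries)),
                          region_id = perm[((seq_len(n_countries) - 1L) %% 18L) + 1L])
    dom <- reg_map[dom, on = "country_id"]
    setcolorder(dom, c("cell_id", "lat", "lon", "area_ha", "country_id",
                       "region_id"))

    ag <- runif(n_cells) >= nonag_frac
    crop <- ifelse(ag, runif(n_cells, 0.05, 0.60), 0)
    past <- ifelse(ag, runif(n_cells, 0, 1) * pmin(0.35, 1 - crop), 0)
    dom[, `:=`(cropland_frac = crop, pasture_frac = past)]
    setkey(dom, cell_id)
    setattr(dom, "class", c("grid_domain", class(dom)))
    dom[]
  })
}

# Low-frequency random field on (lat, lon): a sum of sinusoidal basis
# functions with random orientation and phase.  Gives smooth, spatially
# autocorrelated fields without needing a covariance solve.
smooth_field <- function(lat, lon, nbasis = 16, freq = 0.035) {
  k <- matrix(rnorm(2 * nbasis, sd = freq), ncol = 2)
  phase <- runif(nbasis, 0, 2 * pi)
  amp <- rnorm(nbasis)
  f <- matrix(0, length(lat), 1)
  for (j in seq_len(nbasis))
    f <- f + amp[j] * sin(2 * pi * (k[j, 1] * lat + k[j, 2] * lon) + phase[j])
  z <- drop(f)
  if (sd(z) > 0) (z - mean(z)) / sd(z) else z
}

#' Generate time-invariant soil properties
#'
#' Draws spatially autocorrelated fields (smooth random basis expansions) for
#' pH, soil organic carbon, bulk density and texture.  Invariants: pH in
#' \[3, 10\], SOC > 0, `sand_frac + clay_frac <= 1`.
#'
#' @param domain a [generate_domain()] result.
#' @param seed integer seed.
#' @return `data.table` with columns `cell_id`, `ph`, `soc` (g C / kg),
#'   `bulk_density` (g / cm3), `sand_frac`, `clay_frac`.
#' @export
generate_soil <- function(domain, seed = 1L) {
  with_seed(seed, {
    la <- domain$lat; lo <- domain$lon
    z1 <- smooth_field(la, lo); z2 <- smooth_field(la, lo)
    z3 <- smooth_field(la, lo); z4 <- smooth_field(la, lo)
    z5 <- smooth_field(la, lo)
    sand_raw <- stats::plogis(z4)
    soil <- data.table(
      cell_id = domain$cell_id,
      ph = 3 + 7 * stats::plogis(1.1 * z1),
      soc = exp(2.6 + 0.55 * z2),
      bulk_density = pmin(1.9, pmax(0.8, 1.35 + 0.15 * z3)),
      sand_frac = 0.8 * sand_raw
    )
    soil[, clay_frac := (1 - sand_frac) * 0.6 * stats::plogis(z5)]
    setkey(soil, cell_id)
    soil[]
  })
}

#' Default warming rates per climate pathway
#'
#' Linear global-mean warming trends (degC per decade) used by the synthetic
#' climate generator: end-of-century warming ordering SSP1-2.6 < SSP2-4.5 <
#' SSP5-8.5 is built in.
#' @export
pathway_warming_rates <- function() {
  c("SSP1-2.6" = 0.10, "SSP2-4.5" = 0.25, "SSP5-8.5" = 0.45, "HIST" = 0.20)
}

#' Generate a synthetic monthly climate ensemble
#'
#' Builds a per-cell monthly climatology (zonal temperature gradient with a
#' seasonal cycle, smooth precipitation field), adds a pathway-specific
#' linear warming trend, and realizes `n_members` pseudo-GCM members, each
#' with a member-specific additive temperature bias (sd `bias_sd`), a
#' multiplicative precipitation bias, and seeded month-to-month noise.  One
#' unbiased OBS series is produced for historical years (`<= hist_end`).
#'
#' With `bias_sd = 0`, `p_bias_sd = 0`, `t_noise_sd = 0`, `p_noise_sd = 0`
#' and `warming_rate = 0` every member reproduces the OBS climatology
#' exactly.
#'
#' @param domain a [generate_domain()] result.
#' @param years integer vector of years.
#' @param pathway one of `"SSP1-2.6"`, `"SSP2-4.5"`, `"SSP5-8.5"`, `"HIST"`.
#' @param n_members ensemble size (ignored for the OBS series).
#' @param warming_rate degC per decade; default from [pathway_warming_rates()].
#' @param bias_sd sd of the member-specific additive temperature bias (degC).
#' @param p_bias_sd sd of the member-specific log precipitation bias.
#' @param t_noise_sd sd of monthly temperature noise (degC).
#' @param p_noise_sd sd of monthly log precipitation noise.
#' @param hist_end last historical year; OBS covers `years <= hist_end`.
#' @param seed integer seed.
#' @return An object of class `climate_ensemble`: list with `obs` (monthly
#'   `data.table` or `NULL`), `members` (list of monthly `data.table`s with
#'   columns `cell_id`, `year`, `month`, `tas`, `pr`), `pathway`, `years`.
#' @export
generate_climate <- function(domain, years, pathway, n_members = 1L,
                             warming_rate = NULL, bias_sd = 0.6,
                             p_bias_sd = 0.10, t_noise_sd = 0.5,
                             p_noise_sd = 0.25, hist_end = 2014, seed = 1L) {
  pathways <- names(pathway_warming_rates())
  if (!pathway %in% pathways)
    stop2("invalid_argument", "unknown pathway '%s'", pathway)
  if (length(years) == 0 || n_members < 1)
    stop2("invalid_argument", "need non-empty years and n_members >= 1")
  warming_rate <- warming_rate %||% unname(pathway_warming_rates()[pathway])

  clim <- with_seed(seed, {
    tbar <- 27 - 0.38 * abs(domain$lat) + 2 * smooth_field(domain$lat, domain$lon)
    amp <- 0.33 * abs(domain$lat) + 1
    pfield <- stats::plogis(smooth_field(domain$lat, domain$lon))
    pbar <- 15 + 220 * pfield                     # mm / month
    list(tbar = tbar, amp = amp, pbar = pbar)
  })

  base <- CJ(cell_id = domain$cell_id, year = as.integer(years),
             month = 1:12)
  hemis <- domain$lat[match(base$cell_id, domain$cell_id)] >= 0
  season <- cos(2 * pi * (base$month - 7) / 12)
  season <- ifelse(hemis, season, -season)
  idx <- match(base$cell_id, domain$cell_id)
  trend <- warming_rate / 10 * (base$year - 2010)
  clim_tas <- clim$tbar[idx] + clim$amp[idx] * season + trend
  pseason <- 1 + 0.3 * season
  clim_pr <- clim$pbar[idx] * pseason

  realize <- function(mseed, tbias, pbias) {
    with_seed(mseed, {
      tas <- clim_tas + tbias +
        (if (t_noise_sd > 0) rnorm(nrow(base), sd = t_noise_sd) else 0)
      pr <- clim_pr * pbias *
        (if (p_noise_sd > 0) exp(rnorm(nrow(base), sd = p_noise_sd) -
                                   p_noise_sd^2 / 2) else 1)
      dt <- data.table(cell_id = base$cell_id, year = base$year,
                       month = base$month, tas = tas, pr = pmax(pr, 0))
      setkey(dt, cell_id, year, month)
      dt[]
    })
  }

  hist_years <- years[years <= hist_end]
  obs <- NULL
  if (length(hist_years)) {
    keep <- base$year <= hist_end
    obs <- with_seed(child_seed(seed, 0L), {
      tas <- clim_tas[keep] +
        (if (t_noise_sd > 0) rnorm(sum(keep), sd = t_noise_sd) else 0)
      pr <- clim_pr[keep] *
        (if (p_noise_sd > 0) exp(rnorm(sum(keep), sd = p_noise_sd) -
                                   p_noise_sd^2 / 2) else 1)
      dt <- data.table(cell_id = base$cell_id[keep], year = base$year[keep],
                       month = base$month[keep], tas = tas, pr = pmax(pr, 0))
      setkey(dt, cell_id, year, month)
      dt[]
    })
    setattr(obs, "member_id", "OBS")
    setattr(obs, "pathway", if (pathway == "HIST") "HIST" else pathway)
  }

  biases <- with_seed(child_seed(seed, 1L), list(
    t = if (bias_sd > 0) rnorm(n_members, sd = bias_sd) else rep(0, n_members),
    p = if (p_bias_sd > 0) exp(rnorm(n_members, sd = p_bias_sd)) else
      rep(1, n_members)))
  members <- lapply(seq_len(n_members), function(m) {
    dt <- realize(child_seed(seed, m + 1L), biases$t[m], biases$p[m])
    setattr(dt, "member_id", m)
    setattr(dt, "pathway", pathway)
    dt
  })

  structure(list(obs = obs, members = members, pathway = pathway,
                 years = as.integer(years), hist_end = hist_end,
                 warming_rate = warming_rate),
            class = "climate_ensemble")
}

#' @export
print.climate_ensemble <- function(x, ...) {
  cat(sprintf("<climate_ensemble> pathway=%s members=%d years=%d-%d obs=%s\n",
              x$pathway, length(x$members), min(x$years), max(x$years),
              if (is.null(x$obs)) "none" else "yes"))
  invisible(x)
}

#' Parameters of the true EF response surface
#'
#' Closed-form response of the N2O emission factor (percent of applied
#' fertilizer N) used as ground truth by the synthetic world: a calibrated
#' scale times a logistic-saturating (increasing) factor in N application
#' rate, an exponential (increasing) factor in temperature anomaly above
#' `t_ref`, a unimodal factor in aridity index, and mild SOC and pH
#' modifiers.  All factors are positive, so EF >= 0 and monotonicity in
#' `n_rate` and temperature hold everywhere by construction.
#'
#' `constant` overrides the whole surface with a fixed EF (used for the
#' static-limit equivalence check).
#'
#' @param scale overall multiplier, calibrated by [generate_true_ef_surface()].
#' @param n_half,n_slope,n_low,n_range logistic N-rate response: factor runs
#'   from `n_low` to `n_low + n_range` with midpoint `n_half` kg N/ha and
#'   width `n_slope`.
#' @param t_ref,gamma_t temperature response `exp(gamma_t * (tas - t_ref))`.
#' @param a_opt,a_width,a_floor aridity response: Gaussian bump at `a_opt`
#'   over a floor `a_floor`.
#' @param soc_ref,soc_scale,soc_amp SOC modifier `1 + soc_amp *
#'   tanh((soc - soc_ref)/soc_scale)`.
#' @param ph_opt,ph_width,ph_amp pH modifier `1 - ph_amp *
#'   ((ph - ph_opt)/ph_width)^2`.
#' @param noise_sd sd (EF percentage points) of the label noise added by
#'   [emit_training_table()].
#' @param constant optional fixed EF percent overriding everything.
#' @return list of class `ef_surface_params`.
#' @export
ef_surface_params <- function(scale = 1, n_half = 120, n_slope = 60,
                              n_low = 0.6, n_range = 0.8, t_ref = 12,
                              gamma_t = 0.04, a_opt = 0.8, a_width = 0.6,
                              a_floor = 0.4, soc_ref = 15, soc_scale = 10,
                              soc_amp = 0.10, ph_opt = 6.5, ph_width = 2,
                              ph_amp = 0.05, noise_sd = 0.3,
                              constant = NULL) {
  structure(as.list(environment()), class = "ef_surface_params")
}

#' Evaluate the true EF surface
#'
#' @param surface an `ef_surface` (calibrated) or `ef_surface_params` object.
#' @param n_rate kg N / ha / yr applied to the fertilized fraction.
#' @param tas annual mean temperature, degC.
#' @param aridity_index dimensionless annual P/PET.
#' @param soc g C / kg.
#' @param ph soil pH.
#' @return EF in percent, same length as the inputs.
#' @export
ef_true <- function(surface, n_rate, tas, aridity_index, soc, ph) {
  p <- surface
  if (!is.null(p$constant)) return(rep(p$constant, length(n_rate)))
  fn <- p$n_low + p$n_range * stats::plogis((n_rate - p$n_half) / p$n_slope)
  ft <- exp(p$gamma_t * (tas - p$t_ref))
  fa <- p$a_floor + (1 - p$a_floor) *
    exp(-((aridity_index - p$a_opt)^2) / (2 * p$a_width^2))
  fsoc <- 1 + p$soc_amp * tanh((soc - p$soc_ref) / p$soc_scale)
  fph <- pmax(0, 1 - p$ph_amp * ((ph - p$ph_opt) / p$ph_width)^2)
  p$scale * fn * ft * fa * fsoc * fph
}

#' Calibrate the true EF surface to a 2010 mean-EF window
#'
#' Rescales the surface so that the fertilized-area-weighted mean EF over
#' the synthetic world in `calibration_year` falls in `target_window`
#' (default 1.18-1.22 percent, i.e. above the IPCC Tier-1 1 percent).  The
#' mean is linear in the scale parameter, so calibration converges in one
#' step; a bounded iteration guards against degenerate inputs and raises a
#' `calibration_error` if the window cannot be reached.
#'
#' When `params$constant` is set the surface is a fixed EF and calibration
#' is a no-op (the constant is returned as-is).
#'
#' @param domain,soil,fertilizer synthetic world components.
#' @param climate_obs monthly OBS climate `data.table` covering
#'   `calibration_year`.
#' @param params an [ef_surface_params()] object.
#' @param target_window length-2 numeric, percent.
#' @param calibration_year year whose features anchor the calibration.
#' @param max_iter safety bound on recalibration steps.
#' @return object of class `ef_surface` (the params with `scale` set and a
#'   `calibrated_mean` attribute).
#' @export
generate_true_ef_surface <- function(domain, soil, climate_obs, fertilizer,
                                     params = ef_surface_params(),
                                     target_window = c(1.18, 1.22),
                                     calibration_year = 2010,
                                     max_iter = 5) {
  if (!is.null(params$constant)) {
    out <- params
    class(out) <- c("ef_surface", "ef_surface_params")
    attr(out, "calibrated_mean") <- params$constant
    return(out)
  }
  feat <- annual_features(climate_obs[year == calibration_year])
  tab <- assemble_features(feat, soil, fertilizer)
  tab <- tab[n_rate > 0]
  if (nrow(tab) == 0)
    stop2("calibration_error", "no fertilized cells to calibrate against")
  w <- fertilized_area(domain)[tab, on = "cell_id"]$fert_area_ha
  target <- mean(target_window)
  for (it in seq_len(max_iter)) {
    ef <- ef_true(params, tab$n_rate, tab$tas, tab$aridity_index, tab$soc,
                  tab$ph)
    m <- sum(w * ef) / sum(w)
    if (!is.finite(m) || m <= 0)
      stop2("calibration_error", "degenerate surface mean %s", format(m))
    if (m >= target_window[1] && m <= target_window[2]) break
    params$scale <- params$scale * target / m
  }
  ef <- ef_true(params, tab$n_rate, tab$tas, tab$aridity_index, tab$soc,
                tab$ph)
  m <- sum(w * ef) / sum(w)
  if (m < target_window[1] || m > target_window[2])
    stop2("calibration_error",
          "calibration failed: mean EF %.4f outside [%.2f, %.2f]",
          m, target_window[1], target_window[2])
  class(params) <- c("ef_surface", "ef_surface_params")
  attr(params, "calibrated_mean") <- m
  params
}

# Agricultural (fertilized) area per cell, hectares.
fertilized_area <- function(domain) {
  data.table(cell_id = domain$cell_id,
             fert_area_ha = domain$area_ha *
               (domain$cropland_frac + domain$pasture_frac),
             key = "cell_id")
}

#' Generate the baseline (2010) fertilizer field
#'
#' Log-normal application rates across agricultural cells with mean
#' `mean_rate` and log-sd `skew`; `skew = 0` gives a uniform rate.  The
#' right skew concentrates nitrogen in a minority of cells, producing the
#' emission hotspots the mitigation analysis targets.  Non-agricultural
#' cells get rate zero.
#'
#' @param domain a [generate_domain()] result.
#' @param mean_rate mean rate over agricultural cells, kg N / ha / yr.
#' @param skew log-sd of the rate distribution.
#' @param seed integer seed.
#' @return `data.table` with `cell_id`, `n_rate_2010` (kg N / ha / yr on the
#'   fertilized fraction).
#' @export
generate_baseline_fertilizer <- function(domain, mean_rate = 80, skew = 1,
                                         seed = 1L) {
  if (mean_rate <= 0) stop2("invalid_argument", "mean_rate must be > 0")
  with_seed(seed, {
    ag <- (domain$cropland_frac + domain$pasture_frac) > 0
    rate <- numeric(nrow(domain))
    if (any(ag)) {
      z <- rnorm(sum(ag))
      rate[ag] <- mean_rate * exp(skew * z - skew^2 / 2)
    }
    data.table(cell_id = domain$cell_id, n_rate_2010 = rate,
               key = "cell_id")[]
  })
}

#' Build the EF training table
#'
#' One record per fertilized cell-year over the historical OBS climate:
#' the full feature schema (see [ef_feature_names]) plus the label `ef`,
#' which is the true surface evaluated at the features plus Gaussian noise
#' of sd `surface$noise_sd`.  Cells with zero fertilizer are excluded.
#'
#' @param surface calibrated `ef_surface`.
#' @param climate_obs monthly OBS climate table.
#' @param soil,fertilizer,domain world components.
#' @param years which years to include (default: all years in `climate_obs`).
#' @param seed seed for the label noise.
#' @return `data.table` with `cell_id`, `year`, the feature columns, and
#'   `ef` (percent).
#' @export
emit_training_table <- function(surface, climate_obs, soil, fertilizer,
                                domain, years = NULL, seed = 1L) {
  years <- years %||% sort(unique(climate_obs$year))
  feat <- annual_features(climate_obs[year %in% years])
  tab <- assemble_features(feat, soil, fertilizer)
  tab <- tab[n_rate > 0]
  if (nrow(tab) == 0)
    stop2("empty_table", "no fertilized cell-years in the requested window")
  truth <- ef_true(surface, tab$n_rate, tab$tas, tab$aridity_index, tab$soc,
                   tab$ph)
  noise_sd <- surface$noise_sd %||% 0
  tab[, ef := truth + if (noise_sd > 0)
    with_seed(seed, rnorm(.N, sd = noise_sd)) else 0]
  tab[]
}

#' Assemble the default synthetic world
#'
#' Convenience constructor mirroring the package's stated default world:
#' 2000 cells, 18 countries (one per subregion), historical years
#' 1990-2014 of OBS climate, a skewed baseline fertilizer field, and a true
#' EF surface calibrated so the fertilized-area-weighted 2010 mean EF lies
#' in 1.18-1.22 percent.
#'
#' @param n_cells,n_countries domain size.
#' @param hist_years historical years for the OBS climate.
#' @param seed master seed; all components derive sub-seeds from it.
#' @param surface_params optional [ef_surface_params()] override.
#' @param mean_rate,skew baseline fertilizer configuration.
#' @return list of class `synthetic_world` with elements `domain`, `soil`,
#'   `climate_obs`, `fertilizer`, `surface`.
#' @export
synthetic_world <- function(n_cells = 2000, n_countries = 18,
                            hist_years = 1990:2014, seed = 1L,
                            surface_params = ef_surface_params(),
                            mean_rate = 80, skew = 1) {
  domain <- generate_domain(n_cells, n_countries, seed = child_seed(seed, 11L))
  soil <- generate_soil(domain, seed = child_seed(seed, 12L))
  clim <- generate_climate(domain, years = hist_years, pathway = "HIST",
                           n_members = 1L, seed = child_seed(seed, 13L))
  fert <- generate_baseline_fertilizer(domain, mean_rate = mean_rate,
                                       skew = skew,
                                       seed = child_seed(seed, 14L))
  surface <- generate_true_ef_surface(
    domain, soil, clim$obs, fert, params = surface_params,
    calibration_year = if (2010 %in% hist_years) 2010 else min(hist_years))
  structure(list(domain = domain, soil = soil, climate_obs = clim$obs,
                 fertilizer = fert, surface = surface, seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d cells, %d countries, 2010 mean EF %.3f%%\n",
    nrow(x$domain), length(unique(x$domain$country_id)),
    attr(x$surface, "calibrated_mean")))
  invisible(x)
}
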