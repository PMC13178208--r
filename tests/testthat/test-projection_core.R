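test_that("ensemble summary follows the linear-interpolation percentile convention", {
  m <- matrix(c(1, 2, 3, 4), nrow = 1, dimnames = list("2020", NULL))
  s <- ensemble_summary(m)
  expect_equal(s$median, 2.5)
  expect_equal(s$p25, 1.75)
  expect_equal(s$p75, 3.25)

  same <- matrix(7, nrow = 3, ncol = 5,
                 dimnames = list(2020:2022, NULL))
  ss <- ensemble_summary(same)
  expect_equal(ss$p25, ss$median)
  expect_equal(ss$median, ss$p75)

  # naive sort-based percentile oracle on 37 random members
  set.seed(10)
  m37 <- matrix(rnorm(5 * 37), 5, 37, dimnames = list(2010:2014, NULL))
  naive_pct <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  s37 <- ensemble_summary(m37)
  expect_equal(s37$median, unname(apply(m37, 1, naive_pct, 0.5)))
  expect_equal(s37$p25, unname(apply(m37, 1, naive_pct, 0.25)))
  expect_equal(s37$p75, unname(apply(m37, 1, naive_pct, 0.75)))
  expect_true(all(s37$p25 <= s37$median & s37$median <= s37$p75))
  expect_error(ensemble_summary(matrix(numeric(0), 0, 0)),
               class = "invalid_argument")
})

test_that("relative change reproduces the printed reduction arithmetic", {
  s <- c("2010" = 1.46, "2030" = 1.46)
  expect_equal(unname(relative_change(s)["2030"]), 0)

  s2 <- c("2010" = 1.46, "2030" = 0.64, "2050" = 0.81)
  rc <- relative_change(s2)
  expect_equal(round(unname(rc["2030"])), -56)
  expect_equal(round(unname(rc["2050"])), -45)

  expect_error(relative_change(c("2010" = 0, "2030" = 1)),
               class = "undefined_baseline")
})

test_that("goal-attainment years: annual and cumulative bases", {
  years <- 2010:2050
  flat <- setNames(rep(2, length(years)), years)
  expect_true(is.na(cumulative_target_year(flat, 0.25)))
  expect_true(is.na(cumulative_target_year(flat, 0.45, "cumulative")))

  step <- setNames(c(rep(2, 10), rep(1, 31)), years)  # halves in 2020
  expect_equal(cumulative_target_year(step, 0.25, "annual"), 2020)

  # brute-force scan oracle on a linear decline
  lin <- setNames(seq(2, 0.1, length.out = length(years)), years)
  oracle <- function(v, goal, basis) {
    base <- v["2010"]
    for (t in years[-1]) {
      ok <- if (basis == "annual") v[as.character(t)] <= (1 - goal) * base
      else sum(v[as.character(2011:t)]) <= (1 - goal) * (t - 2010) * base
      if (ok) return(t)
    }
    NA_integer_
  }
  for (goal in c(0.25, 0.45)) {
    ya <- cumulative_target_year(lin, goal, "annual")
    yc <- cumulative_target_year(lin, goal, "cumulative")
    expect_equal(ya, oracle(lin, goal, "annual"))
    expect_equal(yc, oracle(lin, goal, "cumulative"))
    expect_gte(yc, ya)  # cumulative attainment lags annual attainment
  }
  expect_error(cumulative_target_year(lin, 1.2), class = "invalid_argument")
})

test_that("regional totals aggregate and normalize", {
  d <- toy_domain(4)
  expect_equal(regional_totals(c(1, 2, 3, 4) * 1e9, d)$share, 1)

  d2 <- data.table::copy(d)
  d2[3:4, region_id := "CHN"]
  rt <- regional_totals(c(1, 1, 1, 1) * 1e9, d2)
  expect_equal(rt$share, c(0.5, 0.5))
  expect_equal(sum(rt$emission_tg), 4)

  w <- test_world()
  set.seed(3)
  rt18 <- regional_totals(runif(nrow(w$domain)) * 1e6, w$domain)
  expect_equal(sum(rt18$share), 1)
  d_na <- data.table::copy(d)[1, region_id := NA_character_]
  expect_error(regional_totals(1:4, d_na), class = "domain_error")
})

test_that("mitigation potential converts Tg N to percent and CO2e", {
  bau <- c("2050" = 3.07)
  amb <- c("2050" = 0.93)
  mp <- mitigation_potential(bau, amb, 2050)
  expect_equal(mp$delta_tg, 2.14)
  expect_equal(round(mp$percent), 70)

  mp2 <- mitigation_potential(c("2050" = 2.5), c("2050" = 0), 2050,
                              gwp100 = 265)
  expect_equal(mp2$pg_co2e, 2.5 * (44 / 28) * 265 / 1000)
  expect_equal(round(mp2$pg_co2e, 2), 1.04)

  mp0 <- mitigation_potential(bau, bau, 2050, cropland_area_ha = 1e9)
  expect_equal(mp0$delta_tg, 0)
  expect_equal(mp0$pg_co2e, 0)
  expect_equal(mp0$mg_co2e_per_ha, 0)
})

test_that("static-dynamic gap matches its defining arithmetic", {
  g <- static_dynamic_gap(c("2010" = 1.41), c("2010" = 1.04))
  expect_equal(round(g$gap_pct), 26)
  g0 <- static_dynamic_gap(c("2010" = 2, "2011" = 3),
                           c("2010" = 2, "2011" = 3))
  expect_equal(g0$gap_tg, c(0, 0))
  expect_equal(g0$gap_pct, c(0, 0))
})

test_that("project_scenario: flat inputs give flat series and exact static identity", {
  w <- test_world()
  em <- test_emulator()
  years <- 2010:2020
  ens <- generate_climate(w$domain, years, "SSP2-4.5", n_members = 1,
                          warming_rate = 0, bias_sd = 0, p_bias_sd = 0,
                          t_noise_sd = 0, p_noise_sd = 0, hist_end = 2009,
                          seed = 4)
  ct <- country_fertilizer_trajectories("INMS3", w$fertilizer, w$domain,
                                        years = years)
  ct[, fertilizer_kg := fertilizer_kg[year == 2010], by = country_id]
  fert <- scale_gridded_fertilizer(w$fertilizer, ct, w$domain)
  pr <- project_scenario("INMS3", em, ens, fert, w$domain, w$soil,
                         keep_cell_years = 2010)
  expect_equal(diff(range(pr$member_tg)), 0, tolerance = 1e-12)

  fa <- w$domain$area_ha * (w$domain$cropland_frac + w$domain$pasture_frac)
  expect_equal(unname(pr$static_tg["2010"]),
               0.01 * sum(w$fertilizer$n_rate_2010 * fa) / 1e9)

  expect_error(project_scenario("INMS1", em, ens, fert, w$domain, w$soil),
               class = "config_error")
})

test_that("projection median equals a naive per-year median over members", {
  w <- test_world()
  em <- test_emulator()
  years <- 2010:2014
  ens <- generate_climate(w$domain, years, "SSP2-4.5", n_members = 5,
                          hist_end = 2009, seed = 12)
  fert <- build_scenario_fertilizer("INMS3", w$fertilizer, w$domain,
                                    years = years)
  pr <- project_scenario("INMS3", em, ens, fert, w$domain, w$soil)
  s <- ensemble_summary(pr)
  naive_median <- apply(pr$member_tg, 1, function(x) {
    x <- sort(x)
    x[3]  # odd count: middle element
  })
  expect_equal(s$median, unname(naive_median))

  # additivity: global equals the sum of regional series (kept cell year)
  rt <- regional_totals(pr$cell_emissions[, "2010"], w$domain)
  expect_equal(sum(rt$emission_tg), sum(pr$cell_emissions[, "2010"]) / 1e9)
})
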