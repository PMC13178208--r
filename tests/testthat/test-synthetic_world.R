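test_that("generate_domain partitions cells into labelled countries", {
  d1 <- generate_domain(n_cells = 1, n_countries = 1, seed = 0)
  expect_equal(nrow(d1), 1)
  expect_equal(length(unique(d1$country_id)), 1)

  d <- generate_domain(n_cells = 200, n_countries = 10, seed = 7)
  expect_equal(sum(table(d$country_id)), 200)
  expect_equal(length(unique(d$country_id)), 10)
  # one region per country
  expect_true(all(d[, data.table::uniqueN(region_id),
                    by = country_id]$V1 == 1))
  expect_true(all(d$area_ha > 0))
  expect_true(all(d$cropland_frac + d$pasture_frac >= 0 &
                    d$cropland_frac + d$pasture_frac <= 1))
  expect_true(all(d$region_id %in% N2O_REGIONS))

  expect_identical(d, generate_domain(n_cells = 200, n_countries = 10,
                                      seed = 7))
  expect_error(generate_domain(5, 6), class = "invalid_argument")
})

test_that("generate_soil honours invariants and is spatially autocorrelated", {
  d <- generate_domain(n_cells = 2000, seed = 11)
  s <- generate_soil(d, seed = 4)
  expect_true(all(s$ph >= 3 & s$ph <= 10))
  expect_true(all(s$soc > 0))
  expect_true(all(s$sand_frac + s$clay_frac <= 1))
  expect_identical(s, generate_soil(d, seed = 4))

  # neighbour correlation of SOC: pair each cell with its nearest neighbour
  nn <- vapply(seq_len(nrow(d)), function(i) {
    d2 <- (d$lat - d$lat[i])^2 + (d$lon - d$lon[i])^2
    d2[i] <- Inf
    which.min(d2)
  }, integer(1))
  expect_gt(cor(s$soc, s$soc[nn]), 0)
})

test_that("generate_climate: null generator reproduces the climatology", {
  d <- generate_domain(80, seed = 2)
  ens <- generate_climate(d, years = 2000:2020, pathway = "SSP2-4.5",
                          n_members = 2, warming_rate = 0, bias_sd = 0,
                          p_bias_sd = 0, t_noise_sd = 0, p_noise_sd = 0,
                          seed = 9)
  ob <- ens$obs
  for (m in ens$members) {
    common <- m[year <= 2014]
    expect_equal(common$tas, ob$tas)
    expect_equal(common$pr, ob$pr)
  }
})

test_that("generate_climate warming trends separate pathways as configured", {
  d <- generate_domain(150, seed = 2)
  diff_2050_2010 <- function(rate) {
    ens <- generate_climate(d, years = c(2010, 2050), pathway = "SSP2-4.5",
                            n_members = 6, warming_rate = rate, seed = 31)
    means <- sapply(ens$members, function(m)
      m[, mean(tas), by = year]$V1)
    rowMeans(means)[2] - rowMeans(means)[1]
  }
  # trends 0.3 vs 0.1 degC/decade over 40 years differ by 0.8 degC
  expect_equal(diff_2050_2010(0.3) - diff_2050_2010(0.1), 0.8,
               tolerance = 0.05)

  ens <- generate_climate(d, 2000:2010, "SSP1-2.6", n_members = 2, seed = 5)
  expect_identical(ens$members[[1]],
                   generate_climate(d, 2000:2010, "SSP1-2.6", n_members = 2,
                                    seed = 5)$members[[1]])
  expect_error(generate_climate(d, 2000:2010, "RCP8.5"),
               class = "invalid_argument")
})

test_that("pathway ordering of end-of-window warming holds for ensemble means", {
  d <- generate_domain(100, seed = 6)
  m2050 <- sapply(c("SSP1-2.6", "SSP2-4.5", "SSP5-8.5"), function(p) {
    ens <- generate_climate(d, years = 2050, pathway = p, n_members = 8,
                            seed = 21)
    mean(sapply(ens$members, function(m) mean(m$tas)))
  })
  expect_true(m2050[1] < m2050[2] && m2050[2] < m2050[3])
})

test_that("true EF surface calibrates to the 2010 window and is monotone", {
  w <- test_world()
  m <- attr(w$surface, "calibrated_mean")
  expect_gte(m, 1.18)
  expect_lte(m, 1.22)

  # constant surface: mean is exactly the constant, no calibration applied
  wc <- synthetic_world(n_cells = 100, hist_years = 2008:2014, seed = 1,
                        surface_params = ef_surface_params(constant = 1))
  expect_equal(attr(wc$surface, "calibrated_mean"), 1)
  expect_equal(ef_true(wc$surface, 50, 20, 1, 15, 6.5), 1)

  # finite-difference monotonicity at random points
  set.seed(42)
  n <- 1000
  pts <- data.frame(n_rate = runif(n, 0, 400), tas = runif(n, -5, 35),
                    ai = runif(n, 0, 3), soc = runif(n, 2, 60),
                    ph = runif(n, 3, 10))
  f0 <- ef_true(w$surface, pts$n_rate, pts$tas, pts$ai, pts$soc, pts$ph)
  fn <- ef_true(w$surface, pts$n_rate + 5, pts$tas, pts$ai, pts$soc, pts$ph)
  ft <- ef_true(w$surface, pts$n_rate, pts$tas + 0.5, pts$ai, pts$soc,
                pts$ph)
  expect_true(all(fn >= f0))
  expect_true(all(ft >= f0))
  expect_true(all(f0 >= 0))
})

test_that("baseline fertilizer skew concentrates N in the top decile", {
  d <- generate_domain(1200, seed = 8)
  top_share <- function(skew) {
    f <- generate_baseline_fertilizer(d, mean_rate = 80, skew = skew,
                                      seed = 13)
    r <- sort(f[n_rate_2010 > 0]$n_rate_2010, decreasing = TRUE)
    k <- floor(0.1 * length(r))
    sum(r[seq_len(k)]) / sum(r)
  }
  expect_equal(top_share(0), 0.1, tolerance = 0.01)  # uniform rates
  expect_gt(top_share(1), 0.30)

  d0 <- data.table::copy(d)[, `:=`(cropland_frac = 0, pasture_frac = 0)]
  f0 <- generate_baseline_fertilizer(d0, seed = 1)
  expect_true(all(f0$n_rate_2010 == 0))
  expect_error(generate_baseline_fertilizer(d, mean_rate = -1),
               class = "invalid_argument")
})

test_that("emit_training_table matches truth with zero noise and counts records", {
  w <- test_world()
  surf0 <- w$surface
  surf0$noise_sd <- 0
  tt0 <- emit_training_table(surf0, w$climate_obs, w$soil, w$fertilizer,
                             w$domain, seed = 1)
  truth <- ef_true(surf0, tt0$n_rate, tt0$tas, tt0$aridity_index, tt0$soc,
                   tt0$ph)
  expect_equal(tt0$ef, truth)

  n_fert <- sum(w$fertilizer$n_rate_2010 > 0)
  n_years <- length(unique(w$climate_obs$year))
  expect_equal(nrow(tt0), n_fert * n_years)
  expect_true(all(tt0$n_rate > 0))
  expect_named(tt0, c("cell_id", "year", ef_feature_names(), "ef"),
               ignore.order = TRUE)

  tt_a <- emit_training_table(w$surface, w$climate_obs, w$soil,
                              w$fertilizer, w$domain, seed = 7)
  tt_b <- emit_training_table(w$surface, w$climate_obs, w$soil,
                              w$fertilizer, w$domain, seed = 7)
  expect_identical(tt_a, tt_b)

  empty_fert <- data.table::copy(w$fertilizer)[, n_rate_2010 := 0]
  expect_error(
    emit_training_table(w$surface, w$climate_obs, w$soil, empty_fert,
                        w$domain),
    class = "empty_table")
})
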