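# Shared fixtures, built once per test run and memoised.  Sizes are chosen
# so the whole suite stays fast; the acceptance tests build their own
# larger worlds where a criterion demands it.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

test_world <- function() memo("world", {
  synthetic_world(n_cells = 400, n_countries = 18, hist_years = 2003:2014,
                  seed = 3)
})

test_training <- function() memo("training", {
  w <- test_world()
  emit_training_table(w$surface, w$climate_obs, w$soil, w$fertilizer,
                      w$domain, seed = 2)
})

test_emulator <- function() memo("emulator", {
  train_emulator(test_training(), seed = 5)
})

# A tiny hand-specified domain: n cells, one country, equal unit areas,
# fully cropland.  Useful for exact arithmetic on ranking and NI logic.
toy_domain <- function(n, area_ha = 1, cropland = 1) {
  dt <- data.table::data.table(
    cell_id = seq_len(n), lat = 0, lon = seq_len(n), area_ha = area_ha,
    country_id = "C01", region_id = "EU",
    cropland_frac = cropland, pasture_frac = 0)
  data.table::setkey(dt, cell_id)
  dt
}

# Monthly climate table with constant temperature/precipitation.
flat_monthly <- function(cells, years, tas = 15, pr = 80) {
  dt <- data.table::CJ(cell_id = cells, year = as.integer(years),
                       month = 1:12)
  dt[, `:=`(tas = ..tas, pr = ..pr)]
  data.table::setkey(dt, cell_id, year, month)
  dt[]
}
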