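#' @import data.table
#' @importFrom stats rnorm runif rlnorm quantile median sd predict
#'   complete.cases setNames
#' @importFrom utils write.csv head tail
NULL

# The 18 agricultural subregions used for country labelling and regional
# aggregation throughout the package.
#' Region labels
#'
#' The 18 agricultural subregion codes used to label synthetic countries and
#' to aggregate emissions: Brazil, Central America, Canada, Central Asia,
#' China, Equatorial Africa, Europe, Korea+Japan, Mideast, Northern Africa,
#' Northern South America, Oceania, Russia, Southern Africa, South Asia,
#' Southeast Asia, Southwest South America, USA.
#'
#' @format Character vector of length 18.
#' @export
N2O_REGIONS <- c("BRA", "CAM", "CAN", "CAS", "CHN", "EQAF", "EU", "KAJ",
                 "MIDE", "NAF", "NSA", "OCE", "RUS", "SAF", "SAS", "SEAS",
                 "SSA", "USA")

# Ordered feature schema shared by the training table, the annual feature
# assembler and the emulator.  Any mismatch is a hard error, so the schema
# lives in exactly one place.
ef_feature_names <- function() {
  c("n_rate", "tas", "pr", "aridity_index", "soc", "ph",
    "bulk_density", "sand_frac", "clay_frac")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  All generators funnel randomness through
# this so they are pure functions of (config, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a reproducible child seed (kept below 2^31) for sub-streams such as
# per-member climate noise.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(class = c(code, "n2odyn_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}
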