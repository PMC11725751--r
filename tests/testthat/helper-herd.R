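# Shared fixtures. The calibrated 20,000-pig herd and its fitted model are
# expensive, so they are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Calibrated default herd at the scale used for the headline error bound.
calibrated_herd <- function() {
  cached("herd", function() {
    generate_herd(default_herd_config(n_pigs = 20000L, seed = 0))
  })
}

calibrated_model <- function() {
  cached("model", function() {
    fit_pig_clusters(calibrated_herd(), n_init = 50, seed = 0)
  })
}

# Herd with Korean grades and cluster/group columns attached.
calibrated_pigs <- function() {
  cached("pigs", function() {
    assign_pigs(grade_pigs(calibrated_herd()), calibrated_model())
  })
}

# Small deterministic pig table for unit tests (no simulation involved).
tiny_pigs <- function() {
  data.frame(
    pig_id = paste0("p", 1:6),
    farm_id = c("f1", "f1", "f1", "f2", "f2", "f3"),
    carcass_weight_kg = c(86, 88, 84, 95, 105, 79),
    backfat_mm = c(22, 21, 23, 26, 30, 14))
}

# Independent nearest-centroid search used as an assignment oracle.
brute_nearest <- function(point, centroids) {
  d2 <- colSums((t(centroids) - point)^2)
  which(d2 == min(d2))[1]
}
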