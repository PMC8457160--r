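# Shared fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the default synthetic forest: 1 site, 4 trees, 1 year, noise sd 0.2
default_forest <- function() {
  cached("default_forest", generate_forest(synthetic_config(seed = 1)))
}

default_analysis <- function() {
  cached("default_analysis", analyze_forest(default_forest()))
}

# two species at one site: an early fast grower and a slow-rehydrating,
# slower-growing one (diel window 4 h later)
two_species_forest <- function() {
  cached("two_species_forest", generate_forest(synthetic_config(
    seed = 7,
    species = list(species_spec("EARLY", growth_rate = 2, diel_offset = 0),
                   species_spec("LATE", growth_rate = 1, diel_offset = 4)))))
}

two_site_analysis <- function() {
  cached("two_site_analysis",
         analyze_forest(generate_forest(synthetic_config(seed = 11, n_sites = 2))))
}

hour_seq <- function(n, start = "2020-06-01 00:00:00") {
  seq(as.POSIXct(start, tz = "UTC"), by = 3600, length.out = n)
}

# hourly radius series from a vector of displacements
hourly_series <- function(values, id = "T1", start = "2020-06-01 00:00:00") {
  radius_series(id, hour_seq(length(values), start), values)
}

# independent brute-force prefix-maximum oracle
oracle_partition <- function(r) {
  run_max <- vapply(seq_along(r), function(t) max(r[seq_len(t)]), numeric(1))
  list(run_max = run_max,
       gro_inc = c(0, diff(run_max)),
       twd = run_max - r)
}
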