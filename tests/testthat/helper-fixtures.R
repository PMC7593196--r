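# Shared fixture builders. Everything is generated in code; no data files.

# small, fast simulation configuration
tiny_config <- function(seed = 42, ...) {
  sim_config(n_species = 3, n_sites = 8, individuals_per_site = 15,
             grid_step = 5, seed = seed, ...)
}

# site table with prescribed SST values (bypasses simulate_environment)
sites_with_sst <- function(sst, npp = 500) {
  n <- length(sst)
  data.frame(
    site_id = sprintf("site_%03d", seq_len(n)),
    latitude = seq(-30, 30, length.out = n),
    longitude = seq(-150, 150, length.out = n),
    sst = sst,
    npp = rep_len(npp, n),
    stringsAsFactors = FALSE
  )
}

# populations table for model selection with known generating model
make_populations <- function(n, beta = c(12, 0.05, 0, 0), noise_sd = 0.15,
                             seed = 1) {
  set.seed(seed)
  sst <- runif(n, 10, 30)
  npp <- 500 + 150 * rnorm(n)
  abundance <- runif(n, 0, 0.8)
  data.frame(
    log_p95 = beta[1] + beta[2] * sst + beta[3] * sst^2 + beta[4] * npp +
      rnorm(n, 0, noise_sd),
    sst = sst, npp = npp, abundance = abundance
  )
}

# independent sort-and-interpolate reference for the type-7 p-quantile
quantile_reference <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# independent spherical great-circle distance (haversine), km
haversine_km <- function(lat1, lon1, lat2, lon2, r = 6371) {
  p <- pi / 180
  a <- sin((lat2 - lat1) * p / 2)^2 +
    cos(lat1 * p) * cos(lat2 * p) * sin((lon2 - lon1) * p / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}
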