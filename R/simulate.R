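#' Simulation configuration
#'
#' Builds and validates the configuration object for the synthetic-data
#' generator. The generator emulates the statistical structure the
#' size-environment analysis assumes: sites scattered over the tropical
#' and subtropical ocean, sea-surface temperature (SST) decreasing
#' smoothly away from the equator, net primary productivity (NPP)
#' correlated with SST (Pearson correlation \code{target_sst_npp_corr},
#' default 0.4), species with Gaussian thermal niches generating
#' relative abundances, lognormal individual shell areas whose
#' population 95th percentile responds linearly/quadratically to SST
#' and linearly to NPP, and a logistic size-biased collector retention
#' process.
#'
#' Per species and site the target log 95th percentile is
#' \deqn{\log P95 = \beta_0 + \beta_1 SST + \beta_2 SST^2 + \beta_3 NPP + \epsilon,
#'   \quad \epsilon \sim N(0, \sigma_{site}^2)}
#' and individual log areas are drawn
#' \eqn{N(\log P95 - z_{0.95}\sigma_{ind}, \sigma_{ind}^2)} with
#' \eqn{z_{0.95} = 1.6449}, so the population's theoretical 95th
#' percentile equals the target exactly.
#'
#' @param n_species number of species (>= 1).
#' @param n_sites number of sites (>= 3).
#' @param lat_range half-width of the latitudinal band in degrees
#'   (sites are uniform in \code{[-lat_range, lat_range]}).
#' @param sst_niche_centers per-species thermal optimum, degrees C. Recycled
#'   or defaulted to an even spread over 16-29 degrees C.
#' @param sst_niche_widths per-species niche standard deviation, degrees C.
#' @param size_coefficients matrix (n_species x 4) or length-4 vector of
#'   (beta0, beta1, beta2, beta3): intercept, SST slope, SST^2 term and
#'   NPP slope of the population log-P95 response, natural-log um^2 scale.
#' @param site_noise_sd sd of the site-level deviation of log-P95, log-units.
#' @param individual_log_sd sd of individual log areas around the
#'   population location, log-units.
#' @param individuals_per_site individuals drawn per species x site.
#' @param target_sst_npp_corr target Pearson correlation of SST and NPP
#'   across sites.
#' @param bias_midpoint,bias_steepness location and scale (log-units) of
#'   the logistic collector-retention curve
#'   \eqn{P(keep) = logistic((\log area - midpoint)/steepness)}.
#' @param drift_jitter_km if > 0, extra assemblage records are placed at
#'   coordinates jittered by up to this geodesic distance, emulating
#'   postmortem drift of settling shells.
#' @param grid_step grid spacing in degrees for the synthetic covariate
#'   grids.
#' @param seed root integer seed; per-stage child streams are derived
#'   from it so stages are independently reproducible.
#' @return a list of class \code{"sim_config"}.
#' @seealso [simulate_dataset()] for one-call generation.
#' @export
sim_config <- function(n_species = 5,
                       n_sites = 50,
                       lat_range = 40,
                       sst_niche_centers = NULL,
                       sst_niche_widths = 6,
                       size_coefficients = c(11.5, 0.05, 0, 5e-4),
                       site_noise_sd = 0.15,
                       individual_log_sd = 0.5,
                       individuals_per_site = 30,
                       target_sst_npp_corr = 0.4,
                       bias_midpoint = 11.8,
                       bias_steepness = 0.5,
                       drift_jitter_km = 0,
                       grid_step = 2,
                       seed = 1L) {
  if (n_species < 1) stop("n_species must be >= 1")
  if (n_sites < 3) stop("n_sites must be >= 3")
  if (!is.finite(lat_range) || lat_range <= 0 || lat_range > 90)
    stop("lat_range must be in (0, 90]")
  if (site_noise_sd <= 0 || individual_log_sd <= 0 || sst_niche_widths[1] <= 0)
    stop("all sd parameters must be > 0")
  if (individuals_per_site < 1) stop("individuals_per_site must be >= 1")
  if (abs(target_sst_npp_corr) > 1) stop("target_sst_npp_corr must be in [-1, 1]")

  if (is.null(sst_niche_centers))
    sst_niche_centers <- seq(16, 29, length.out = n_species)
  sst_niche_centers <- rep_len(sst_niche_centers, n_species)
  sst_niche_widths <- rep_len(sst_niche_widths, n_species)

  if (is.null(dim(size_coefficients))) {
    size_coefficients <- matrix(rep(size_coefficients, each = n_species),
                                nrow = n_species)
  }
  if (ncol(size_coefficients) != 4 || nrow(size_coefficients) != n_species)
    stop("size_coefficients must be n_species x 4 (beta0, beta1, beta2, beta3)")
  colnames(size_coefficients) <- c("beta0", "beta1", "beta2", "beta3")

  structure(list(
    n_species = as.integer(n_species),
    n_sites = as.integer(n_sites),
    lat_range = lat_range,
    sst_niche_centers = sst_niche_centers,
    sst_niche_widths = sst_niche_widths,
    size_coefficients = size_coefficients,
    site_noise_sd = site_noise_sd,
    individual_log_sd = individual_log_sd,
    individuals_per_site = as.integer(individuals_per_site),
    target_sst_npp_corr = target_sst_npp_corr,
    bias_midpoint = bias_midpoint,
    bias_steepness = bias_steepness,
    drift_jitter_km = drift_jitter_km,
    grid_step = grid_step,
    seed = as.integer(seed),
    species = sprintf("species_%02d", seq_len(n_species))
  ), class = "sim_config")
}

# quantile of the standard normal at p = 0.95, fixed so the generator's
# truth is analytically available in tests
Z95 <- 1.6449

# Child seed for a named generation stage. One root seed fans out into
# independent per-stage streams (Mersenne-Twister via set.seed), so e.g.
# respecifying the collector bias does not perturb the environment draw.
stage_seed <- function(seed, stage) {
  offsets <- c(environment = 11L, abundance = 23L, specimens = 37L,
               bias = 53L, jitter = 71L, pool = 89L, baseline = 97L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000003L) * 1009L + offsets[[stage]]
}

# latitudinal SST profile: warm at the equator, parabolic decline poleward
sst_profile <- function(lat) 28.5 - 18 * (lat / 45)^2

#' Simulate site locations, environment, and covariate grids
#'
#' Places \code{n_sites} sites uniformly in
#' \code{[-lat_range, lat_range]} latitude and \code{[-180, 180)}
#' longitude, builds regular lat/lon covariate grids for SST and NPP,
#' and reads each site's latent SST/NPP off its nearest grid node.
#' Grid SST is a smooth decreasing function of absolute latitude plus
#' noise; NPP is constructed from standardized SST plus independent
#' noise so that the realized site-level Pearson correlation converges
#' to \code{target_sst_npp_corr}, then rescaled to a mean of 500 and sd
#' of 150 mg C m^-2 day^-1.
#'
#' @param config a [sim_config()].
#' @return list with \code{sites} (data.frame: site_id, latitude,
#'   longitude, sst, npp) and \code{grids} (named list of long-format
#'   data.frames latitude/longitude/value for "sst" and "npp").
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "environment"))
  n <- config$n_sites
  step <- config$grid_step

  lat <- runif(n, -config$lat_range, config$lat_range)
  lon <- runif(n, -180, 180)

  # regular grid covering the latitudinal band
  glat <- seq(-ceiling(config$lat_range), ceiling(config$lat_range), by = step)
  glon <- seq(-180, 180 - step, by = step)
  grid <- expand.grid(latitude = glat, longitude = glon,
                      KEEP.OUT.ATTRS = FALSE)

  grid_sst <- sst_profile(grid$latitude) + rnorm(nrow(grid), 0, 1.5)

  # site latent SST with the same marginal structure, then NPP built from
  # the standardized SST so corr(SST, NPP) -> target across sites
  site_sst_raw <- sst_profile(lat) + rnorm(n, 0, 1.5)
  r <- config$target_sst_npp_corr
  z_sst <- as.numeric(scale(site_sst_raw))
  z_npp <- r * z_sst + sqrt(max(0, 1 - r^2)) * rnorm(n)
  site_npp_raw <- 500 + 150 * z_npp

  grid_npp <- 500 + 150 * (r * as.numeric(scale(grid_sst)) +
                             sqrt(max(0, 1 - r^2)) * rnorm(nrow(grid)))
  grid_npp <- pmax(grid_npp, 10)
  site_npp_raw <- pmax(site_npp_raw, 10)

  # write each site's latent value onto its nearest grid node, then read
  # it back: the stored grid is therefore exactly consistent with the
  # site table under nearest-node matching
  node_of <- function(x, breaks) {
    i <- round((x - breaks[1]) / step) + 1
    pmin(pmax(i, 1L), length(breaks))
  }
  ilat <- node_of(lat, glat)
  ilon <- node_of(lon, glon)
  idx <- (ilon - 1L) * length(glat) + ilat
  grid_sst[idx] <- site_sst_raw
  grid_npp[idx] <- site_npp_raw
  sst <- grid_sst[idx]
  npp <- grid_npp[idx]

  sites <- data.frame(
    site_id = sprintf("site_%03d", seq_len(n)),
    latitude = lat, longitude = lon,
    sst = sst, npp = npp,
    stringsAsFactors = FALSE
  )
  grids <- list(
    sst = data.frame(latitude = grid$latitude, longitude = grid$longitude,
                     value = grid_sst),
    npp = data.frame(latitude = grid$latitude, longitude = grid$longitude,
                     value = grid_npp)
  )
  list(sites = sites, grids = grids)
}

# Gaussian thermal-niche weights, rows = sites, cols = species
niche_weights <- function(sst, config) {
  w <- vapply(seq_len(config$n_species), function(i) {
    exp(-(sst - config$sst_niche_centers[i])^2 /
          (2 * config$sst_niche_widths[i]^2))
  }, numeric(length(sst)))
  matrix(w, nrow = length(sst))
}

#' Simulate assemblage relative abundances from Gaussian thermal niches
#'
#' Species i's weight at a site is
#' \eqn{\exp(-(SST - T_{opt,i})^2 / (2\sigma_{niche,i}^2))}; relative
#' abundance is the weight normalized over species, so abundances sum
#' to 1 at every site. With \code{drift_jitter_km > 0} extra records are
#' added at jittered coordinates (each with abundances from its own
#' local SST), emulating the scatter of seafloor assemblage databases
#' around the morphometric sites.
#'
#' @param sites site table from [simulate_environment()].
#' @param config a [sim_config()].
#' @return long-format data.frame: record_id, site_id, latitude,
#'   longitude, species, abundance.
#' @export
simulate_abundances <- function(sites, config) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(sites))
  set.seed(stage_seed(config$seed, "abundance"))
  w <- niche_weights(sites$sst, config)
  tot <- rowSums(w)
  if (any(tot <= 0 | !is.finite(tot))) {
    bad <- sites$site_id[tot <= 0 | !is.finite(tot)]
    stop("all species weights vanish at site(s) ", paste(bad, collapse = ", "),
         ": niche widths too narrow for the site's SST")
  }
  ab <- w / tot

  rec <- data.frame(
    record_id = paste0(sites$site_id, "_a0"),
    site_id = sites$site_id,
    latitude = sites$latitude,
    longitude = sites$longitude,
    stringsAsFactors = FALSE
  )
  out <- cbind(rec[rep(seq_len(nrow(rec)), each = config$n_species), ],
               species = rep(config$species, nrow(rec)),
               abundance = as.vector(t(ab)))

  if (config$drift_jitter_km > 0) {
    set.seed(stage_seed(config$seed, "jitter"))
    for (j in 1:2) {
      brg <- runif(nrow(sites), 0, 360)
      dst <- runif(nrow(sites), 0, config$drift_jitter_km) * 1000
      pts <- geosphere::destPoint(cbind(sites$longitude, sites$latitude),
                                  brg, dst)
      jit <- data.frame(
        record_id = paste0(sites$site_id, "_a", j),
        site_id = sites$site_id,
        latitude = pts[, "lat"],
        longitude = pts[, "lon"],
        stringsAsFactors = FALSE
      )
      jw <- niche_weights(sites$sst + rnorm(nrow(sites), 0, 0.5), config)
      jab <- jw / rowSums(jw)
      out <- rbind(out,
                   cbind(jit[rep(seq_len(nrow(jit)), each = config$n_species), ],
                         species = rep(config$species, nrow(jit)),
                         abundance = as.vector(t(jab))))
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate individual specimens with known population 95th percentiles
#'
#' For every species x site, the target natural-log 95th percentile is
#' \eqn{\beta_0 + \beta_1 SST + \beta_2 SST^2 + \beta_3 NPP + \epsilon}
#' with site noise \eqn{\epsilon \sim N(0, site\_noise\_sd^2)};
#' individual log areas are \eqn{N(target - 1.6449\,\sigma_{ind},
#' \sigma_{ind}^2)} so the population's theoretical 95th percentile
#' equals the target.
#'
#' @param sites site table from [simulate_environment()].
#' @param config a [sim_config()].
#' @return list with \code{specimens} (data.frame: species, site_id,
#'   latitude, longitude, area in um^2, collection = "simulated") and
#'   \code{truth} (data.frame per species x site: sst, npp, true log-P95
#'   target and the site noise draw).
#' @export
simulate_specimens <- function(sites, config) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(sites))
  if (config$individuals_per_site < 1)
    stop("individuals_per_site must be >= 1")
  set.seed(stage_seed(config$seed, "specimens"))

  pops <- expand.grid(species_i = seq_len(config$n_species),
                      site_i = seq_len(config$n_sites),
                      KEEP.OUT.ATTRS = FALSE)
  b <- config$size_coefficients[pops$species_i, , drop = FALSE]
  sst <- sites$sst[pops$site_i]
  npp <- sites$npp[pops$site_i]
  eps <- rnorm(nrow(pops), 0, config$site_noise_sd)
  target <- b[, "beta0"] + b[, "beta1"] * sst + b[, "beta2"] * sst^2 +
    b[, "beta3"] * npp + eps

  truth <- data.frame(
    species = config$species[pops$species_i],
    site_id = sites$site_id[pops$site_i],
    sst = sst, npp = npp,
    site_noise = eps,
    true_log_p95 = target,
    stringsAsFactors = FALSE
  )

  m <- config$individuals_per_site
  mu <- rep(target - Z95 * config$individual_log_sd, each = m)
  log_area <- rnorm(length(mu), mu, config$individual_log_sd)

  specimens <- data.frame(
    species = rep(truth$species, each = m),
    site_id = rep(truth$site_id, each = m),
    latitude = rep(sites$latitude[pops$site_i], each = m),
    longitude = rep(sites$longitude[pops$site_i], each = m),
    area = exp(log_area),
    collection = "simulated",
    stringsAsFactors = FALSE
  )
  list(specimens = specimens, truth = truth)
}

# draw m individuals per population from the lognormal size model given
# the truth table; stream picks the RNG child seed
draw_individuals <- function(truth, sites, config, m, stream) {
  set.seed(stage_seed(config$seed, stream))
  mu <- rep(truth$true_log_p95 - Z95 * config$individual_log_sd, each = m)
  log_area <- rnorm(length(mu), mu, config$individual_log_sd)
  i <- match(truth$site_id, sites$site_id)
  data.frame(
    species = rep(truth$species, each = m),
    site_id = rep(truth$site_id, each = m),
    latitude = rep(sites$latitude[i], each = m),
    longitude = rep(sites$longitude[i], each = m),
    area = exp(log_area),
    collection = stream,
    stringsAsFactors = FALSE
  )
}

#' Simulate paired collections for the collector-bias audit
#'
#' Emulates the museum-versus-resampled design: two independent draws
#' of individuals from the same populations (identical species x site
#' log-P95 targets), where the "collection" draw starts from a larger
#' candidate pool (\code{pool_factor} x \code{individuals_per_site},
#' the material a collector picks through) and is thinned by the
#' logistic size-biased retention, while the "baseline" draw of
#' \code{individuals_per_site} individuals is kept unbiased. Comparing
#' their population summaries with [bias_audit()] isolates the
#' collector effect.
#'
#' @param sites site table from [simulate_environment()].
#' @param config a [sim_config()].
#' @param pool_factor multiple of \code{individuals_per_site} in the
#'   pre-thinning collection pool.
#' @param biased if FALSE, the collection draw is thinned by a flat
#'   coin flip sized to match the expected biased retention count
#'   instead of the size-selective curve (for null comparisons).
#' @return list: \code{collection} (biased specimens),
#'   \code{baseline} (unbiased specimens), \code{truth}.
#' @export
simulate_paired_collections <- function(sites, config, pool_factor = 3,
                                        biased = TRUE) {
  sp <- simulate_specimens(sites, config)
  m <- config$individuals_per_site
  pool <- draw_individuals(sp$truth, sites, config, m * pool_factor, "pool")
  set.seed(stage_seed(config$seed, "bias"))
  if (biased) {
    p <- stats::plogis((log(pool$area) - config$bias_midpoint) /
                         config$bias_steepness)
  } else {
    p <- rep(mean(stats::plogis((log(pool$area) - config$bias_midpoint) /
                                  config$bias_steepness)), nrow(pool))
  }
  keep <- runif(nrow(pool)) < p
  collection <- pool[keep, , drop = FALSE]
  collection$collection <- "collection"
  rownames(collection) <- NULL
  baseline <- draw_individuals(sp$truth, sites, config, m, "baseline")
  baseline$collection <- "baseline"
  list(collection = collection, baseline = baseline, truth = sp$truth)
}

#' Apply size-biased collector retention to specimens
#'
#' Each specimen is kept independently with probability
#' \eqn{logistic((\log area - midpoint)/steepness)}: a collector
#' preferentially retaining large specimens, as museum hand-picked
#' collections are prone to. As \code{bias_steepness} grows the curve
#' flattens toward 0.5 (unbiased thinning).
#'
#' @param specimens specimen data.frame with an \code{area} column.
#' @param config a [sim_config()] providing \code{bias_midpoint},
#'   \code{bias_steepness} and the seed.
#' @param collection label written into the retained specimens'
#'   \code{collection} column.
#' @return the retained specimens, with \code{collection} relabelled.
#'   An empty result is allowed (a message is emitted).
#' @export
apply_collector_bias <- function(specimens, config, collection = "biased") {
  stopifnot(inherits(config, "sim_config"), is.data.frame(specimens))
  set.seed(stage_seed(config$seed, "bias"))
  p <- stats::plogis((log(specimens$area) - config$bias_midpoint) /
                       config$bias_steepness)
  keep <- runif(nrow(specimens)) < p
  out <- specimens[keep, , drop = FALSE]
  if (nrow(out) == 0)
    message("collector bias retained no specimens")
  out$collection <- collection
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_environment()], [simulate_abundances()] and
#' [simulate_specimens()] under one root seed and returns everything the
#' downstream pipeline consumes, plus the generating truth.
#'
#' @param config a [sim_config()].
#' @return list of class \code{"synthetic_dataset"}: \code{specimens},
#'   \code{sites}, \code{grids}, \code{assemblage}, \code{truth},
#'   \code{config}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  env <- simulate_environment(config)
  assemblage <- simulate_abundances(env$sites, config)
  sp <- simulate_specimens(env$sites, config)
  structure(list(
    specimens = sp$specimens,
    sites = env$sites,
    grids = env$grids,
    assemblage = assemblage,
    truth = sp$truth,
    config = config
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset to CSV files
#'
#' Writes specimens, sites, grids and assemblage tables as CSV and the
#' configuration as a plain-text key-value file into \code{dir}.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    specimens = file.path(dir, "specimens.csv"),
    sites = file.path(dir, "sites.csv"),
    grid_sst = file.path(dir, "grid_sst.csv"),
    grid_npp = file.path(dir, "grid_npp.csv"),
    assemblage = file.path(dir, "assemblage.csv"),
    truth = file.path(dir, "truth.csv"),
    config = file.path(dir, "config.txt")
  )
  utils::write.csv(dataset$specimens, files["specimens"], row.names = FALSE)
  utils::write.csv(dataset$sites, files["sites"], row.names = FALSE)
  utils::write.csv(dataset$grids$sst, files["grid_sst"], row.names = FALSE)
  utils::write.csv(dataset$grids$npp, files["grid_npp"], row.names = FALSE)
  utils::write.csv(dataset$assemblage, files["assemblage"], row.names = FALSE)
  utils::write.csv(dataset$truth, files["truth"], row.names = FALSE)
  cfg <- dataset$config
  scalar <- vapply(cfg, function(x) is.atomic(x) && length(x) == 1, logical(1))
  writeLines(c(
    paste0(names(cfg)[scalar], ": ", unlist(cfg[scalar])),
    paste0("sst_niche_centers: ", paste(cfg$sst_niche_centers, collapse = ",")),
    paste0("sst_niche_widths: ", paste(cfg$sst_niche_widths, collapse = ",")),
    paste0("size_coefficients: ",
           paste(apply(cfg$size_coefficients, 1, paste, collapse = ","),
                 collapse = ";"))
  ), files["config"])
  invisible(files)
}
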