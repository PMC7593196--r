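test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_species = 0), "n_species")
  expect_error(sim_config(n_sites = 2), "n_sites")
  expect_error(sim_config(lat_range = 0), "lat_range")
  expect_error(sim_config(lat_range = 95), "lat_range")
  expect_error(sim_config(site_noise_sd = 0), "sd parameters")
  expect_error(sim_config(individuals_per_site = 0), "individuals_per_site")
  expect_error(sim_config(size_coefficients = matrix(1, 2, 3)),
               "size_coefficients")
})

test_that("same seed gives identical datasets, different seeds differ", {
  a <- simulate_dataset(tiny_config(seed = 11))
  b <- simulate_dataset(tiny_config(seed = 11))
  expect_identical(a$specimens, b$specimens)
  expect_identical(a$sites, b$sites)
  expect_identical(a$grids, b$grids)
  expect_identical(a$assemblage, b$assemblage)
  c <- simulate_dataset(tiny_config(seed = 12))
  expect_false(identical(a$specimens$area, c$specimens$area))
})

test_that("per-stage seed streams keep stages independently reproducible", {
  cfg1 <- tiny_config(seed = 5)
  cfg2 <- tiny_config(seed = 5, bias_midpoint = 13)
  # changing a bias parameter must not perturb the environment draw
  expect_identical(simulate_environment(cfg1), simulate_environment(cfg2))
})

test_that("realized SST-NPP correlation converges to its target", {
  cors <- vapply(1:20, function(s) {
    env <- simulate_environment(sim_config(n_sites = 500, grid_step = 5,
                                           seed = 100 + s))
    cor(env$sites$sst, env$sites$npp)
  }, numeric(1))
  expect_true(all(cors > 0.3 & cors < 0.5))

  cors0 <- vapply(1:5, function(s) {
    env <- simulate_environment(sim_config(n_sites = 500, grid_step = 5,
                                           target_sst_npp_corr = 0,
                                           seed = 200 + s))
    cor(env$sites$sst, env$sites$npp)
  }, numeric(1))
  expect_true(all(abs(cors0) < 0.15))
})

test_that("environment geometry and grid consistency hold", {
  cfg <- tiny_config(seed = 3)
  env <- simulate_environment(cfg)
  expect_true(all(abs(env$sites$latitude) <= cfg$lat_range))
  expect_true(all(env$sites$longitude >= -180 & env$sites$longitude < 180))
  # site values are readable back off the stored grids by nearest match
  for (i in seq_len(nrow(env$sites))) {
    m <- nearest_match(env$sites$latitude[i], env$sites$longitude[i],
                       env$grids$sst)
    expect_equal(m$value, env$sites$sst[i])
  }
  # SST declines away from the equator on the grid (profile + bounded noise)
  g <- env$grids$sst
  eq <- mean(g$value[abs(g$latitude) < 10])
  edge <- mean(g$value[abs(g$latitude) > 30])
  expect_gt(eq, edge)
})

test_that("abundances are Gaussian-niche weights normalized across species", {
  # one species: abundance 1 everywhere
  cfg1 <- sim_config(n_species = 1, n_sites = 4, seed = 1)
  ab1 <- simulate_abundances(sites_with_sst(c(15, 20, 25, 28)), cfg1)
  expect_true(all(abs(ab1$abundance - 1) < 1e-12))

  # two species, equal widths, SST midway between optima: 0.5 / 0.5
  cfg2 <- sim_config(n_species = 2, n_sites = 3, seed = 1,
                     sst_niche_centers = c(18, 26), sst_niche_widths = 5)
  ab2 <- simulate_abundances(sites_with_sst(c(22, 22, 22)), cfg2)
  expect_equal(ab2$abundance, rep(0.5, 6))

  # sums to one at every record
  cfg <- tiny_config(seed = 9)
  env <- simulate_environment(cfg)
  ab <- simulate_abundances(env$sites, cfg)
  sums <- tapply(ab$abundance, ab$record_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # all-zero weights fail loudly, not as silent NaN
  cfg0 <- sim_config(n_species = 2, n_sites = 3, seed = 1,
                     sst_niche_centers = c(10, 12), sst_niche_widths = 1e-3)
  expect_error(simulate_abundances(sites_with_sst(c(25, 25, 25)), cfg0),
               "weights vanish")
})

test_that("individual sizes center so the theoretical P95 equals the target", {
  # degenerate individual noise: every log area equals the target log-P95
  cfg <- sim_config(n_species = 1, n_sites = 3, individuals_per_site = 10,
                    individual_log_sd = 1e-9, site_noise_sd = 1e-9,
                    grid_step = 5, seed = 21)
  env <- simulate_environment(cfg)
  sp <- simulate_specimens(env$sites, cfg)
  target <- sp$truth$true_log_p95[match(sp$specimens$site_id,
                                        sp$truth$site_id)]
  expect_equal(log(sp$specimens$area), target, tolerance = 1e-6)

  # Monte-Carlo oracle: sample P95 at 10,000 individuals within 0.02 of target
  cfg2 <- sim_config(n_species = 1, n_sites = 3, individuals_per_site = 10000,
                     grid_step = 5, seed = 22)
  env2 <- simulate_environment(cfg2)
  sp2 <- simulate_specimens(env2$sites, cfg2)
  sm <- population_summaries(sp2$specimens)
  i <- match(sm$site_id, sp2$truth$site_id)
  expect_true(all(abs(sm$p95 - sp2$truth$true_log_p95[i]) < 0.02))
})

test_that("sample P95 error shrinks at the order-statistic rate", {
  # empirical sd of (sample p95 - target) vs sqrt(p(1-p)/n)/phi(z95) * sigma
  cfg0 <- sim_config(n_species = 1, n_sites = 3, grid_step = 5, seed = 1)
  for (n in c(50, 500, 5000)) {
    errs <- unlist(lapply(1:25, function(r) {
      cfg <- sim_config(n_species = 1, n_sites = 3, individuals_per_site = n,
                        grid_step = 5, seed = 400 + r)
      env <- simulate_environment(cfg)
      sp <- simulate_specimens(env$sites, cfg)
      sm <- population_summaries(sp$specimens)
      sm$p95 - sp$truth$true_log_p95[match(sm$site_id, sp$truth$site_id)]
    }))
    theo <- sqrt(0.95 * 0.05 / n) / dnorm(1.6449) * cfg0$individual_log_sd
    expect_gt(sd(errs), 0.5 * theo)
    expect_lt(sd(errs), 2.0 * theo)
  }
})

test_that("a pure SST effect is recovered exactly from the truth table", {
  cfg <- sim_config(n_species = 1, n_sites = 20, site_noise_sd = 1e-9,
                    size_coefficients = c(11.5, 0.07, 0, 0),
                    grid_step = 5, seed = 31)
  env <- simulate_environment(cfg)
  sp <- simulate_specimens(env$sites, cfg)
  fit <- ols_ml_loglik(sp$truth$true_log_p95,
                       matrix(sp$truth$sst, ncol = 1))
  expect_equal(unname(fit$coefficients[2]), 0.07, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[1]), 11.5, tolerance = 1e-5)
})

test_that("collector retention is logistic in log area", {
  cfg <- sim_config(n_species = 2, n_sites = 30, individuals_per_site = 50,
                    grid_step = 5, seed = 51)
  env <- simulate_environment(cfg)
  sp <- simulate_specimens(env$sites, cfg)

  # flat-logistic limit: steepness so large the curve is ~0.5 everywhere
  cfg_flat <- sim_config(n_species = 2, n_sites = 30, individuals_per_site = 50,
                         grid_step = 5, bias_steepness = 1e6, seed = 51)
  kept <- apply_collector_bias(sp$specimens, cfg_flat)
  frac <- nrow(kept) / nrow(sp$specimens)
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)

  # size-biased retention raises the mean log area
  kept2 <- apply_collector_bias(sp$specimens, cfg)
  expect_gte(mean(log(kept2$area)), mean(log(sp$specimens$area)))
  expect_true(all(kept2$collection == "biased"))

  # determinism
  expect_identical(apply_collector_bias(sp$specimens, cfg),
                   apply_collector_bias(sp$specimens, cfg))
})

test_that("paired collections share truth but draw independent individuals", {
  cfg <- tiny_config(seed = 61)
  env <- simulate_environment(cfg)
  pc <- simulate_paired_collections(env$sites, cfg)
  expect_false(any(pc$collection$area %in% pc$baseline$area))
  expect_setequal(unique(pc$collection$site_id), unique(pc$baseline$site_id))
  # collection is size-shifted upward relative to baseline
  expect_gt(mean(log(pc$collection$area)), mean(log(pc$baseline$area)))
})

test_that("dataset round-trips through CSV files", {
  ds <- simulate_dataset(tiny_config(seed = 71))
  dir <- withr::local_tempdir()
  files <- write_dataset(ds, dir)
  expect_true(all(file.exists(files)))
  sp <- read.csv(files["specimens"])
  expect_equal(nrow(sp), nrow(ds$specimens))
  expect_equal(sp$area, ds$specimens$area, tolerance = 1e-12)
  ab <- read.csv(files["assemblage"])
  sums <- tapply(ab$abundance, ab$record_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
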