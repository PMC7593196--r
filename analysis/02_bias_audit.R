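#!/usr/bin/env Rscript
# Stage 2: collector-bias audit.
#
# Emulates the museum-vs-resampled comparison: two independent draws of
# individuals from the same populations at 10 sites, one thinned by the
# logistic size-biased collector retention. The audit ranks the five
# population metrics (mean, median, p75, p95, max of log area) by MSE
# of their residuals around the 1:1 line; the winner is the response
# metric used downstream.

library(foramsize)

cfg <- sim_config(n_species = 20, n_sites = 10, individuals_per_site = 25,
                  seed = 2027L)
env <- simulate_environment(cfg)
pc <- simulate_paired_collections(env$sites, cfg)

audit <- bias_audit(population_summaries(pc$collection),
                    population_summaries(pc$baseline))
print(audit)

dir.create("results", showWarnings = FALSE)
write.csv(audit$table, "results/bias_audit.csv", row.names = FALSE)
write.csv(audit$pairs, "results/bias_audit_pairs.csv", row.names = FALSE)

cat("\nall five mean residuals positive:",
    all(audit$table$mean_residual > 0),
    "-> the collection runs systematically large\n")
cat("audit tables written to results/bias_audit*.csv\n")
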