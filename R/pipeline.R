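#' End-to-end shell-size analysis pipeline
#'
#' Orchestrates the full analysis over a synthetic dataset or CSV
#' inputs: population summaries of log shell area, optional collector
#' bias audit, geodesic covariate matching (SST, NPP, abundance), and
#' per-species AICc model selection. Every stage's row counts and
#' parameters are recorded in a manifest; reruns with an identical
#' configuration reproduce identical outputs.
#'
#' Populations enter model selection only if their site has matched
#' covariates and they hold at least \code{min_individuals} specimens;
#' dropped populations are listed in the manifest.
#'
#' @param data either a \code{"synthetic_dataset"} (from
#'   [simulate_dataset()]) or a list with \code{specimens},
#'   \code{sites}, \code{grids}, \code{assemblage} in the same layout.
#' @param baseline_specimens optional second specimen table (e.g.
#'   resampled bulk sediment) triggering the collector-bias audit
#'   against \code{data$specimens}.
#' @param candidates candidate model list, see [candidate_models()].
#' @param delta_threshold plausible-set AICc cutoff.
#' @param radius_km abundance matching radius, km.
#' @param abundance_variant \code{"nearest"} (single nearest assemblage
#'   record, the headline variant) or \code{"radius"} (median within
#'   \code{radius_km}).
#' @param min_individuals minimum specimens per population.
#' @param exclude_sites site_ids to drop before analysis (sensitivity
#'   filter).
#' @param output_dir if non-NULL, all derived tables and the manifest
#'   are written there as CSV/text.
#' @return list of class \code{"pipeline_report"}: \code{summaries},
#'   \code{audit} (or NULL), \code{covariates}, \code{populations}
#'   (model-selection input), \code{selection} (per-species
#'   model_selection), \code{plausible} (per-species label vectors),
#'   \code{manifest}.
#' @export
run_pipeline <- function(data,
                         baseline_specimens = NULL,
                         candidates = candidate_models(),
                         delta_threshold = 2,
                         radius_km = 300,
                         abundance_variant = c("nearest", "radius"),
                         min_individuals = 1,
                         exclude_sites = character(0),
                         output_dir = NULL) {
  abundance_variant <- match.arg(abundance_variant)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(
    parameters = list(delta_threshold = delta_threshold,
                      radius_km = radius_km,
                      abundance_variant = abundance_variant,
                      min_individuals = min_individuals,
                      exclude_sites = exclude_sites),
    counts = list()
  )

  specimens <- data$specimens
  manifest$counts$specimens_in <- nrow(specimens)
  if (length(exclude_sites)) {
    specimens <- specimens[!specimens$site_id %in% exclude_sites, , drop = FALSE]
  }
  manifest$counts$specimens_after_site_filter <- nrow(specimens)

  summaries <- stage("population_summaries",
                     population_summaries(specimens, min_individuals = 1))
  manifest$counts$populations <- nrow(summaries)

  audit <- NULL
  if (!is.null(baseline_specimens)) {
    base_sum <- stage("population_summaries",
                      population_summaries(baseline_specimens))
    audit <- stage("bias_audit", bias_audit(summaries, base_sum))
    manifest$counts$audit_pairs <- audit$n_pairs
  }

  sites <- data$sites[!data$sites$site_id %in% exclude_sites, , drop = FALSE]
  sites <- sites[sites$site_id %in% specimens$site_id, , drop = FALSE]
  covs <- stage("match_covariates",
                match_covariates(sites[, c("site_id", "latitude", "longitude")],
                                 data$grids, data$assemblage,
                                 radius_km = radius_km))
  manifest$counts$sites_matched <- length(unique(covs$site_id))
  manifest$match_distance_quantiles <- lapply(
    grep("_dist_km$", names(covs), value = TRUE),
    function(cn) stats::quantile(covs[[cn]], c(0, 0.5, 1)))
  names(manifest$match_distance_quantiles) <-
    grep("_dist_km$", names(covs), value = TRUE)

  ab_col <- if (abundance_variant == "nearest") "abundance_nearest"
            else "abundance_radius"
  pops <- merge(summaries, covs,
                by.x = c("site_id", "species"),
                by.y = c("site_id", "species"))
  pops$abundance <- pops[[ab_col]]
  pops$log_p95 <- pops$p95
  small <- pops$n_individuals < min_individuals
  manifest$dropped_populations <- pops[small, c("species", "site_id",
                                                "n_individuals")]
  pops <- pops[!small, , drop = FALSE]
  manifest$counts$populations_analyzed <- nrow(pops)

  selection <- list()
  for (sp in sort(unique(pops$species))) {
    d <- pops[pops$species == sp, , drop = FALSE]
    sel <- tryCatch(
      stage("select_models",
            select_models(d, candidates, delta_threshold = delta_threshold)),
      error = function(e) e)
    selection[[sp]] <- sel
  }
  ok <- !vapply(selection, inherits, logical(1), "error")
  plausible <- lapply(selection[ok], `[[`, "plausible")
  manifest$counts$species_analyzed <- sum(ok)
  manifest$not_analyzable <- names(selection)[!ok]

  report <- structure(list(
    summaries = summaries,
    audit = audit,
    covariates = covs,
    populations = pops,
    selection = selection[ok],
    plausible = plausible,
    manifest = manifest
  ), class = "pipeline_report")

  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

# write all report tables + a plain-text manifest
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(report$populations, file.path(dir, "populations.csv"),
                   row.names = FALSE)
  sel <- do.call(rbind, lapply(names(report$selection), function(sp)
    cbind(species = sp, report$selection[[sp]]$table)))
  utils::write.csv(sel, file.path(dir, "model_selection.csv"),
                   row.names = FALSE)
  if (!is.null(report$audit)) {
    utils::write.csv(report$audit$table, file.path(dir, "bias_audit.csv"),
                     row.names = FALSE)
  }
  mf <- report$manifest
  lines <- c(
    "pipeline manifest",
    paste0("  ", names(mf$parameters), ": ",
           vapply(mf$parameters, function(x)
             paste(format(x), collapse = ","), character(1))),
    paste0("  ", names(mf$counts), ": ", unlist(mf$counts)),
    paste0("  not_analyzable: ", paste(mf$not_analyzable, collapse = ",")))
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report:", x$manifest$counts$populations_analyzed,
      "populations,", length(x$selection), "species analyzed\n")
  for (sp in names(x$plausible))
    cat(sprintf("  %-14s plausible: %s\n", sp,
                paste(x$plausible[[sp]], collapse = ", ")))
  if (!is.null(x$audit))
    cat("  bias audit selected metric:", x$audit$selected_metric, "\n")
  invisible(x)
}

#' Sensitivity rerun: plausible-set differences under a site filter
#'
#' Reruns the pipeline with the given sites excluded and reports, per
#' species, which models enter or leave the equally-plausible set
#' relative to the base run. Species whose data vanish under the filter
#' are flagged as not analyzable; the rerun continues for the others.
#'
#' @param data as for [run_pipeline()].
#' @param exclude_sites site_ids to drop in the filtered run.
#' @param ... further arguments passed to both [run_pipeline()] calls.
#' @return list of class \code{"sensitivity_report"}: \code{base},
#'   \code{filtered} (the two pipeline reports) and \code{diff}
#'   (per-species list with \code{entered}, \code{left},
#'   \code{unchanged} flag).
#' @export
sensitivity_rerun <- function(data, exclude_sites, ...) {
  base <- run_pipeline(data, ...)
  filtered <- run_pipeline(data, exclude_sites = exclude_sites, ...)
  species <- union(names(base$plausible), names(filtered$plausible))
  diff <- lapply(stats::setNames(species, species), function(sp) {
    b <- base$plausible[[sp]]
    f <- filtered$plausible[[sp]]
    if (is.null(f)) {
      list(analyzable = FALSE, entered = character(0), left = b,
           unchanged = FALSE)
    } else {
      list(analyzable = TRUE,
           entered = setdiff(f, b),
           left = setdiff(b, f),
           unchanged = setequal(b, f))
    }
  })
  structure(list(base = base, filtered = filtered, diff = diff),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity rerun (", length(x$diff), "species )\n")
  for (sp in names(x$diff)) {
    d <- x$diff[[sp]]
    if (!d$analyzable) {
      cat(sprintf("  %-14s not analyzable after filter\n", sp))
    } else if (d$unchanged) {
      cat(sprintf("  %-14s unchanged\n", sp))
    } else {
      cat(sprintf("  %-14s entered: {%s} left: {%s}\n", sp,
                  paste(d$entered, collapse = ","),
                  paste(d$left, collapse = ",")))
    }
  }
  invisible(x)
}
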