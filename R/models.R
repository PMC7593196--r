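#' Candidate size-environment models
#'
#' The candidate set relating population log shell size to mean annual
#' sea-surface temperature (sst), net primary productivity (pp) and
#' species relative abundance (abund). Labels expand to design terms
#' as: \code{null} = intercept only; \code{sst} = SST; \code{sst2} =
#' SST + SST^2; \code{pp} = NPP; \code{abund} = abundance;
#' \code{sst+pp} and \code{sst+abund} additive; \code{sst:pp} = SST +
#' NPP + SST x NPP (main effects included); \code{sst2+pp} = SST +
#' SST^2 + NPP; \code{sst2:pp} = SST + SST^2 + NPP + SST x NPP.
#' The parameter count k includes the residual variance, so e.g. the
#' intercept-only model has k = 2 and \code{sst2:pp} has k = 6.
#'
#' @param labels subset of the ten labels; default = all.
#' @return named list; each element has \code{terms} (design-term
#'   names) and \code{k}.
#' @export
candidate_models <- function(labels = NULL) {
  all <- list(
    "null"      = character(0),
    "sst"       = "sst",
    "sst2"      = c("sst", "sst_sq"),
    "pp"        = "npp",
    "abund"     = "abundance",
    "sst+pp"    = c("sst", "npp"),
    "sst+abund" = c("sst", "abundance"),
    "sst:pp"    = c("sst", "npp", "sst_x_npp"),
    "sst2+pp"   = c("sst", "sst_sq", "npp"),
    "sst2:pp"   = c("sst", "sst_sq", "npp", "sst_x_npp")
  )
  if (is.null(labels)) labels <- names(all)
  unknown <- setdiff(labels, names(all))
  if (length(unknown)) stop("unknown candidate label(s): ",
                            paste(unknown, collapse = ", "))
  lapply(stats::setNames(labels, labels), function(l)
    list(terms = all[[l]], k = length(all[[l]]) + 2L))
}

#' Gaussian maximum-likelihood linear fit
#'
#' Ordinary least-squares coefficients with the Gaussian maximum
#' likelihood, \eqn{\log L = -\frac{n}{2}(\ln(2\pi RSS/n) + 1)}, i.e.
#' the likelihood at the ML variance estimate RSS/n. This is the
#' log-likelihood that feeds AICc.
#'
#' @param y response vector (no missing values).
#' @param X design matrix of regressors, excluding the intercept
#'   (added internally); NULL or 0 columns for the intercept-only
#'   model.
#' @return list: \code{coefficients} (intercept first), \code{rss},
#'   \code{logLik}, \code{n}, \code{k} (coefficients + 1 for the
#'   residual variance), \code{r_squared}, \code{fitted},
#'   \code{residuals}.
#' @export
ols_ml_loglik <- function(y, X = NULL) {
  if (anyNA(y) || (!is.null(X) && anyNA(X))) stop("missing values in y or X")
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  X <- as.matrix(X)
  Xi <- cbind("(Intercept)" = 1, X)
  if (n <= ncol(Xi)) stop("need n > number of coefficients")
  qr_ <- qr(Xi)
  if (qr_$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qr_$pivot[(qr_$rank + 1):ncol(Xi)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qr_, y)
  fitted <- drop(Xi %*% beta)
  rss <- sum((y - fitted)^2)
  if (rss <= 0)
    stop("zero residual sum of squares: degenerate Gaussian likelihood")
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  tss <- sum((y - mean(y))^2)
  list(
    coefficients = beta,
    rss = rss,
    logLik = ll,
    n = n,
    k = ncol(Xi) + 1L,
    r_squared = if (tss > 0) 1 - rss / tss else 0,
    fitted = fitted,
    residuals = y - fitted
  )
}

#' Akaike information criterion corrected for small samples
#'
#' \deqn{AICc = -2\log L + 2k + \frac{2k(k+1)}{n - k - 1}}
#' where k counts all estimated parameters including the residual
#' variance. Converges to AIC as n grows; undefined for n <= k + 1.
#'
#' @param logLik model log-likelihood (natural log).
#' @param k number of parameters including the residual variance.
#' @param n number of observations.
#' @return the AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (any(n <= k + 1)) stop("AICc undefined: need n > k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# build the design matrix for a candidate's terms from a populations table
design_matrix <- function(populations, terms) {
  cols <- list(
    sst = function(d) d$sst,
    sst_sq = function(d) d$sst^2,
    npp = function(d) d$npp,
    abundance = function(d) d$abundance,
    sst_x_npp = function(d) d$sst * d$npp
  )
  needs <- list(sst = "sst", sst_sq = "sst", npp = "npp",
                abundance = "abundance", sst_x_npp = c("sst", "npp"))
  missing_cols <- setdiff(unique(unlist(needs[terms])), names(populations))
  if (length(missing_cols))
    stop("populations table lacks covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  if (length(terms) == 0)
    return(matrix(numeric(0), nrow = nrow(populations), ncol = 0))
  X <- vapply(terms, function(t) cols[[t]](populations),
              numeric(nrow(populations)))
  matrix(X, ncol = length(terms), dimnames = list(NULL, terms))
}

#' Fit and rank the candidate model set by AICc
#'
#' Fits every candidate by Gaussian maximum likelihood, computes AICc,
#' AICc differences to the best model, Akaike weights
#' \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}} over the fitted
#' set, and adjusted \eqn{R^2 = 1 - (1 - R^2)(n-1)/(n-p-1)} with p the
#' number of regressors excluding the intercept. Models within
#' \code{delta_threshold} AICc units of the best (strict inequality)
#' form the "equally plausible" set. Candidates infeasible at the given
#' n (n <= k + 1) are skipped with a warning.
#'
#' @param populations data.frame with column \code{log_p95} and the
#'   covariates needed by the candidates (\code{sst}, \code{npp},
#'   \code{abundance}).
#' @param candidates a [candidate_models()] list (default: all ten).
#' @param delta_threshold plausible-set cutoff in AICc units
#'   (default 2).
#' @param center if TRUE, center covariates before fitting (off by
#'   default; covariates are used untransformed).
#' @return list of class \code{"model_selection"}: \code{table}
#'   (per-model label, k, logLik, AICc, delta_aicc, weight, r2_adj,
#'   sorted by AICc), \code{plausible} (labels with delta <
#'   threshold), \code{fits} (full fit objects), \code{n}.
#' @export
select_models <- function(populations, candidates = candidate_models(),
                          delta_threshold = 2, center = FALSE) {
  stopifnot(is.data.frame(populations), "log_p95" %in% names(populations))
  y <- populations$log_p95
  n <- length(y)
  if (center) {
    for (v in intersect(c("sst", "npp", "abundance"), names(populations)))
      populations[[v]] <- populations[[v]] - mean(populations[[v]])
  }

  fits <- list()
  for (label in names(candidates)) {
    cand <- candidates[[label]]
    if (n <= cand$k + 1) {
      warning("skipping candidate '", label, "': n = ", n,
              " too small for k = ", cand$k)
      next
    }
    X <- design_matrix(populations, cand$terms)
    fit <- tryCatch(ols_ml_loglik(y, X), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("skipping candidate '", label, "': ", conditionMessage(fit))
      next
    }
    p <- length(cand$terms)
    fit$label <- label
    fit$aicc <- aicc(fit$logLik, cand$k, n)
    fit$r2_adj <- if (n - p - 1 > 0)
      1 - (1 - fit$r_squared) * (n - 1) / (n - p - 1) else NA_real_
    fits[[label]] <- fit
  }
  if (length(fits) == 0) stop("no candidate model is feasible at n = ", n)

  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  w <- w / sum(w)

  tab <- data.frame(
    label = names(fits),
    k = vapply(fits, `[[`, integer(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    aicc = aiccs,
    delta_aicc = delta,
    weight = w,
    r2_adj = vapply(fits, `[[`, numeric(1), "r2_adj"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL

  structure(list(
    table = tab,
    plausible = tab$label[tab$delta_aicc < delta_threshold],
    fits = fits,
    n = n,
    delta_threshold = delta_threshold
  ), class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection over", nrow(x$table), "candidates, n =", x$n, "\n")
  print(x$table, digits = 4)
  cat("plausible set (delta AICc <", x$delta_threshold, "):",
      paste(x$plausible, collapse = ", "), "\n")
  invisible(x)
}

#' Random-intercept likelihood-ratio test for an abundance effect
#'
#' Tests whether population log shell size is predicted by local
#' relative abundance across species, with species as a random
#' intercept: ML fits (not REML, so the fixed-effect comparison is
#' valid) of \code{log_p95 ~ abundance + (1 | species)} against
#' \code{log_p95 ~ 1 + (1 | species)}; the statistic is
#' \eqn{\chi^2 = 2(\log L_{full} - \log L_{null})} on 1 df.
#'
#' @param populations data.frame with columns \code{log_p95},
#'   \code{abundance}, \code{species}.
#' @return list of class \code{"abundance_lrt"}: \code{chisq},
#'   \code{df}, \code{p_value}, \code{slope} (fixed-effect abundance
#'   estimate), \code{logLik_full}, \code{logLik_null},
#'   \code{singular} (TRUE if a variance component sat on the
#'   boundary).
#' @export
lrt_abundance_mixed <- function(populations) {
  stopifnot(is.data.frame(populations),
            all(c("log_p95", "abundance", "species") %in% names(populations)))
  if (length(unique(populations$species)) < 2)
    stop("need >= 2 species for a species random intercept")
  counts <- table(populations$species)
  if (any(counts < 2))
    stop("need >= 2 populations per species; too few for: ",
         paste(names(counts)[counts < 2], collapse = ", "))

  full <- lme4::lmer(log_p95 ~ abundance + (1 | species),
                     data = populations, REML = FALSE)
  null <- lme4::lmer(log_p95 ~ 1 + (1 | species),
                     data = populations, REML = FALSE)
  ll_f <- as.numeric(stats::logLik(full))
  ll_n <- as.numeric(stats::logLik(null))
  chisq <- max(0, 2 * (ll_f - ll_n))
  structure(list(
    chisq = chisq,
    df = 1L,
    p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
    slope = unname(lme4::fixef(full)["abundance"]),
    logLik_full = ll_f,
    logLik_null = ll_n,
    singular = lme4::isSingular(full) || lme4::isSingular(null)
  ), class = "abundance_lrt")
}

#' @export
print.abundance_lrt <- function(x, ...) {
  cat(sprintf(
    "Mixed-model LRT for abundance: chisq(%d) = %.2f, p = %.3g, slope = %.4g%s\n",
    x$df, x$chisq, x$p_value, x$slope,
    if (x$singular) " [variance component on boundary]" else ""))
  invisible(x)
}
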