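# Meta-analytic benefit-transfer model for ecosystem-service values:
# country random-intercept mixed models fitted by maximum likelihood,
# exhaustively enumerated over fixed-effect subsets, selected by
# delta-AICc <= 2, combined by Akaike weights, and used for spatial
# prediction with bootstrap uncertainty. Mixed models are fitted with
# lme4; AICc, enumeration, weighting, averaging, cross-validation and
# the direct benefit-transfer baseline are implemented here.

es_class_levels <- function() c("cultural", "provisioning", "regulating")
method_class_levels <- function() {
  c("cost-based", "revealed preference", "stated preference")
}

#' Default candidate fixed-effect terms for model enumeration
#'
#' Eight terms (the two clustered factors plus six spatial/temporal
#' covariates), so exhaustive enumeration yields 2^8 = 256 models.
#'
#' @return Character vector of term labels.
#' @export
es_candidate_terms <- function() {
  c(
    "es_class", "method_class", "year", "temperature", "precipitation",
    "accessibility", "richness_birds", "carbon_density"
  )
}

#' Screen raw valuation records
#'
#' Applies the standard valuation-database exclusion rules, expressed
#' as data-driven
#' flags on the raw table: records derived by benefit transfer, records
#' without a specific location, ES type or valuation method, and
#' net-present-value records lacking a discount rate or horizon are
#' removed. Surviving NPV records are annualized with the annuity factor
#' before inclusion.
#'
#' @param raw data frame of raw records. Recognised flag columns (all
#'   optional, assumed passing when absent): `benefit_transfer`,
#'   `has_location`, `has_es_type`, `has_method`. NPV records carry
#'   `is_npv = TRUE` with `npv`, `discount_rate`, `horizon`; others carry
#'   `value` (currency/ha/yr).
#' @param rules named logical vector enabling each rule; see
#'   [default_screening_rules()].
#' @return The surviving records with `value` and `log_value` filled in,
#'   plus attribute `screening_report` counting removals per rule.
#' @export
screen_records <- function(raw, rules = default_screening_rules()) {
  keep <- rep(TRUE, nrow(raw))
  report <- c()
  drop_rule <- function(keep, fail, label) {
    fail <- fail & keep
    report[label] <<- sum(fail)
    keep & !fail
  }
  flag <- function(col, default = FALSE) {
    if (col %in% names(raw)) isTRUE(rules[[col]]) & raw[[col]] else
      rep(default, nrow(raw))
  }
  if (isTRUE(rules[["benefit_transfer"]]) && "benefit_transfer" %in% names(raw)) {
    keep <- drop_rule(keep, raw$benefit_transfer %in% TRUE, "benefit_transfer")
  }
  for (col in c("has_location", "has_es_type", "has_method")) {
    if (isTRUE(rules[[col]]) && col %in% names(raw)) {
      keep <- drop_rule(keep, !(raw[[col]] %in% TRUE), col)
    }
  }
  if (isTRUE(rules[["npv_needs_rate"]]) && "is_npv" %in% names(raw)) {
    bad <- raw$is_npv %in% TRUE &
      (is.na(raw$discount_rate) | is.na(raw$horizon))
    keep <- drop_rule(keep, bad, "npv_without_rate")
  }
  out <- raw[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no records survive screening", call. = FALSE)
  if ("is_npv" %in% names(out)) {
    npv <- out$is_npv %in% TRUE
    if (any(npv)) {
      out$value[npv] <- annualize(
        out$npv[npv], out$discount_rate[npv], out$horizon[npv]
      )
    }
  }
  if (any(out$value <= 0)) {
    stop("screened records must have positive value", call. = FALSE)
  }
  out$log_value <- log(out$value)
  attr(out, "screening_report") <- report
  class(out) <- unique(c("valuation_records", class(out)))
  out
}

#' Default record-screening rules (all enabled)
#' @return Named logical vector.
#' @export
default_screening_rules <- function() {
  c(
    benefit_transfer = TRUE, has_location = TRUE, has_es_type = TRUE,
    has_method = TRUE, npv_needs_rate = TRUE
  )
}

# coerce the clustered factors to fixed level sets so prediction designs
# are stable even when a resample lacks a level
prepare_model_frame <- function(records) {
  d <- as.data.frame(records)
  if ("es_class" %in% names(d)) {
    d$es_class <- factor(d$es_class, levels = es_class_levels())
  }
  if ("method_class" %in% names(d)) {
    d$method_class <- factor(d$method_class, levels = method_class_levels())
  }
  d$country <- factor(d$country)
  d
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik maximized log-likelihood (ML scale).
#' @param k number of estimated parameters (fixed effects, variance
#'   components and intercept).
#' @param n number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) {
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one ES-value mixed model
#'
#' Fits `log_value ~ terms + (1 | country)` by maximum likelihood (not
#' REML, so AICc is comparable across fixed-effect sets). With a single
#' country the model degenerates to a fixed-effects regression and the
#' country variance is reported as 0 with a flag; a singular fit
#' likewise reports `sigma_country = 0` with a flag. A rank-deficient
#' fixed-effect design is an error naming the collinear columns.
#'
#' @param records a fit-ready `valuation_records` table (needs
#'   `log_value` and `country`).
#' @param terms character vector of fixed-effect term labels (may be
#'   empty for the intercept-only model).
#' @return An `es_model`: coefficients, variance components, estimated
#'   country effects, log-likelihood, parameter count `k`, AICc, training
#'   means of `year` and `forest_area` (used to fill unmapped predictors
#'   at prediction time), and flags.
#' @export
fit_mixed_model <- function(records, terms = character()) {
  d <- prepare_model_frame(records)
  if (!"log_value" %in% names(d)) stop("records need a log_value column")
  fixed <- stats::reformulate(if (length(terms)) terms else "1",
    response = "log_value"
  )
  X <- stats::model.matrix(stats::reformulate(
    if (length(terms)) terms else "1"
  ), d)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(
      "rank-deficient design; collinear terms: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  one_country <- length(unique(d$country)) < 2L
  singular <- FALSE
  if (one_country) {
    fit <- stats::lm(fixed, data = d)
    fixef <- stats::coef(fit)
    fixef_se <- summary(fit)$coefficients[, "Std. Error"]
    sigma_resid <- sqrt(sum(stats::residuals(fit)^2) / nrow(d)) # ML scale
    sigma_country <- 0
    country_effects <- stats::setNames(
      numeric(length(levels(d$country))), levels(d$country)
    )
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
  } else {
    form <- stats::update(fixed, . ~ . + (1 | country))
    fit <- suppressMessages(lme4::lmer(
      form,
      data = d, REML = FALSE,
      control = lme4::lmerControl(
        calc.derivs = FALSE,
        check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)
      )
    ))
    singular <- lme4::isSingular(fit)
    fixef <- lme4::fixef(fit)
    fixef_se <- stats::setNames(
      sqrt(diag(as.matrix(stats::vcov(fit)))), names(fixef)
    )
    vc <- lme4::VarCorr(fit)
    sigma_country <- attr(vc$country, "stddev")[[1]]
    sigma_resid <- stats::sigma(fit)
    re <- lme4::ranef(fit)$country
    country_effects <- stats::setNames(re[["(Intercept)"]], rownames(re))
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
  }
  model <- list(
    terms = terms,
    fixef = fixef,
    fixef_se = fixef_se,
    alpha = unname(fixef[["(Intercept)"]]),
    beta = fixef[setdiff(names(fixef), "(Intercept)")],
    sigma_country = as.numeric(sigma_country),
    sigma_resid = as.numeric(sigma_resid),
    country_effects = country_effects,
    loglik = ll, k = k, n = nrow(d),
    aicc = aicc(ll, k, nrow(d)),
    train_means = c(
      year = if ("year" %in% names(d)) mean(d$year) else NA_real_,
      forest_area = if ("forest_area" %in% names(d)) mean(d$forest_area) else NA_real_
    ),
    one_country = one_country,
    singular = singular
  )
  class(model) <- "es_model"
  model
}

#' Predict log values from a fitted ES model
#'
#' Known countries receive their estimated random intercept; countries
#' unseen in training are predicted from the fixed effects only. `year`
#' and `forest_area`, which have no spatial layer, are filled with their
#' training means when absent from `newdata`. Any other missing
#' covariate used by the model is an error naming it.
#'
#' @param object an `es_model`.
#' @param newdata data frame of prediction rows (needs a `country`
#'   column for the random-effect lookup; absent countries use fixed
#'   effects only).
#' @param ... unused.
#' @return Numeric vector of predicted log values.
#' @export
predict.es_model <- function(object, newdata, ...) {
  d <- as.data.frame(newdata)
  for (v in c("year", "forest_area")) {
    if (v %in% object$terms && !v %in% names(d)) {
      d[[v]] <- object$train_means[[v]]
    }
  }
  missing <- setdiff(object$terms, names(d))
  if (length(missing)) {
    stop(
      "newdata lacks covariates: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  d <- prepare_model_frame(
    if ("country" %in% names(d)) d else cbind(d, country = NA)
  )
  X <- stats::model.matrix(stats::reformulate(
    if (length(object$terms)) object$terms else "1"
  ), d)
  stopifnot(all(colnames(X) %in% names(object$fixef)))
  eta <- drop(X %*% object$fixef[colnames(X)])
  if ("country" %in% names(newdata)) {
    ac <- object$country_effects[as.character(newdata$country)]
    ac[is.na(ac)] <- 0 # unseen country: fixed effects only
    eta <- eta + ac
  }
  unname(eta)
}

#' Enumerate all fixed-effect subsets and fit each model
#'
#' Fits every subset of `candidate_terms` (including the intercept-only
#' model): 2^J models, e.g. 256 for the default 8 candidate terms.
#' Delta-AICc and Akaike weights `exp(-delta/2) / sum(exp(-delta/2))`
#' are computed over all models that fitted; failures are recorded and
#' excluded from the weights.
#'
#' @param records fit-ready records.
#' @param candidate_terms candidate fixed-effect labels (at most 12).
#' @return An `es_model_set` with the fitted models, their term lists,
#'   AICc, delta-AICc, Akaike weights and a list of failed subsets.
#' @export
enumerate_models <- function(records, candidate_terms = es_candidate_terms()) {
  j <- length(candidate_terms)
  if (j > 12L) stop("at most 12 candidate terms (2^J enumeration)", call. = FALSE)
  subsets <- lapply(seq_len(2^j) - 1L, function(mask) {
    candidate_terms[bitwAnd(mask, 2^(seq_len(j) - 1L)) > 0]
  })
  models <- vector("list", length(subsets))
  failed <- list()
  for (i in seq_along(subsets)) {
    m <- tryCatch(fit_mixed_model(records, subsets[[i]]),
      error = function(e) e
    )
    if (inherits(m, "error")) {
      failed[[length(failed) + 1L]] <- list(
        terms = subsets[[i]], message = conditionMessage(m)
      )
      models[[i]] <- NULL
    } else {
      models[[i]] <- m
    }
  }
  ok <- !vapply(models, is.null, logical(1))
  models <- models[ok]
  terms_list <- subsets[ok]
  aicc_vals <- vapply(models, function(m) m$aicc, numeric(1))
  delta <- aicc_vals - min(aicc_vals)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  set <- list(
    models = models, terms_list = terms_list, aicc = aicc_vals,
    delta_aicc = delta, akaike_weight = w,
    top_mask = rep(TRUE, length(models)),
    failed = failed, cutoff = NA_real_, n_candidates = j
  )
  class(set) <- "es_model_set"
  set
}

#' Retain the high-support models (delta-AICc within a cutoff)
#'
#' Models with delta-AICc less than or equal to the cutoff (inclusive;
#' ties at the boundary are retained) are kept and their Akaike weights
#' renormalized to sum to 1.
#'
#' @param model_set an `es_model_set`.
#' @param cutoff delta-AICc cutoff (default 2).
#' @return An `es_model_set` containing only the retained models.
#' @export
select_top <- function(model_set, cutoff = 2) {
  keep <- model_set$delta_aicc <= cutoff
  set <- model_set
  set$models <- model_set$models[keep]
  set$terms_list <- model_set$terms_list[keep]
  set$aicc <- model_set$aicc[keep]
  set$delta_aicc <- model_set$delta_aicc[keep]
  w <- model_set$akaike_weight[keep]
  set$akaike_weight <- w / sum(w)
  set$top_mask <- rep(TRUE, sum(keep))
  set$cutoff <- cutoff
  set
}

# rebuild a model set from a list of already-fitted models (used by the
# bootstrap refit path); weights recomputed from AICc
model_set_from_models <- function(models) {
  aicc_vals <- vapply(models, function(m) m$aicc, numeric(1))
  delta <- aicc_vals - min(aicc_vals)
  w <- exp(-delta / 2)
  set <- list(
    models = models,
    terms_list = lapply(models, function(m) m$terms),
    aicc = aicc_vals, delta_aicc = delta, akaike_weight = w / sum(w),
    top_mask = rep(TRUE, length(models)),
    failed = list(), cutoff = NA_real_,
    n_candidates = NA_integer_
  )
  class(set) <- "es_model_set"
  set
}

#' Model-averaged prediction
#'
#' Per-model predictions (conditional on the estimated country effects
#' where available) combined as a weighted average using renormalized
#' Akaike weights. Averaging at the prediction level is equivalent to
#' conditional coefficient averaging for these linear predictors.
#'
#' @param top_set an `es_model_set` (typically after [select_top()]).
#' @param newdata prediction rows.
#' @param mode averaging mode; only `"conditional"` is implemented.
#' @return Numeric vector of model-averaged predicted log values.
#' @export
average_predict <- function(top_set, newdata, mode = "conditional") {
  mode <- match.arg(mode, "conditional")
  w <- top_set$akaike_weight / sum(top_set$akaike_weight)
  preds <- vapply(
    top_set$models, function(m) predict(m, newdata),
    numeric(nrow(as.data.frame(newdata)))
  )
  preds <- matrix(preds, nrow = nrow(as.data.frame(newdata)))
  drop(preds %*% w)
}

#' Predict the per-cell total ecosystem-service value surface
#'
#' For each cell and each ES class, one prediction is made per
#' valuation-method level; the three method-level predictions are
#' averaged on the log scale and back-transformed by exponentiation
#' (a geometric mean over methods). Class values are then combined as
#' `TEV = sum(multiplier_class * value_class)`; the default multipliers
#' (cultural 5, provisioning 5, regulating 6) count the service types
#' aggregated per class, with one regulating service excluded to avoid
#' double counting the separately valued carbon emissions.
#'
#' @param top_set an `es_model_set`.
#' @param grid a `landscape_grid`.
#' @param multipliers named non-negative counts per ES class.
#' @return Numeric per-cell TEV (currency/ha/yr) with attribute
#'   `components`, the per-class value matrix.
#' @export
predict_tev_grid <- function(top_set, grid,
                             multipliers = c(
                               cultural = 5, provisioning = 5,
                               regulating = 6
                             )) {
  if (any(multipliers < 0)) config_error("multipliers", "must be >= 0")
  stopifnot(all(sort(names(multipliers)) == sort(es_class_levels())))
  base <- as.data.frame(grid)
  base$country <- grid$country_id
  comp <- matrix(0, nrow(base), 3,
    dimnames = list(NULL, es_class_levels())
  )
  for (cl in es_class_levels()) {
    logp <- matrix(0, nrow(base), length(method_class_levels()))
    for (mi in seq_along(method_class_levels())) {
      nd <- base
      nd$es_class <- cl
      nd$method_class <- method_class_levels()[mi]
      logp[, mi] <- average_predict(top_set, nd)
    }
    comp[, cl] <- exp(rowMeans(logp))
  }
  tev <- drop(comp %*% multipliers[colnames(comp)])
  attr(tev, "components") <- comp
  tev
}

#' Bootstrap ensemble of TEV surfaces
#'
#' Resamples the valuation records with replacement, refits the selected
#' top-model structures on each resample, recomputes their Akaike
#' weights, and re-predicts the TEV surface, yielding B bootstrap maps
#' of total ES value. Replicates whose refit fails (e.g. a resample that
#' loses a factor level) are redrawn and counted. With
#' `re_enumerate = TRUE` the full enumeration and selection is rerun per
#' replicate instead.
#'
#' @param records fit-ready records.
#' @param grid a `landscape_grid`.
#' @param B number of bootstrap replicates.
#' @param candidate_terms candidate terms for the selection run.
#' @param cutoff delta-AICc cutoff.
#' @param multipliers per-class service-type counts.
#' @param seed integer seed.
#' @param re_enumerate rerun the full enumeration per replicate?
#' @param top_set optionally, a pre-selected `es_model_set` to reuse.
#' @return An `es_map_ensemble`: `maps` (cells x B matrix), the point
#'   estimate map, the selected set, and the redraw count.
#' @export
bootstrap_es_maps <- function(records, grid, B = 500L,
                              candidate_terms = es_candidate_terms(),
                              cutoff = 2,
                              multipliers = c(
                                cultural = 5, provisioning = 5,
                                regulating = 6
                              ),
                              seed = 1L, re_enumerate = FALSE,
                              top_set = NULL) {
  stopifnot(B >= 1L)
  if (is.null(top_set)) {
    top_set <- select_top(enumerate_models(records, candidate_terms), cutoff)
  }
  point_map <- predict_tev_grid(top_set, grid, multipliers)
  n <- nrow(records)
  maps <- matrix(NA_real_, nrow(grid), B)
  redraws <- 0L
  with_seed(derive_seed(seed, "es_bootstrap"), {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        res <- tryCatch(
          {
            d <- records[idx, , drop = FALSE]
            set_b <- if (re_enumerate) {
              select_top(enumerate_models(d, candidate_terms), cutoff)
            } else {
              model_set_from_models(
                lapply(top_set$terms_list, function(tt) fit_mixed_model(d, tt))
              )
            }
            predict_tev_grid(set_b, grid, multipliers)
          },
          error = function(e) e
        )
        if (!inherits(res, "error")) break
        redraws <- redraws + 1L
        if (redraws > 10L * B) {
          stop("bootstrap: too many failed replicates", call. = FALSE)
        }
      }
      maps[, b] <- res
    }
  })
  structure(
    list(
      maps = maps, B = B, point_map = point_map, top_set = top_set,
      multipliers = multipliers, redraws = redraws
    ),
    class = "es_map_ensemble"
  )
}

#' Leave-one-out cross-validation of the selection-and-averaging pipeline
#'
#' Each record is held out in turn; the remaining records are refitted
#' (either by rerunning the full enumeration and selection, or by
#' refitting fixed top-model structures) and the held-out record is
#' predicted by the averaged model. Accuracy is summarized by the mean
#' absolute percentage error on the log-value scale, and by a
#' through-origin regression of observed on predicted values
#' (`slope = sum(pred * obs) / sum(pred^2)`; a slope of 1 indicates
#' unbiased prediction).
#'
#' @param records fit-ready records (>= 3).
#' @param candidate_terms candidate terms.
#' @param procedure `"full"` reruns enumeration + selection per fold;
#'   `"top"` refits the structures selected on the full data.
#' @param cutoff delta-AICc cutoff.
#' @return A `cv_result` list: `mape`, `slope`, `r2`, and the per-record
#'   prediction table.
#' @export
loo_cv <- function(records, candidate_terms = es_candidate_terms(),
                   procedure = c("full", "top"), cutoff = 2) {
  procedure <- match.arg(procedure)
  n <- nrow(records)
  if (n < 3L) stop("leave-one-out needs at least 3 records", call. = FALSE)
  full_top <- if (procedure == "top") {
    select_top(enumerate_models(records, candidate_terms), cutoff)
  }
  pred <- numeric(n)
  for (i in seq_len(n)) {
    train <- records[-i, , drop = FALSE]
    set_i <- if (procedure == "full") {
      select_top(enumerate_models(train, candidate_terms), cutoff)
    } else {
      model_set_from_models(
        lapply(full_top$terms_list, function(tt) fit_mixed_model(train, tt))
      )
    }
    pred[i] <- average_predict(set_i, records[i, , drop = FALSE])
  }
  obs <- records$log_value
  result <- list(
    mape = mean(abs(pred - obs) / abs(obs)),
    slope = through_origin_slope(pred, obs),
    r2 = summary(stats::lm(obs ~ 0 + pred))$r.squared,
    predictions = data.frame(record = seq_len(n), observed = obs, predicted = pred)
  )
  class(result) <- "cv_result"
  result
}

#' Through-origin regression slope of observed on predicted
#'
#' `sum(pred * obs) / sum(pred^2)`: the least-squares slope of a
#' no-intercept regression of observations on predictions. A slope of 1
#' indicates unbiased prediction.
#'
#' @param pred predicted values.
#' @param obs observed values.
#' @return The slope.
#' @export
through_origin_slope <- function(pred, obs) {
  sum(pred * obs) / sum(pred^2)
}

#' Direct benefit-transfer baseline
#'
#' Leave-one-out prediction of each record by the mean log value of the
#' remaining records in its stratum: ES class at the global level, ES
#' class crossed with region at the regional level. An empty stratum
#' falls back to the global leave-one-out mean, flagged per record.
#'
#' @param records fit-ready records; the regional level requires a
#'   `region` column.
#' @param level `"global"` or `"regional"`.
#' @return A `cv_result` list with `mape`, the prediction table, and a
#'   `fallback` flag per record.
#' @export
direct_benefit_transfer <- function(records, level = c("global", "regional")) {
  level <- match.arg(level)
  obs <- records$log_value
  n <- length(obs)
  strata <- if (level == "global") {
    records$es_class
  } else {
    if (!"region" %in% names(records)) {
      stop("regional transfer needs a region column", call. = FALSE)
    }
    paste(records$es_class, records$region, sep = ":")
  }
  pred <- numeric(n)
  fallback <- logical(n)
  tot <- tapply(obs, strata, sum)
  cnt <- tapply(obs, strata, length)
  for (i in seq_len(n)) {
    s <- strata[i]
    if (cnt[[s]] > 1L) {
      pred[i] <- (tot[[s]] - obs[i]) / (cnt[[s]] - 1L)
    } else {
      pred[i] <- (sum(obs) - obs[i]) / (n - 1L)
      fallback[i] <- TRUE
    }
  }
  result <- list(
    mape = mean(abs(pred - obs) / abs(obs)),
    predictions = data.frame(
      record = seq_len(n), observed = obs, predicted = pred,
      fallback = fallback
    ),
    level = level
  )
  class(result) <- "cv_result"
  result
}

#' Collinearity, heteroscedasticity and spatial-independence diagnostics
#'
#' Variance inflation factors are computed on the fixed-effects linear
#' analogue of the mixed model; the Breusch-Pagan test is run on the
#' analogue with country as a fixed effect; an empirical semivariogram
#' of the analogue's residuals over binned inter-point distances, with
#' the slope of semivariance against distance, checks for spatial
#' structure (slope indistinguishable from 0 means none).
#'
#' @param records fit-ready records with `x`, `y` coordinates.
#' @param terms fixed-effect terms to diagnose.
#' @param n_bins number of distance bins for the semivariogram.
#' @return A list: `vif` (named; `Inf` entries name perfectly collinear
#'   columns), `bp_pvalue`, `semivariogram` (binned table), and the
#'   fitted `slope` with its standard error.
#' @export
diagnostics <- function(records, terms, n_bins = 10L) {
  d <- prepare_model_frame(records)
  f_main <- stats::reformulate(terms, response = "log_value")
  fit_main <- stats::lm(f_main, data = d)
  al <- stats::alias(fit_main)
  if (!is.null(al$Complete)) {
    aliased <- rownames(al$Complete)
    vif <- stats::setNames(rep(Inf, length(aliased)), aliased)
    attr(vif, "collinear_with") <- colnames(al$Complete)
  } else if (length(terms) >= 2L) {
    v <- car::vif(fit_main)
    vif <- if (is.matrix(v)) stats::setNames(v[, 1], rownames(v)) else v
  } else {
    vif <- stats::setNames(rep(1, length(terms)), terms)
  }
  f_bp <- stats::reformulate(c(terms, "country"), response = "log_value")
  bp <- lmtest::bptest(stats::lm(f_bp, data = d))
  resid <- stats::residuals(fit_main)
  dx <- stats::dist(cbind(records$x, records$y))
  dg <- stats::dist(cbind(resid))^2 / 2
  dxv <- as.vector(dx)
  dgv <- as.vector(dg)
  use <- dxv <= max(dxv) / 2 # short-range half, as is conventional
  bins <- cut(dxv[use], breaks = n_bins)
  sv <- data.frame(
    dist = tapply(dxv[use], bins, mean),
    gamma = tapply(dgv[use], bins, mean),
    n = as.integer(table(bins))
  )
  sv <- sv[sv$n > 0, , drop = FALSE]
  svfit <- stats::lm(gamma ~ dist, data = sv, weights = sv$n)
  list(
    vif = vif,
    bp_pvalue = unname(bp$p.value),
    semivariogram = sv,
    slope = unname(stats::coef(svfit)[["dist"]]),
    slope_se = summary(svfit)$coefficients["dist", "Std. Error"]
  )
}
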