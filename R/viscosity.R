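#' Microviscosity model parameters
#'
#' Bundles the Perrin-relation constants with the linear
#' composition-to-viscosity regression model. The steady-state Perrin
#' relation for a membrane-anchored probe (TMA-DPH) is used in its
#' hyperbolic form eta = C * r / (r0 - r), where `r0` is the limiting
#' anisotropy of the probe and `C` a calibration constant in poise; both
#' are the classic DPH-probe conventions and are fully config-exposed.
#'
#' @param r0 limiting TMA-DPH anisotropy (default 0.362).
#' @param calib_c calibration constant, poise (default 2.4).
#' @param coefficients named numeric vector of regression weights over
#'   predictor tokens (subset of `sat_unsat_ratio`, `total_n6_lcpufa`,
#'   `pct_18_1n9`, `CHO`, `SM`), poise per predictor unit.
#' @param intercept regression intercept, poise.
#' @return a `viscosity_params` list.
#' @export
viscosity_params <- function(r0 = 0.362, calib_c = 2.4,
                             coefficients = NULL, intercept = 0) {
  stopifnot(r0 > 0, r0 < 0.4, calib_c > 0)
  allowed <- c("sat_unsat_ratio", "total_n6_lcpufa", "pct_18_1n9", "CHO", "SM")
  if (!is.null(coefficients)) {
    bad <- setdiff(names(coefficients), allowed)
    if (length(bad)) stop("unknown viscosity predictor(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(r0 = r0, calib_c = calib_c,
                 coefficients = coefficients, intercept = intercept),
            class = "viscosity_params")
}

#' Apparent microviscosity from steady-state anisotropy (Perrin relation)
#'
#' eta = C * r / (r0 - r); strictly increasing in r, 0 at r = 0 and
#' diverging as r approaches the limiting anisotropy r0.
#'
#' @param r anisotropy value(s), 0 <= r < r0.
#' @param params a [viscosity_params()].
#' @return apparent microviscosity in poise.
#' @export
perrin_viscosity <- function(r, params = viscosity_params()) {
  if (any(r < 0) || any(r >= params$r0)) {
    stop("anisotropy outside [0, r0): ",
         paste(r[r < 0 | r >= params$r0], collapse = ", "), call. = FALSE)
  }
  params$calib_c * r / (params$r0 - r)
}

#' Anisotropy from apparent microviscosity
#'
#' Exact algebraic inverse of [perrin_viscosity()]:
#' r = r0 * eta / (C + eta).
#'
#' @param eta viscosity value(s) >= 0, poise.
#' @inheritParams perrin_viscosity
#' @return anisotropy in `[0, r0)`.
#' @export
anisotropy_from_viscosity <- function(eta, params = viscosity_params()) {
  stopifnot(all(eta >= 0))
  params$r0 * eta / (params$calib_c + eta)
}

#' Predictor table for the composition-to-viscosity regression
#'
#' Derived indexes plus the raw class/species predictors the model may
#' use (`pct_18_1n9` is the oleic-acid mol%).
#'
#' @param cohort a `raft_cohort`.
#' @return data.frame of predictor columns, one row per subject.
#' @export
viscosity_predictors <- function(cohort) {
  idx <- derive_indexes(cohort)
  out <- data.frame(
    subject_id = idx$subject_id, group = idx$group,
    sat_unsat_ratio = idx$sat_unsat_ratio,
    total_n6_lcpufa = idx$total_n6_lcpufa,
    stringsAsFactors = FALSE
  )
  out$pct_18_1n9 <- if ("18:1n-9" %in% names(cohort)) cohort[["18:1n-9"]] else 0
  out$CHO <- if ("CHO" %in% names(cohort)) cohort[["CHO"]] else 0
  out$SM <- if ("SM" %in% names(cohort)) cohort[["SM"]] else 0
  out
}

#' Predict per-subject apparent microviscosity from lipid composition
#'
#' @param params a [viscosity_params()] with `coefficients` set.
#' @param cohort a `raft_cohort`.
#' @return numeric vector of eta_app, poise, named by subject.
#' @export
predict_viscosity <- function(params, cohort) {
  stopifnot(inherits(params, "viscosity_params"),
            !is.null(params$coefficients))
  pred <- viscosity_predictors(cohort)
  X <- as.matrix(pred[, names(params$coefficients), drop = FALSE])
  eta <- drop(X %*% params$coefficients) + params$intercept
  setNames(eta, pred$subject_id)
}

#' Default forward viscosity model
#'
#' Slopes encode the qualitative physics (higher saturate packing raises
#' viscosity; n-6 LCPUFA and oleic acid fluidize); the intercept is
#' solved so that, at the configured group mean compositions, the
#' NSL-to-ALS contrast equals the target percent fluidity increase
#' (default +14.8% in ALS, the study-level contrast).
#'
#' @param config a `cohort_config` defining the group mean profiles.
#' @param fluidity_target percent fluidity increase in ALS vs NSL.
#' @param slopes named slopes for the three default predictors.
#' @return a [viscosity_params()] with coefficients and intercept set.
#' @export
default_viscosity_params <- function(config = default_cohort_config(calibrate = FALSE),
                                     fluidity_target = 14.8,
                                     slopes = c(sat_unsat_ratio = 2.0,
                                                total_n6_lcpufa = -0.03,
                                                pct_18_1n9 = -0.02)) {
  # mean-profile predictor values per group
  mean_val <- function(g) {
    mp <- g$mean_profile
    fa <- mp[setdiff(names(mp), LIPID_CLASSES)]
    tot <- compute_totals(fa)
    c(sat_unsat_ratio = tot$total_saturates / tot$total_unsaturates,
      total_n6_lcpufa = tot$total_n6_lcpufa,
      pct_18_1n9 = unname(fa["18:1n-9"]))
  }
  v_nsl <- sum(slopes * mean_val(config$groups[[1]]))
  v_als <- sum(slopes * mean_val(config$groups[[2]]))
  # fluidity ratio (1/eta_ALS)/(1/eta_NSL) = 1 + target/100
  k <- 1 + fluidity_target / 100
  # eta_NSL / eta_ALS = k  =>  b0 + v_nsl = k (b0 + v_als)
  b0 <- (v_nsl - k * v_als) / (k - 1)
  viscosity_params(coefficients = slopes, intercept = b0)
}

#' Fit the composition-to-viscosity regression
#'
#' Ordinary least squares of observed eta on the configured predictor
#' set; collinear designs (condition number above `kappa_max`) are
#' rejected with the offending predictor pair named.
#'
#' @param cohort a `raft_cohort`.
#' @param eta_obs numeric vector of observed eta_app per subject (same
#'   order as `cohort`, or named by subject_id).
#' @param predictors character vector of predictor tokens.
#' @param kappa_max condition-number threshold for the scaled design.
#' @return a `viscosity_fit` list: `params` (a [viscosity_params()]),
#'   `r_squared`, `se` (per-coefficient standard errors), `fit` (the lm).
#' @export
fit_viscosity_model <- function(cohort, eta_obs,
                                predictors = c("sat_unsat_ratio",
                                               "total_n6_lcpufa",
                                               "pct_18_1n9"),
                                kappa_max = 1e8) {
  pred <- viscosity_predictors(cohort)
  if (!is.null(names(eta_obs)) && all(pred$subject_id %in% names(eta_obs))) {
    eta_obs <- eta_obs[pred$subject_id]
  }
  stopifnot(length(eta_obs) == nrow(pred))
  if (nrow(pred) < length(predictors) + 2L) {
    stop("need at least p + 2 subjects for p predictors", call. = FALSE)
  }
  X <- as.matrix(pred[, predictors, drop = FALSE])
  Xs <- scale(X)
  if (ncol(X) > 1L) {
    kap <- kappa(cbind(1, Xs), exact = TRUE)
    if (!is.finite(kap) || kap > kappa_max) {
      cc <- abs(cor(X)); diag(cc) <- 0
      worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      stop("collinear viscosity predictors: ",
           predictors[worst[1]], " and ", predictors[worst[2]],
           call. = FALSE)
    }
  }
  dat <- data.frame(eta = as.numeric(eta_obs), X, check.names = FALSE)
  fml <- stats::as.formula(paste("eta ~",
                                 paste(sprintf("`%s`", predictors),
                                       collapse = " + ")))
  fit <- lm(fml, data = dat)
  sm <- summary(fit)
  coefs <- coef(fit)
  params <- viscosity_params(
    coefficients = setNames(coefs[-1], predictors),
    intercept = unname(coefs[1])
  )
  structure(list(params = params, r_squared = sm$r.squared,
                 se = sm$coefficients[, "Std. Error"], fit = fit),
            class = "viscosity_fit")
}

#' Group microviscosity comparison
#'
#' Percent fluidity change is computed on the reciprocal scale,
#' 100 * (mean(1/eta_ALS) / mean(1/eta_NSL) - 1): a viscosity decrease
#' in ALS is reported as a fluidity increase. Cohen's d follows the
#' pipeline sign convention (NSL minus ALS).
#'
#' @param cohort a `raft_cohort`.
#' @param eta per-subject eta_app (named by subject_id or cohort order);
#'   if NULL, predicted from `params`.
#' @param params a [viscosity_params()] used when `eta` is NULL.
#' @return list `eta` (per subject), `group_means`,
#'   `pct_fluidity_change`, `cohens_d`, `p_value` (Mann-Whitney).
#' @export
compare_group_viscosity <- function(cohort, eta = NULL,
                                    params = default_viscosity_params()) {
  if (is.null(eta)) eta <- predict_viscosity(params, cohort)
  if (!is.null(names(eta)) && all(cohort$subject_id %in% names(eta))) {
    eta <- eta[cohort$subject_id]
  }
  stopifnot(length(eta) == nrow(cohort))
  if (any(eta <= 0)) stop("non-positive viscosity value(s)", call. = FALSE)
  g <- cohort$group
  eta_nsl <- eta[g == "NSL"]
  eta_als <- eta[g == "ALS"]
  d <- cohens_d(eta_nsl, eta_als)
  mw <- mann_whitney(eta_nsl, eta_als)
  list(
    eta = setNames(as.numeric(eta), cohort$subject_id),
    group_means = c(NSL = mean(eta_nsl), ALS = mean(eta_als)),
    pct_fluidity_change = 100 * (mean(1 / eta_als) / mean(1 / eta_nsl) - 1),
    cohens_d = d$d,
    p_value = mw$p_value
  )
}
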