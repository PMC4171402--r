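#' Fit baseline-predictor bridge regressions
#'
#' Imputation of the unobserved counterfactual biomarker leans on baseline
#' covariates that predict it: `g(E[S0 | U]) = gamma0 + gamma1' U` is fit
#' exclusively on control-arm subjects (where `s0` is observed) and
#' `g(E[S1 | V]) = beta0 + beta1' V` exclusively on treated subjects.
#' Validity of the cross-arm transport rests on randomization making
#' `(S0, S1)` independent of `Z` given `(U, V)`. The baseline-irrelevant
#' vaccination strategy is this operation with `V` set to the immune
#' response to an unrelated vaccine administered at baseline, a proxy for
#' overall immune responsiveness.
#'
#' @param trial An [observed_trial] whose biomarker column may be
#'   continuous (bridge models are usually fit before discretization).
#' @param u_cols Character vector of covariate columns predicting `s0`
#'   (`NULL` to skip the control-side model).
#' @param v_cols Covariate columns predicting `s1` (`NULL` to skip).
#' @param link `"identity"` (Gaussian least squares) or
#'   `"logit-on-scaled"` (quasibinomial on the biomarker rescaled to
#'   (0, 1) by the support range — for markers bounded on their support).
#' @param support Required for the logit link (supplies the range).
#' @return A `bridge_models` list: `gamma`, `beta` (coefficient vectors),
#'   `fit0`, `fit1` (model objects), `diagnostics` (R-squared / deviance
#'   and arm sizes), `link`, `u_cols`, `v_cols`.
#' @export
fit_bridge_models <- function(trial, u_cols = NULL, v_cols = NULL,
                              link = c("identity", "logit-on-scaled"),
                              support = NULL) {
  stopifnot(inherits(trial, "observed_trial"))
  link <- match.arg(link)
  if (is.null(u_cols) && is.null(v_cols))
    stop("at least one of `u_cols`, `v_cols` must be supplied", call. = FALSE)

  fit_side <- function(arm, cols) {
    d <- trial[trial$z == arm & !is.na(trial$s), , drop = FALSE]
    missing_cols <- setdiff(cols, names(d))
    if (length(missing_cols))
      stop("covariate column(s) not found: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    d <- d[stats::complete.cases(d[cols]), , drop = FALSE]
    if (nrow(d) < length(cols) + 2)
      stop("arm ", arm, " has too few subjects (", nrow(d),
           ") to fit ", length(cols) + 1, " coefficients", call. = FALSE)
    X <- as.matrix(d[cols])
    if (qr(cbind(1, X))$rank < ncol(X) + 1) {
      degenerate <- cols[apply(X, 2, function(x) stats::var(x) == 0)]
      stop("collinear or constant covariate(s)",
           if (length(degenerate)) paste0(": ", paste(degenerate, collapse = ", ")),
           call. = FALSE)
    }
    fml <- stats::reformulate(cols, response = "s")
    if (link == "identity") {
      fit <- stats::lm(fml, data = d)
      # summary.lm warns on an exactly collinear (perfect-predictor) fit;
      # R^2 = 1 is a legitimate diagnostic value here
      r2 <- suppressWarnings(summary(fit)$r.squared)
      list(fit = fit, coef = stats::coef(fit),
           diag = c(r_squared = r2, n = nrow(d)))
    } else {
      if (is.null(support))
        stop("`support` is required for the logit-on-scaled link",
             call. = FALSE)
      rng <- range(support$levels)
      d$.s_scaled <- (d$s - rng[1]) / diff(rng)
      d$.s_scaled <- pmin(pmax(d$.s_scaled, 1e-6), 1 - 1e-6)
      fit <- stats::glm(stats::reformulate(cols, response = ".s_scaled"),
                        data = d, family = stats::quasibinomial())
      if (!fit$converged)
        stop("bridge model did not converge under the logit link",
             call. = FALSE)
      list(fit = fit, coef = stats::coef(fit),
           diag = c(deviance = stats::deviance(fit), n = nrow(d)))
    }
  }
  side0 <- if (!is.null(u_cols)) fit_side(0, u_cols) else NULL
  side1 <- if (!is.null(v_cols)) fit_side(1, v_cols) else NULL
  structure(list(gamma = side0$coef, beta = side1$coef,
                 fit0 = side0$fit, fit1 = side1$fit,
                 diagnostics = list(gamma = side0$diag, beta = side1$diag),
                 link = link, u_cols = u_cols, v_cols = v_cols),
            class = "bridge_models")
}

#' Impute counterfactual biomarkers from bridge models
#'
#' Completes the trial table: treated rows gain an imputed `s0` from the
#' control-side model, control rows an imputed `s1` from the treated-side
#' model; each row's own-arm biomarker is its observed value. Mean mode
#' uses the fitted value; stochastic mode adds a Gaussian residual draw
#' (seeded) to propagate imputation uncertainty into a bootstrap. Imputed
#' values are re-binned to the support so the per-stratum machinery
#' applies unchanged. Rows with missing required covariates are excluded
#' and listed in the `excluded_rows` attribute.
#'
#' @param trial An [observed_trial].
#' @param models A `bridge_models` object.
#' @param mode `"mean"` or `"stochastic"`.
#' @param seed RNG seed for stochastic mode.
#' @param support Optional [biomarker_support] for re-binning; when absent
#'   imputed values are left on the model's continuous scale.
#' @param c_value Optional constant control biomarker level: when the
#'   constant-control assumption is asserted no control-side model is
#'   needed and treated rows take `s0 = c_value` (the baseline-irrelevant
#'   vaccination setting).
#' @return A data.frame of class `completed_trial` with columns `z`, `y`,
#'   `s0`, `s1`, `s0_imputed`, `s1_imputed`, plus the original covariates.
#' @export
impute_counterfactual_biomarkers <- function(trial, models,
                                             mode = c("mean", "stochastic"),
                                             seed = 1L, support = NULL,
                                             c_value = NULL) {
  stopifnot(inherits(trial, "observed_trial"),
            inherits(models, "bridge_models"))
  mode <- match.arg(mode)
  if (mode == "stochastic") set.seed(seed)
  d <- as.data.frame(trial)
  need <- c(if (!is.null(models$u_cols)) models$u_cols,
            if (!is.null(models$v_cols)) models$v_cols)
  bad <- !stats::complete.cases(d[need])
  excluded <- which(bad)
  d <- d[!bad, , drop = FALSE]

  predict_marker <- function(fit, newdata) {
    if (models$link == "identity") {
      mu <- stats::predict(fit, newdata = newdata)
      if (mode == "stochastic")
        mu <- mu + stats::rnorm(length(mu), 0, stats::sigma(fit))
      mu
    } else {
      mu <- stats::predict(fit, newdata = newdata, type = "response")
      rng <- range(support$levels)
      mu * diff(rng) + rng[1]
    }
  }
  s0 <- ifelse(d$z == 0, d$s, NA_real_)
  s1 <- ifelse(d$z == 1, d$s, NA_real_)
  s0_imputed <- d$z == 1
  s1_imputed <- d$z == 0
  if (any(s0_imputed)) {
    if (!is.null(models$fit0)) {
      s0[s0_imputed] <- predict_marker(models$fit0, d[s0_imputed, , drop = FALSE])
    } else if (!is.null(c_value)) {
      s0[s0_imputed] <- c_value
    } else {
      stop("no control-side bridge model available to impute s0 ",
           "(supply `u_cols` when fitting, or assert a constant control ",
           "biomarker via `c_value`)", call. = FALSE)
    }
  }
  if (any(s1_imputed)) {
    if (is.null(models$fit1))
      stop("no treated-side bridge model available to impute s1", call. = FALSE)
    s1[s1_imputed] <- predict_marker(models$fit1, d[s1_imputed, , drop = FALSE])
  }
  if (!is.null(support)) {
    s0[s0_imputed] <- bin_values(s0[s0_imputed], support)
    s1[s1_imputed] <- bin_values(s1[s1_imputed], support)
  }
  out <- data.frame(z = d$z, y = d$y, s0 = s0, s1 = s1,
                    s0_imputed = s0_imputed, s1_imputed = s1_imputed)
  cov_cols <- setdiff(names(d), canonical_cols)
  if (length(cov_cols)) out <- cbind(out, d[cov_cols])
  structure(out, excluded_rows = excluded, mode = mode,
            class = c("completed_trial", "data.frame"))
}

#' Fit the observed risk model on a completed table
#'
#' With each row carrying observed and imputed biomarker values the
#' two-arm risk model
#' `g(R_z) = alpha0 + alpha1 z + alpha2 theta(s0, s1) + alpha3 z theta(s0, s1)`
#' is fit by maximum likelihood, where `theta` is a pre-declared scalar
#' summary of the stratum (default `s1 - s0`, which reduces to `s1` under
#' a constant control biomarker at 0). `alpha3` measures how the
#' treatment effect varies with the biomarker contrast — the quantity a
#' surrogate evaluation is after.
#'
#' @param completed A `completed_trial` (or any data.frame with `z`, `y`,
#'   `s0`, `s1`).
#' @param theta_spec A function of `(s0, s1)` (default `s1 - s0`), or one
#'   of the strings `"diff"`, `"s1"`.
#' @param link `"logit"` (binomial ML) or `"identity"` (linear
#'   probability, with a range warning).
#' @return A `risk_model_fit` list: `alpha` (named coefficients alpha0 to
#'   alpha3), `theta_name`, `link`, `fit`, `converged`, and `surface`
#'   (the model-induced `estimand_surface` over observed strata).
#' @export
fit_risk_model <- function(completed, theta_spec = "diff",
                           link = c("logit", "identity")) {
  link <- match.arg(link)
  req <- c("z", "y", "s0", "s1")
  if (!all(req %in% names(completed)))
    stop("completed table must have columns z, y, s0, s1", call. = FALSE)
  theta_name <- if (is.character(theta_spec)) theta_spec else "custom"
  theta <- if (is.function(theta_spec)) theta_spec
           else switch(theta_spec,
                       diff = function(s0, s1) s1 - s0,
                       s1 = function(s0, s1) s1,
                       stop("unknown theta_spec: ", theta_spec, call. = FALSE))
  d <- data.frame(z = completed$z, y = completed$y,
                  th = theta(completed$s0, completed$s1))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (stats::var(d$th) == 0)
    stop("collinearity: theta(s0, s1) is constant on the data", call. = FALSE)
  fam <- if (link == "logit") stats::binomial() else stats::gaussian()
  fit <- stats::glm(y ~ z * th, data = d, family = fam)
  if (!fit$converged)
    stop("risk model did not converge (", fit$iter, " iterations)",
         call. = FALSE)
  alpha <- stats::coef(fit)
  names(alpha) <- c("alpha0", "alpha1", "alpha2", "alpha3")
  if (anyNA(alpha)) stop("risk model is rank deficient", call. = FALSE)

  pairs <- data.frame(s0 = completed$s0, s1 = completed$s1)
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  strata <- unique(pairs)
  key <- paste(pairs$s0, pairs$s1)
  counts <- table(key)[paste(strata$s0, strata$s1)]
  th_s <- theta(strata$s0, strata$s1)
  linkinv <- fam$linkinv
  r0 <- linkinv(alpha[1] + alpha[3] * th_s)
  r1 <- linkinv(alpha[1] + alpha[2] + (alpha[3] + alpha[4]) * th_s)
  if (link == "identity" && (any(r0 < 0 | r0 > 1) || any(r1 < 0 | r1 > 1)))
    warning("identity-link risk model predicts outside [0, 1]; ",
            "predicted risks are truncated on the surface")
  surf <- new_surface(s0 = strata$s0, s1 = strata$s1,
                      r0 = pmin(pmax(r0, 0), 1), r1 = pmin(pmax(r1, 0), 1),
                      n = as.vector(counts),
                      conditioning = "sa1", provenance = "estimated")
  structure(list(alpha = alpha, theta_name = theta_name, link = link,
                 fit = fit, converged = fit$converged, surface = surf),
            class = "risk_model_fit")
}
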