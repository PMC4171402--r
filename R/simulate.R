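#' Configure a counterfactual trial simulation
#'
#' The simulator is the only source of *joint* counterfactual truth in this
#' package: a parallel-arm trial never reveals both biomarker values or
#' both outcomes on the same subject, so every estimator is validated
#' against simulated tables where the full joint distribution is known and
#' the estimands have closed form.
#'
#' Two regimes for the joint biomarker distribution are supported:
#' \describe{
#'   \item{`mode = "sa2"`}{the constant-placebo-biomarker regime: `s0` is
#'     the constant `c_value` for everyone and `s1` is drawn from `s1_pmf`
#'     over the support levels. Principal strata collapse to `s1` alone.}
#'   \item{`mode = "grid"`}{a full pmf `joint_s` over the K x K grid of
#'     `(s0, s1)` pairs (rows index `s0`).}
#' }
#'
#' @param n Number of subjects.
#' @param support A [biomarker_support] (default levels `0:(k-1)`).
#' @param k Number of levels when `support` is not supplied.
#' @param mode `"sa2"` or `"grid"`.
#' @param c_value The constant placebo biomarker level under `"sa2"`.
#' @param s1_pmf Pmf of `s1` over the support levels (`"sa2"` mode).
#' @param joint_s K x K pmf matrix of `(s0, s1)` (`"grid"` mode).
#' @param risk0,risk1 Per-stratum outcome risks `P(Y_z = 1 | stratum)`: a
#'   scalar, a length-K vector indexed by `s1` level (`"sa2"`), or a K x K
#'   matrix (`"grid"`).
#' @param a_model Undefined-biomarker mechanism: a list with elements `p0`
#'   and `p1`, each a length-2 vector `c(P(a_z = 0 | y_z = 0),
#'   P(a_z = 0 | y_z = 1))`. Outcome-linked undefinedness (second entry
#'   larger) emulates clinical events occurring before the biomarker could
#'   be measured.
#' @param assign_p Randomization probability `P(Z = 1)`.
#' @param covariate_model Optional list with elements `u` and/or `v`, each
#'   `list(target = "s0"|"s1", cor = rho)`: generates a Gaussian baseline
#'   covariate with the stated correlation to the targeted potential
#'   biomarker (`cor = 1` gives the potential value itself).
#' @param closeout_delta Integer level shift applied to closeout
#'   measurements; 0 is exact time constancy.
#' @param monotone_y If `TRUE`, couple `(y0, y1)` through one shared
#'   uniform per subject so that `y1 <= y0` holds pathwise; requires
#'   `risk1 <= risk0` on every stratum.
#' @param seed Default RNG seed for [simulate_counterfactual_trial].
#' @param tau Measurement-time metadata.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n, support = NULL, k = 5,
                       mode = c("sa2", "grid"), c_value = 0,
                       s1_pmf = NULL, joint_s = NULL,
                       risk0, risk1,
                       a_model = list(p0 = c(0, 0), p1 = c(0, 0)),
                       assign_p = 0.5, covariate_model = NULL,
                       closeout_delta = 0, monotone_y = FALSE,
                       seed = 1L, tau = 1) {
  mode <- match.arg(mode)
  if (is.null(support)) support <- biomarker_support(0:(k - 1))
  stopifnot(inherits(support, "biomarker_support"))
  K <- support$k
  cfg_err <- function(...) stop("invalid sim_config: ", ..., call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || n < 1) cfg_err("`n` must be >= 1")

  if (mode == "sa2") {
    if (is.null(s1_pmf)) cfg_err("`s1_pmf` required in sa2 mode")
    s1_pmf <- as.numeric(s1_pmf)
    if (length(s1_pmf) != K) cfg_err("`s1_pmf` must have one mass per level")
    if (any(s1_pmf < 0) || abs(sum(s1_pmf) - 1) > 1e-12)
      cfg_err("`s1_pmf` must be a pmf summing to 1 within 1e-12")
    if (!(c_value %in% support$levels))
      cfg_err("`c_value` must be one of the support levels")
    expand <- function(r) {
      r <- as.numeric(r)
      if (length(r) == 1) rep(r, K) else if (length(r) == K) r
      else cfg_err("risk map must be scalar or length K")
    }
    risk0 <- expand(risk0); risk1 <- expand(risk1)
  } else {
    if (is.null(joint_s)) cfg_err("`joint_s` required in grid mode")
    joint_s <- as.matrix(joint_s)
    if (!all(dim(joint_s) == c(K, K))) cfg_err("`joint_s` must be K x K")
    if (any(joint_s < 0) || abs(sum(joint_s) - 1) > 1e-12)
      cfg_err("`joint_s` must be a pmf summing to 1 within 1e-12")
    expand <- function(r) {
      r <- if (length(r) == 1) matrix(as.numeric(r), K, K) else as.matrix(r)
      if (!all(dim(r) == c(K, K))) cfg_err("risk map must be scalar or K x K")
      r
    }
    risk0 <- expand(risk0); risk1 <- expand(risk1)
  }
  if (any(risk0 < 0 | risk0 > 1) || any(risk1 < 0 | risk1 > 1))
    cfg_err("risk values must lie in [0, 1]")
  if (monotone_y && any(risk1 > risk0 + 1e-9))
    cfg_err("monotone_y requires risk1 <= risk0 on every stratum")
  if (monotone_y) risk1 <- pmin(risk1, risk0)   # exact pathwise dominance
  if (!is.list(a_model) || !all(c("p0", "p1") %in% names(a_model)))
    cfg_err("`a_model` must have elements p0 and p1")
  a_model$p0 <- rep_len(as.numeric(a_model$p0), 2)
  a_model$p1 <- rep_len(as.numeric(a_model$p1), 2)
  if (any(unlist(a_model[c("p0", "p1")]) < 0) ||
      any(unlist(a_model[c("p0", "p1")]) > 1))
    cfg_err("a_model probabilities must lie in [0, 1]")
  if (assign_p <= 0 || assign_p >= 1) cfg_err("`assign_p` must be in (0, 1)")

  structure(list(n = as.integer(n), support = support, mode = mode,
                 c_value = c_value, s1_pmf = s1_pmf, joint_s = joint_s,
                 risk0 = risk0, risk1 = risk1, a_model = a_model,
                 assign_p = assign_p, covariate_model = covariate_model,
                 closeout_delta = closeout_delta, monotone_y = monotone_y,
                 seed = as.integer(seed), tau = tau),
            class = "sim_config")
}

# Per-subject risks given drawn stratum indices (1-based into levels).
risk_at <- function(config, i0, i1) {
  if (config$mode == "sa2")
    list(r0 = config$risk0[i1], r1 = config$risk1[i1])
  else
    list(r0 = config$risk0[cbind(i0, i1)], r1 = config$risk1[cbind(i0, i1)])
}

#' Simulate a counterfactual trial
#'
#' Draws the full potential-outcome table `(a0, a1, s0, s1, y0, y1)` plus
#' optional baseline covariates from a [sim_config]. With
#' `monotone_y = TRUE` the two outcomes share a single uniform draw
#' (comonotone coupling), so the individual-level monotonicity
#' `P(y1 <= y0) = 1` holds pathwise, not merely in distribution.
#' Identical `(config, seed)` pairs give identical tables.
#'
#' @param config A [sim_config].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A [counterfactual_trial].
#' @export
simulate_counterfactual_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n; K <- config$support$k; lev <- config$support$levels
  if (config$mode == "sa2") {
    i1 <- sample.int(K, n, replace = TRUE, prob = config$s1_pmf)
    i0 <- rep(match(config$c_value, lev), n)
  } else {
    cell <- sample.int(K * K, n, replace = TRUE, prob = as.vector(config$joint_s))
    i0 <- ((cell - 1L) %% K) + 1L          # row index (s0)
    i1 <- ((cell - 1L) %/% K) + 1L         # col index (s1)
  }
  rr <- risk_at(config, i0, i1)
  if (config$monotone_y) {
    u <- stats::runif(n)
    y1 <- as.integer(u < rr$r1)
    y0 <- as.integer(u < rr$r0)
  } else {
    y0 <- stats::rbinom(n, 1, rr$r0)
    y1 <- stats::rbinom(n, 1, rr$r1)
  }
  a0 <- 1L - stats::rbinom(n, 1, config$a_model$p0[y0 + 1L])
  a1 <- 1L - stats::rbinom(n, 1, config$a_model$p1[y1 + 1L])
  s0 <- lev[i0]; s1 <- lev[i1]
  s0[a0 == 0L] <- NA; s1[a1 == 0L] <- NA

  covariates <- NULL
  cm <- config$covariate_model
  if (!is.null(cm)) {
    gen <- function(spec, s_target) {
      rho <- spec$cor
      sdt <- stats::sd(s_target)
      noise_sd <- if (rho >= 1 || !is.finite(sdt) || sdt == 0) 0
                  else sdt * sqrt(1 / rho^2 - 1)
      s_target + stats::rnorm(length(s_target), 0, noise_sd)
    }
    full0 <- lev[i0]; full1 <- lev[i1]   # covariates are baseline: use latent values
    covariates <- data.frame(row.names = seq_len(n))
    if (!is.null(cm$u))
      covariates$u <- gen(cm$u, if (identical(cm$u$target, "s1")) full1 else full0)
    if (!is.null(cm$v))
      covariates$v <- gen(cm$v, if (identical(cm$v$target, "s0")) full0 else full1)
  }
  counterfactual_trial(s0 = s0, s1 = s1, y0 = y0, y1 = y1, a0 = a0, a1 = a1,
                       covariates = covariates, tau = config$tau,
                       support = config$support)
}

#' Mask a counterfactual trial into an observed one
#'
#' Realizes randomization and consistency: each subject is assigned
#' `z ~ Bernoulli(assign_p)` independently of all potential outcomes, and
#' the observed `(a_tau, s, y)` equal the potential values under the
#' assigned arm. The parent counterfactual table is retained as an
#' attribute so oracle comparisons remain possible.
#'
#' @param trial A [counterfactual_trial].
#' @param assign_p Randomization probability `P(Z = 1)`.
#' @param seed RNG seed.
#' @return An [observed_trial] with attribute `counterfactual`.
#' @export
mask_to_observed <- function(trial, assign_p = 0.5, seed = 1L) {
  stopifnot(inherits(trial, "counterfactual_trial"))
  set.seed(seed)
  n <- nrow(trial)
  z <- stats::rbinom(n, 1, assign_p)
  s <- ifelse(z == 1L, trial$s1, trial$s0)
  y <- ifelse(z == 1L, trial$y1, trial$y0)
  a <- ifelse(z == 1L, trial$a1, trial$a0)
  cov_cols <- setdiff(names(trial), c("subject_id", "a0", "a1",
                                      "s0", "s1", "y0", "y1"))
  covariates <- if (length(cov_cols)) as.data.frame(trial)[cov_cols] else NULL
  obs <- observed_trial(z = z, s = s, y = y, a_tau = a,
                        covariates = covariates,
                        subject_id = trial$subject_id,
                        tau = attr(trial, "tau"),
                        support = attr(trial, "support"))
  attr(obs, "counterfactual") <- trial
  obs
}

#' Add closeout biomarker measurements to an observed trial
#'
#' Emulates the closeout design: placebo subjects who remained event-free
#' (`z = 0`, `y = 0`) receive the active treatment at study end and have
#' their biomarker measured. Under exact time constancy
#' (`closeout_delta = 0`) the measurement reproduces the subject's `s1`
#' exactly; a nonzero `closeout_delta` shifts the value by that many
#' support levels (end levels absorbing), emulating a drift in the
#' biomarker-generating process over the study.
#'
#' @param trial The parent [counterfactual_trial].
#' @param observed The [observed_trial] derived from it.
#' @param config The [sim_config] (supplies `closeout_delta` and support).
#' @return `observed` with its `closeout_s` column filled; attribute
#'   `closeout_empty` is `TRUE` (with a warning) when no subject is
#'   eligible.
#' @export
simulate_closeout <- function(trial, observed, config) {
  stopifnot(inherits(trial, "counterfactual_trial"),
            inherits(observed, "observed_trial"),
            inherits(config, "sim_config"))
  lev <- config$support$levels; K <- config$support$k
  elig <- observed$z == 0L & observed$y == 0L
  closeout <- rep(NA_real_, nrow(observed))
  if (!any(elig)) {
    warning("no z = 0, y = 0 subjects: closeout set is empty")
    attr(observed, "closeout_empty") <- TRUE
  } else {
    s1 <- trial$s1[elig]
    ok <- !is.na(s1)
    idx <- match(s1[ok], lev)
    idx <- pmin(pmax(idx + round(config$closeout_delta), 1L), K)
    val <- rep(NA_real_, sum(elig)); val[ok] <- lev[idx]
    closeout[elig] <- val
    attr(observed, "closeout_empty") <- FALSE
  }
  observed$closeout_s <- closeout
  observed
}

#' Closed-form estimand truth for a simulation configuration
#'
#' Evaluates the per-stratum risks `R0` and `R1` directly on the
#' generating model, restricted to strata with positive probability.
#' When the undefined-biomarker mechanism is active the risks are
#' conditioned on the biomarker being defined under both assignments
#' (`A0 = A1 = 1`) by exact enumeration over the joint outcome
#' distribution implied by the coupling.
#'
#' @param config A [sim_config].
#' @return An `estimand_surface` (see [oracle_risks]) with provenance
#'   `"truth"`.
#' @export
true_estimands <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lev <- config$support$levels; K <- config$support$k
  if (config$mode == "sa2") {
    keep <- which(config$s1_pmf > 0)
    s0 <- rep(config$c_value, length(keep)); s1 <- lev[keep]
    r0 <- config$risk0[keep]; r1 <- config$risk1[keep]
    pr <- config$s1_pmf[keep]
  } else {
    keep <- which(config$joint_s > 0, arr.ind = TRUE)
    s0 <- lev[keep[, 1]]; s1 <- lev[keep[, 2]]
    r0 <- config$risk0[keep]; r1 <- config$risk1[keep]
    pr <- config$joint_s[keep]
  }
  p0u <- config$a_model$p0; p1u <- config$a_model$p1
  if (any(c(p0u, p1u) > 0)) {
    cond <- t(vapply(seq_along(r0), function(j) {
      joint <- joint_y_dist(r0[j], r1[j], config$monotone_y)
      w <- (1 - p0u[joint$y0 + 1L]) * (1 - p1u[joint$y1 + 1L])
      tot <- sum(joint$p * w)
      c(sum(joint$p * w * joint$y0) / tot, sum(joint$p * w * joint$y1) / tot)
    }, numeric(2)))
    r0 <- cond[, 1]; r1 <- cond[, 2]
  }
  new_surface(s0 = s0, s1 = s1, r0 = r0, r1 = r1, n = pr * config$n,
              conditioning = if (any(c(p0u, p1u) > 0)) "general_A11" else "sa1",
              provenance = "truth")
}

# Joint distribution of (y0, y1) within a stratum under the configured
# coupling: comonotone when monotone (requires r1 <= r0), else independent.
joint_y_dist <- function(r0, r1, monotone) {
  if (monotone) {
    data.frame(y0 = c(1L, 1L, 0L), y1 = c(1L, 0L, 0L),
               p = c(r1, r0 - r1, 1 - r0))
  } else {
    data.frame(y0 = c(1L, 1L, 0L, 0L), y1 = c(1L, 0L, 1L, 0L),
               p = c(r0 * r1, r0 * (1 - r1), (1 - r0) * r1,
                     (1 - r0) * (1 - r1)))
  }
}

#' Read a simulation configuration from JSON
#'
#' JSON fields mirror the arguments of [sim_config]; `levels` (or `k`)
#' describe the support. Used by the command-line interface.
#'
#' @param path JSON file path.
#' @param n,seed Optional overrides.
#' @return A [sim_config].
#' @export
read_sim_config <- function(path, n = NULL, seed = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  support <- if (!is.null(x$levels)) biomarker_support(x$levels) else NULL
  sim_config(n = if (!is.null(n)) n else x$n,
             support = support, k = if (!is.null(x$k)) x$k else 5,
             mode = if (!is.null(x$mode)) x$mode else "sa2",
             c_value = if (!is.null(x$c_value)) x$c_value else 0,
             s1_pmf = x$s1_pmf,
             joint_s = if (!is.null(x$joint_s)) matrix(unlist(x$joint_s),
                                                       nrow = sqrt(length(unlist(x$joint_s))),
                                                       byrow = TRUE) else NULL,
             risk0 = x$risk0, risk1 = x$risk1,
             a_model = if (!is.null(x$a_model)) x$a_model
                       else list(p0 = c(0, 0), p1 = c(0, 0)),
             assign_p = if (!is.null(x$assign_p)) x$assign_p else 0.5,
             covariate_model = x$covariate_model,
             closeout_delta = if (!is.null(x$closeout_delta)) x$closeout_delta else 0,
             monotone_y = isTRUE(x$monotone_y),
             seed = if (!is.null(seed)) seed else if (!is.null(x$seed)) x$seed else 1L,
             tau = if (!is.null(x$tau)) x$tau else 1)
}
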