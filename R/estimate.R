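#' Marginal outcome risks per arm
#'
#' Under randomization and consistency, `P(Y1 = 1)` and `P(Y0 = 1)` are
#' identified as the sample means of `y` within the treated and control
#' arms.
#'
#' @param trial An [observed_trial].
#' @return A list with `p1`, `p0`, and per-arm counts `n1`, `n0`,
#'   `events1`, `events0`.
#' @export
estimate_marginal_risks <- function(trial) {
  stopifnot(inherits(trial, "observed_trial"))
  for (arm in c(0, 1))
    if (!any(trial$z == arm))
      stop("arm ", arm, " is empty: marginal risk not estimable", call. = FALSE)
  y0 <- trial$y[trial$z == 0]; y1 <- trial$y[trial$z == 1]
  list(p1 = mean(y1), p0 = mean(y0),
       n1 = length(y1), n0 = length(y0),
       events1 = sum(y1), events0 = sum(y0))
}

# Shared preprocessing for estimators that assert the all-defined
# biomarker assumption: check the undefined fraction against the cap and
# discard undefined-biomarker subjects (with a loud warning) when any are
# present. Returns the retained trial.
apply_sa1 <- function(trial, sa1_cap = 0.05) {
  frac <- mean(trial$a_tau == 0)
  if (frac > sa1_cap)
    stop(sprintf(paste0("undefined-biomarker fraction %.3f exceeds the cap ",
                        "%.3f: the all-defined assumption is untenable"),
                 frac, sa1_cap), call. = FALSE)
  if (frac > 0) {
    warning(sprintf(paste0("discarding %d subjects (%.1f%%) with undefined ",
                           "biomarker and proceeding as if the biomarker ",
                           "were defined on everyone"),
                    sum(trial$a_tau == 0), 100 * frac))
    trial <- trial[trial$a_tau == 1, , drop = FALSE]
  }
  trial
}

# Empirical pmf of observed s over the support levels.
empirical_pmf <- function(s, support) {
  tab <- tabulate(match(s, support$levels), nbins = support$k)
  if (sum(tab) == 0) return(rep(0, support$k))
  tab / sum(tab)
}

#' Treatment-arm risk curve under the identifying assumptions
#'
#' When the biomarker is defined on everyone and is constant (`c_value`)
#' under control, principal strata collapse to `s1` alone and the treated
#' risk curve `R1(s1)` is nonparametrically identified from the treated
#' arm: `R1(s1) = f(s1 | Y1 = 1) P(Y1 = 1) / f(s1)` with every factor an
#' empirical quantity over treated subjects. Algebraically this equals the
#' per-stratum event proportion among treated subjects; both routes are
#' computed and their agreement (to 1e-12) is enforced internally.
#'
#' @param trial An [observed_trial].
#' @param support A [biomarker_support] for `s1`.
#' @param c_value The asserted constant control-arm biomarker level.
#' @param sa1_cap Maximum tolerated undefined-biomarker fraction; subjects
#'   above zero but below the cap are discarded with a warning.
#' @return An `estimand_surface` carrying `r1` per `s1` stratum (the
#'   non-identified `r0` is `NA`), with attributes `f_s1` (empirical pmf
#'   of `s1` in the treated arm), `p_y1`, and `retained_trial` row count.
#' @export
estimate_r1_under_sa2 <- function(trial, support, c_value = 0,
                                  sa1_cap = 0.05) {
  stopifnot(inherits(trial, "observed_trial"),
            inherits(support, "biomarker_support"))
  trial <- apply_sa1(trial, sa1_cap)
  d <- trial[trial$z == 1, , drop = FALSE]
  if (nrow(d) == 0) stop("treated arm is empty", call. = FALSE)
  f_s1 <- empirical_pmf(d$s, support)
  p_y1 <- mean(d$y)
  if (p_y1 == 0) warning("no events in the treated arm: r1 is identically 0")
  f_s1_y1 <- if (p_y1 > 0) empirical_pmf(d$s[d$y == 1], support)
             else rep(0, support$k)
  occupied <- f_s1 > 0
  r1_bayes <- rep(NA_real_, support$k)
  r1_bayes[occupied] <- f_s1_y1[occupied] * p_y1 / f_s1[occupied]
  # direct route: stratum-wise event proportion
  idx <- match(d$s, support$levels)
  ev <- tabulate(idx[d$y == 1], nbins = support$k)
  tot <- tabulate(idx, nbins = support$k)
  r1_direct <- ifelse(tot > 0, ev / pmax(tot, 1), NA_real_)
  if (max(abs(r1_bayes[occupied] - r1_direct[occupied])) > 1e-12)
    stop("internal error: Bayes-form and direct r1 computations disagree")
  surf <- new_surface(s0 = rep(c_value, sum(occupied)),
                      s1 = support$levels[occupied],
                      r0 = NA_real_, r1 = r1_direct[occupied],
                      n = tot[occupied],
                      conditioning = "sa1_sa2", provenance = "estimated",
                      omitted_strata = support$levels[!occupied])
  attr(surf, "f_s1") <- f_s1
  attr(surf, "p_y1") <- p_y1
  attr(surf, "n_retained") <- nrow(trial)
  surf
}

#' Sensitivity analysis for the non-identified control risk curve
#'
#' Under the identifying assumptions the control risk curve
#' `R0(s1) = f(s1 | Y0 = 1) P(Y0 = 1) / f(s1)` still depends on
#' `f(s1 | Y0 = 1)`, the biomarker distribution that control-arm cases
#' *would* have shown under treatment, which no parallel-arm design
#' reveals. This function indexes that unknown by a one-parameter
#' exponential tilt: `f_beta(s1 | Y0 = 1)` is proportional to
#' `f(s1) exp(beta * rank(s1))` with rank `0..K-1`, so `beta = 0` is "no
#' selection" (cases look like everyone) and larger `|beta|` concentrates
#' cases in high or low biomarker strata. Each `beta` induces an `r0`
#' curve and RD/RR contrasts against the identified `r1`. A `beta` is
#' *feasible* when the implied complementary distribution
#' `f(s1 | Y0 = 0)` is a valid pmf, i.e.
#' `f_beta(s1 | Y0 = 1) P(Y0 = 1) <= f(s1)` coordinate-wise (equivalently
#' the implied `r0 <= 1`).
#'
#' @param trial An [observed_trial].
#' @param support A [biomarker_support].
#' @param beta_grid Numeric vector of tilt parameters.
#' @param c_value Asserted constant control biomarker level.
#' @param sa1_cap As in [estimate_r1_under_sa2].
#' @param pmf_y0_1 Optional list of user-supplied pmfs for
#'   `f(s1 | Y0 = 1)` (scenario mode); overrides the tilt family and the
#'   `beta` column then indexes the list.
#' @return A `sensitivity_family`: long data.frame with columns `beta`,
#'   `s1`, `f_y0_1`, `r0`, `rd`, `rr`, `feasible`, and attributes `f_s1`,
#'   `p_y0`, `r1`, `support`.
#' @export
sensitivity_r0 <- function(trial, support, beta_grid = seq(-2, 2, by = 0.25),
                           c_value = 0, sa1_cap = 0.05, pmf_y0_1 = NULL) {
  stopifnot(inherits(trial, "observed_trial"))
  # P(Y0 = 1) uses the full control arm (y is observed even when s is
  # undefined) unless discarding is active, in which case the discarded
  # set is excluded from every factor for internal consistency.
  frac <- mean(trial$a_tau == 0)
  trial_r1 <- trial
  p_y0_trial <- if (frac > 0 && frac <= sa1_cap) apply_sa1(trial, sa1_cap) else trial
  r1_surf <- suppressWarnings(estimate_r1_under_sa2(trial_r1, support,
                                                    c_value, sa1_cap))
  f_s1 <- attr(r1_surf, "f_s1")
  d0 <- p_y0_trial[p_y0_trial$z == 0, , drop = FALSE]
  if (nrow(d0) == 0) stop("control arm is empty", call. = FALSE)
  p_y0 <- mean(d0$y)
  lev <- support$levels; K <- support$k
  rank_s <- seq_len(K) - 1

  families <- if (is.null(pmf_y0_1)) {
    lapply(beta_grid, function(b) {
      w <- f_s1 * exp(b * rank_s)
      w / sum(w)
    })
  } else {
    beta_grid <- seq_along(pmf_y0_1)
    lapply(pmf_y0_1, function(p) {
      p <- as.numeric(p)
      if (length(p) != K || any(p < 0) || abs(sum(p) - 1) > 1e-9)
        stop("each supplied pmf must be a length-K pmf", call. = FALSE)
      p
    })
  }
  r1_full <- rep(NA_real_, K)
  r1_full[match(r1_surf$s1, lev)] <- r1_surf$r1

  rows <- lapply(seq_along(beta_grid), function(i) {
    fb <- families[[i]]
    r0 <- ifelse(f_s1 > 0, fb * p_y0 / f_s1, NA_real_)
    feasible <- all(fb * p_y0 <= f_s1 + 1e-12, na.rm = TRUE) &&
      all(r0 <= 1 + 1e-12, na.rm = TRUE)
    data.frame(beta = beta_grid[i], s1 = lev, f_y0_1 = fb, r0 = r0,
               rd = r1_full - r0,
               rr = ifelse(!is.na(r0) & r0 > 0, r1_full / r0, NA_real_),
               feasible = feasible)
  })
  fam <- do.call(rbind, rows)
  rownames(fam) <- NULL
  if (!any(fam$feasible))
    warning("no beta on the grid is feasible: every tilt implies an ",
            "invalid complementary distribution")
  structure(fam, f_s1 = f_s1, p_y0 = p_y0, r1 = r1_full, support = support,
            class = c("sensitivity_family", "data.frame"))
}

#' Full estimand surface from crossover data
#'
#' A crossover design with adequate washout observes both potential pairs
#' `(s0, y0)` and `(s1, y1)` on every subject, so the joint table can be
#' treated as counterfactual data and the full surface is identified. The
#' washout adequacy (no carryover) is the analyst's scientific assertion,
#' not checked here.
#'
#' @param paired A data.frame with columns `s0`, `y0`, `s1`, `y1` (one row
#'   per subject; both pairs must be recorded).
#' @return An `estimand_surface` with provenance `"estimated"`.
#' @export
estimate_from_crossover <- function(paired) {
  req <- c("s0", "y0", "s1", "y1")
  if (!all(req %in% names(paired)))
    stop("paired table must have columns s0, y0, s1, y1", call. = FALSE)
  unpaired <- !stats::complete.cases(paired[req])
  if (any(unpaired))
    stop("unpaired rows (missing a potential-outcome pair): ",
         paste(utils::head(which(unpaired), 5), collapse = ", "),
         call. = FALSE)
  cf <- counterfactual_trial(s0 = paired$s0, s1 = paired$s1,
                             y0 = paired$y0, y1 = paired$y1)
  surf <- oracle_risks(cf)
  attr(surf, "provenance") <- "estimated"
  surf
}

#' Stratified nonparametric bootstrap intervals
#'
#' Subject-level bootstrap stratified by arm (preserving the
#' randomization ratio) around any deterministic estimator that maps an
#' observed trial to a named numeric vector. Percentile intervals are
#' returned per quantity; a quantity absent (e.g. an empty stratum) in
#' more than 10% of replicates is flagged unstable.
#'
#' @param estimator `function(trial) -> named numeric vector`.
#' @param trial An [observed_trial].
#' @param b Number of bootstrap replicates (>= 100).
#' @param level Interval coverage (default 0.95).
#' @param seed RNG seed.
#' @return A data.frame with columns `quantity`, `estimate`, `lo`, `hi`,
#'   `n_missing`, `unstable`.
#' @export
bootstrap_ci <- function(estimator, trial, b = 500, level = 0.95, seed = 1L) {
  stopifnot(inherits(trial, "observed_trial"), is.function(estimator))
  if (b < 100) stop("`b` must be at least 100", call. = FALSE)
  set.seed(seed)
  est <- estimator(trial)
  nms <- names(est)
  if (is.null(nms)) stop("estimator must return a *named* numeric vector",
                         call. = FALSE)
  idx0 <- which(trial$z == 0); idx1 <- which(trial$z == 1)
  n0 <- length(idx0); n1 <- length(idx1)
  reps <- matrix(NA_real_, nrow = b, ncol = length(nms),
                 dimnames = list(NULL, nms))
  cols <- lapply(as.data.frame(trial), identity)
  keep_attrs <- attributes(trial)[c("tau", "support")]
  for (i in seq_len(b)) {
    samp <- c(idx0[sample.int(n0, n0, replace = TRUE)],
              idx1[sample.int(n1, n1, replace = TRUE)])
    # resample columns directly: row-subsetting a data.frame with
    # duplicated indices is quadratic in n through row-name mangling
    boot_trial <- lapply(cols, `[`, samp)
    attributes(boot_trial) <- c(list(names = names(cols),
                                     row.names = seq_along(samp),
                                     class = c("observed_trial",
                                               "data.frame")),
                                keep_attrs)
    ri <- estimator(boot_trial)
    common <- intersect(names(ri), nms)
    reps[i, common] <- ri[common]
  }
  alpha <- (1 - level) / 2
  lo <- apply(reps, 2, stats::quantile, probs = alpha, na.rm = TRUE)
  hi <- apply(reps, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  n_missing <- colSums(is.na(reps))
  data.frame(quantity = nms, estimate = unname(est), lo = unname(lo),
             hi = unname(hi), n_missing = unname(n_missing),
             unstable = unname(n_missing > 0.1 * b), row.names = NULL)
}
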