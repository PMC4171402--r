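#' Biomarker distribution of event-free controls from closeout data
#'
#' In a closeout design, placebo subjects who remain event-free are given
#' the active treatment at study end and have their biomarker measured.
#' Under time constancy — the process generating treated biomarker values
#' has not changed over the study — that closeout measurement stands in
#' for the subject's `s1`, so the empirical distribution of closeout
#' values over `z = 0, y = 0` subjects identifies `f(s1 | Y0 = 0)`.
#'
#' @param trial An [observed_trial] with a populated `closeout_s` column.
#' @param support A [biomarker_support].
#' @return A named numeric pmf over the support levels, with attribute
#'   `n_closeout`.
#' @export
estimate_f_s1_given_y0_0 <- function(trial, support) {
  stopifnot(inherits(trial, "observed_trial"),
            inherits(support, "biomarker_support"))
  co <- trial$closeout_s[trial$z == 0 & trial$y == 0]
  co <- co[!is.na(co)]
  if (length(co) == 0)
    stop("no closeout measurements present on z = 0, y = 0 rows",
         call. = FALSE)
  pmf <- empirical_pmf(co, support)
  names(pmf) <- support$levels
  attr(pmf, "n_closeout") <- length(co)
  pmf
}

#' Recover the biomarker distribution of control-arm cases
#'
#' Applies the mixture identity
#' `f(s1 | Y0 = 1) = [f(s1) - f(s1 | Y0 = 0) P(Y0 = 0)] / P(Y0 = 1)`
#' coordinate-wise. At the population level the right-hand side is a
#' valid pmf; with estimated inputs sampling noise can drive coordinates
#' negative, in which case they are clipped to zero, the pmf is
#' renormalized, and the clipped mass is reported — never silently
#' absorbed.
#'
#' @param pmf_s1 Marginal pmf of `s1`.
#' @param pmf_y0_0 Pmf of `s1` among `Y0 = 0` subjects (same support).
#' @param p_y0 `P(Y0 = 1)`, strictly inside (0, 1).
#' @return A list with `pmf` (the recovered `f(s1 | Y0 = 1)`) and
#'   `negativity_mass` (total clipped mass, >= 0).
#' @export
recover_f_s1_given_y0_1 <- function(pmf_s1, pmf_y0_0, p_y0) {
  pmf_s1 <- as.numeric(pmf_s1); pmf_y0_0 <- as.numeric(pmf_y0_0)
  if (length(pmf_s1) != length(pmf_y0_0))
    stop("support mismatch: pmfs have different lengths", call. = FALSE)
  for (p in list(pmf_s1, pmf_y0_0))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("inputs must be valid pmfs summing to 1", call. = FALSE)
  if (p_y0 <= 0 || p_y0 >= 1)
    stop("degenerate outcome: P(Y0 = 1) must be strictly inside (0, 1)",
         call. = FALSE)
  raw <- (pmf_s1 - pmf_y0_0 * (1 - p_y0)) / p_y0
  negativity_mass <- sum(pmax(-raw, 0))
  clipped <- pmax(raw, 0)
  if (sum(clipped) == 0)
    stop("recovered distribution vanished after clipping", call. = FALSE)
  list(pmf = clipped / sum(clipped), negativity_mass = negativity_mass)
}

#' Full estimand surface from a closeout-augmented trial
#'
#' With the all-defined and constant-control-biomarker assumptions plus
#' time constancy, closeout data fully identify the surface: `r1` from
#' the treated arm, `f(s1)` from treated subjects, `P(Y0 = 1)` from the
#' full placebo arm (the identity requires the *marginal* placebo risk),
#' `f(s1 | Y0 = 0)` from closeout measurements, `f(s1 | Y0 = 1)` by the
#' mixture identity, and finally `r0(s1) = f(s1 | Y0 = 1) P(Y0 = 1) /
#' f(s1)`.
#'
#' @param trial An [observed_trial] with closeout measurements.
#' @param support A [biomarker_support].
#' @param c_value Asserted constant control biomarker level.
#' @param sa1_cap As in [estimate_r1_under_sa2].
#' @return A `closeout_estimate` list: `pmf_s1_given_y0_0`,
#'   `pmf_s1_given_y0_1`, `p_y0`, `negativity_mass`, `surface` (an
#'   `estimand_surface` with both risks), `rd`, `rr` (contrast surfaces).
#' @export
estimate_full_surface_closeout <- function(trial, support, c_value = 0,
                                           sa1_cap = 0.05) {
  r1_surf <- estimate_r1_under_sa2(trial, support, c_value, sa1_cap)
  f_s1 <- attr(r1_surf, "f_s1")
  d0 <- trial[trial$z == 0, , drop = FALSE]
  if (nrow(d0) == 0) stop("control arm is empty", call. = FALSE)
  p_y0 <- mean(d0$y)
  pmf_y0_0 <- estimate_f_s1_given_y0_0(trial, support)
  rec <- recover_f_s1_given_y0_1(f_s1, pmf_y0_0, p_y0)
  occupied <- f_s1 > 0
  r0 <- rep(NA_real_, support$k)
  r0[occupied] <- pmin(1, rec$pmf[occupied] * p_y0 / f_s1[occupied])
  idx <- match(r1_surf$s1, support$levels)
  surf <- new_surface(s0 = r1_surf$s0, s1 = r1_surf$s1,
                      r0 = r0[idx], r1 = r1_surf$r1, n = r1_surf$n,
                      conditioning = "sa1_sa2", provenance = "estimated")
  structure(list(pmf_s1_given_y0_0 = pmf_y0_0,
                 pmf_s1_given_y0_1 = rec$pmf,
                 p_y0 = p_y0,
                 negativity_mass = rec$negativity_mass,
                 surface = surf,
                 rd = risk_contrasts(surf, "RD"),
                 rr = risk_contrasts(surf, "RR")),
            class = "closeout_estimate")
}

#' @export
print.closeout_estimate <- function(x, ...) {
  cat("<closeout_estimate> P(Y0=1) =", signif(x$p_y0, 4),
      " clipped mass =", signif(x$negativity_mass, 4), "\n")
  print(as.data.frame(x$surface))
  invisible(x)
}
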