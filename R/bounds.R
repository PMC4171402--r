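#' Test the observable implication of outcome monotonicity
#'
#' The individual-level monotonicity assumption `P(Y1 <= Y0) = 1` (the
#' treatment never causes the outcome it is meant to prevent) is
#' untestable, but it implies `P(Y1 = 1) <= P(Y0 = 1)`, which is testable
#' from the arm-specific event rates. The one-sided two-proportion test of
#' `H0: P(Y1 = 1) <= P(Y0 = 1)` against `H1: >` is computed with the
#' pooled normal approximation, falling back to Fisher's exact test when
#' either arm has fewer than 30 events. Rejection indicates that the
#' implication — and therefore the assumption — fails.
#'
#' @param trial An [observed_trial].
#' @param alpha Test level (default 0.05).
#' @param exact_threshold Event count below which the exact test is used.
#' @return A `monotonicity_test` list: `p1_hat`, `p0_hat`, `difference`,
#'   `p_value`, `method`, `reject`, `alpha`.
#' @export
test_monotonicity_implication <- function(trial, alpha = 0.05,
                                          exact_threshold = 30) {
  stopifnot(inherits(trial, "observed_trial"))
  for (arm in c(0, 1))
    if (!any(trial$z == arm)) stop("arm ", arm, " is empty", call. = FALSE)
  y1 <- trial$y[trial$z == 1]; y0 <- trial$y[trial$z == 0]
  n1 <- length(y1); n0 <- length(y0)
  x1 <- sum(y1); x0 <- sum(y0)
  p1 <- x1 / n1; p0 <- x0 / n0
  if (min(x1, x0) < exact_threshold) {
    method <- "fisher_exact"
    p_value <- stats::fisher.test(rbind(c(x1, n1 - x1), c(x0, n0 - x0)),
                                  alternative = "greater")$p.value
  } else {
    method <- "normal_approx"
    pp <- (x1 + x0) / (n1 + n0)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n0))
    z <- if (se == 0) 0 else (p1 - p0) / se
    p_value <- 1 - stats::pnorm(z)
  }
  structure(list(p1_hat = p1, p0_hat = p0, difference = p1 - p0,
                 p_value = p_value, method = method,
                 reject = p_value < alpha, alpha = alpha),
            class = "monotonicity_test")
}

#' @export
print.monotonicity_test <- function(x, ...) {
  cat("<monotonicity_test> one-sided H0: P(Y1=1) <= P(Y0=1)\n")
  cat(sprintf("  p1 = %.4f, p0 = %.4f, difference = %.4f\n",
              x$p1_hat, x$p0_hat, x$difference))
  cat(sprintf("  p-value = %.4g (%s): %s at alpha = %g\n", x$p_value,
              x$method, if (x$reject) "REJECT (implication fails)"
              else "no evidence against monotonicity", x$alpha))
  invisible(x)
}

#' Partial-identification bounds on the per-stratum contrasts
#'
#' Without auxiliary data the control risk curve depends on the free pmf
#' `p = f(s1 | Y0 = 1)` on the K-simplex. This function bounds the risk
#' difference `RD(s1) = r1(s1) - p(s1) P(Y0 = 1) / f(s1)` per stratum by
#' extremizing `p(s1)` over the polytope cut out of the simplex by the
#' selected constraints, solved as linear programs:
#' \describe{
#'   \item{`mixture_feasibility`}{always imposed: the implied
#'     `f(s1 | Y0 = 0)` must be nonnegative, i.e.
#'     `p(s) <= f(s) / P(Y0 = 1)` coordinate-wise.}
#'   \item{`individual_monotone_y`}{outcome monotonicity forces
#'     `r0(s) >= r1(s)`, i.e. `p(s) >= r1(s) f(s) / P(Y0 = 1)`.}
#'   \item{`stochastic_order_s1`}{the stochastic-ordering assumption that
#'     treated-arm cases have lower biomarkers than control-arm cases
#'     would: the CDF of `p` must lie at or below the identifiable CDF of
#'     `f(s1 | Y1 = 1)` (set `reverse = TRUE` for the opposite
#'     direction).}
#' }
#' Adding a constraint can only shrink the polytope, so intervals never
#' widen. With no events in the control arm `r0` is identically zero and
#' the bounds collapse to the identified point `RD = r1`.
#'
#' @param trial An [observed_trial].
#' @param support A [biomarker_support].
#' @param constraints Character subset of
#'   `c("individual_monotone_y", "stochastic_order_s1")`
#'   (`mixture_feasibility` is always active).
#' @param c_value,sa1_cap As in [estimate_r1_under_sa2].
#' @param reverse Reverse the stochastic-order direction.
#' @return A `bounds_surface` data.frame: `s1`, `r1`, `r0_lo`, `r0_hi`,
#'   `rd_lo`, `rd_hi`, `rr_lo`, `rr_hi`, `feasible`, with attributes
#'   `constraints`, `p_y0`, `f_s1`.
#' @export
partial_id_bounds <- function(trial, support,
                              constraints = character(0),
                              c_value = 0, sa1_cap = 0.05,
                              reverse = FALSE) {
  stopifnot(inherits(trial, "observed_trial"))
  bad <- setdiff(constraints,
                 c("mixture_feasibility", "individual_monotone_y",
                   "stochastic_order_s1"))
  if (length(bad)) stop("unknown constraint(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  r1_surf <- estimate_r1_under_sa2(trial, support, c_value, sa1_cap)
  f <- attr(r1_surf, "f_s1")
  d1 <- trial[trial$z == 1 & trial$a_tau == 1, , drop = FALSE]
  d0 <- trial[trial$z == 0, , drop = FALSE]
  p_y0 <- mean(d0$y)
  lev <- support$levels
  occ <- which(f > 0)
  r1 <- rep(NA_real_, support$k)
  r1[match(r1_surf$s1, lev)] <- r1_surf$r1

  use_mono <- "individual_monotone_y" %in% constraints
  use_sto <- "stochastic_order_s1" %in% constraints
  active <- c("mixture_feasibility",
              intersect(constraints,
                        c("individual_monotone_y", "stochastic_order_s1")))

  if (p_y0 == 0) {
    # no control-arm events: r0 is identically 0, point identification
    out <- data.frame(s1 = lev[occ], r1 = r1[occ],
                      r0_lo = 0, r0_hi = 0,
                      rd_lo = r1[occ], rd_hi = r1[occ],
                      rr_lo = NA_real_, rr_hi = NA_real_,
                      feasible = TRUE)
    return(structure(out, constraints = active, p_y0 = p_y0, f_s1 = f,
                     violated = NULL,
                     class = c("bounds_surface", "data.frame")))
  }

  Kocc <- length(occ)
  ub <- pmin(1, f[occ] / p_y0)               # mixture feasibility
  lb <- if (use_mono) pmin(ub, pmax(0, r1[occ] * f[occ] / p_y0)) else rep(0, Kocc)
  if (use_mono && any(r1[occ] * f[occ] / p_y0 > ub + 1e-9)) {
    violated <- "individual_monotone_y vs mixture_feasibility"
  } else violated <- NULL

  A1 <- diag(Kocc); b1 <- ub
  if (use_sto) {
    f_y1_1 <- if (sum(d1$y) > 0) empirical_pmf(d1$s[d1$y == 1], support)
              else rep(1 / support$k, support$k)
    cdf_ref <- cumsum(f_y1_1[occ])
    if (Kocc > 1) {
      Csum <- outer(seq_len(Kocc - 1), seq_len(Kocc), `>=`) * 1
      if (!reverse) {                       # P stochastically larger
        A1 <- rbind(A1, Csum); b1 <- c(b1, cdf_ref[seq_len(Kocc - 1)])
      } else {
        # reversed direction handled below as >= constraints
      }
    }
  }
  A2 <- NULL; b2 <- NULL
  if (any(lb > 0)) { A2 <- diag(Kocc)[lb > 0, , drop = FALSE]; b2 <- lb[lb > 0] }
  if (use_sto && reverse && Kocc > 1) {
    Csum <- outer(seq_len(Kocc - 1), seq_len(Kocc), `>=`) * 1
    f_y1_1 <- if (sum(d1$y) > 0) empirical_pmf(d1$s[d1$y == 1], support)
              else rep(1 / support$k, support$k)
    cdf_ref <- cumsum(f_y1_1[occ])
    A2 <- rbind(A2, Csum); b2 <- c(b2, cdf_ref[seq_len(Kocc - 1)])
  }
  A3 <- matrix(1, 1, Kocc); b3 <- 1

  solve_lp <- function(obj, maxi) {
    res <- tryCatch({
      if (is.null(A2))
        boot::simplex(a = obj, A1 = A1, b1 = b1, A3 = A3, b3 = b3,
                      maxi = maxi)
      else
        boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                      A3 = A3, b3 = b3, maxi = maxi)
    }, error = function(e) NULL)
    if (is.null(res) || res$solved != 1) return(NA_real_)
    unname(res$value)
  }
  if (max(ub - lb) < 1e-9 && abs(sum(lb) - 1) < 1e-9) {
    # degenerate polytope: the constraints pin p to a single point
    p_min <- p_max <- lb
  } else {
    p_min <- p_max <- rep(NA_real_, Kocc)
    for (j in seq_len(Kocc)) {
      obj <- rep(0, Kocc); obj[j] <- 1
      p_max[j] <- solve_lp(obj, TRUE)
      p_min[j] <- solve_lp(obj, FALSE)
    }
  }
  feasible <- !anyNA(c(p_min, p_max))
  if (!feasible && is.null(violated))
    violated <- paste(active, collapse = " + ")

  r0_lo <- pmax(0, p_min * p_y0 / f[occ])
  r0_hi <- pmin(1, p_max * p_y0 / f[occ])
  rd_lo <- pmax(-1, r1[occ] - r0_hi)
  rd_hi <- pmin(1, r1[occ] - r0_lo)
  rr_lo <- ifelse(r0_hi > 0, r1[occ] / r0_hi, NA_real_)
  rr_hi <- ifelse(r0_lo > 0, r1[occ] / r0_lo, NA_real_)
  out <- data.frame(s1 = lev[occ], r1 = r1[occ],
                    r0_lo = r0_lo, r0_hi = r0_hi,
                    rd_lo = rd_lo, rd_hi = rd_hi,
                    rr_lo = rr_lo, rr_hi = rr_hi,
                    feasible = feasible)
  structure(out, constraints = active, p_y0 = p_y0, f_s1 = f,
            violated = violated,
            class = c("bounds_surface", "data.frame"))
}
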