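# Shared constructor for per-stratum risk surfaces.
new_surface <- function(s0, s1, r0, r1, n,
                        conditioning = c("general_A11", "sa1", "sa1_sa2"),
                        provenance = c("oracle_direct", "oracle_bayes",
                                       "estimated", "truth"),
                        omitted_strata = NULL) {
  conditioning <- match.arg(conditioning)
  provenance <- match.arg(provenance)
  out <- data.frame(s0 = s0, s1 = s1, r0 = r0, r1 = r1, n = n)
  out <- out[order(out$s0, out$s1), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, conditioning = conditioning, provenance = provenance,
            omitted_strata = omitted_strata,
            class = c("estimand_surface", "data.frame"))
}

#' Per-stratum risk estimands from full counterfactual data
#'
#' The oracle: given the (simulated or crossover-identified) joint
#' potential-outcome table, computes within every principal stratum
#' `(s0, s1)` the finite-population means of `y0` and `y1` — the risks
#' `R0(s0, s1) = P(Y0 = 1 | S0 = s0, S1 = s1, A0 = A1 = 1)` and the
#' analogous `R1`. Conditioning on the biomarker being defined under both
#' assignments is what makes the joint stratum labels well defined.
#' Strata with no subjects are omitted (the estimands are undefined off
#' the support) and listed in the `omitted_strata` attribute.
#'
#' @param trial A [counterfactual_trial].
#' @return An `estimand_surface` data.frame with columns `s0`, `s1`, `r0`,
#'   `r1`, `n` and attributes `conditioning` and `provenance`.
#' @export
oracle_risks <- function(trial) {
  stopifnot(inherits(trial, "counterfactual_trial"))
  keep <- trial$a0 == 1L & trial$a1 == 1L
  if (!any(keep))
    stop("empty conditioning set: no subject has a0 = a1 = 1", call. = FALSE)
  d <- trial[keep, , drop = FALSE]
  key <- interaction(d$s0, d$s1, drop = TRUE, lex.order = TRUE)
  s0 <- tapply(d$s0, key, `[`, 1)
  s1 <- tapply(d$s1, key, `[`, 1)
  r0 <- tapply(d$y0, key, mean)
  r1 <- tapply(d$y1, key, mean)
  n <- as.vector(table(key))
  new_surface(s0 = as.vector(s0), s1 = as.vector(s1),
              r0 = as.vector(r0), r1 = as.vector(r1), n = n,
              conditioning = "general_A11", provenance = "oracle_direct")
}

#' Risk estimands via the Bayes-rule decomposition
#'
#' Computes the same per-stratum risks as [oracle_risks] but through the
#' Bayes factorization
#' `R1(s0, s1) = f(s0, s1 | Y1 = 1, A = (1,1)) * P(Y1 = 1 | A = (1,1)) /
#' f(s0, s1 | A = (1,1))` (and analogously for `R0`), with every factor an
#' empirical pmf or proportion on the counterfactual table. On any finite
#' table the decomposition is an algebraic identity with the direct means,
#' which makes it the natural cross-check; it is also the form whose
#' factors the identification strategies target one by one. When no events
#' occur under an arm the conditional pmf factor is vacuous and the risk
#' is 0.
#'
#' @param trial A [counterfactual_trial].
#' @return An `estimand_surface` with provenance `"oracle_bayes"`.
#' @export
oracle_risks_bayes <- function(trial) {
  stopifnot(inherits(trial, "counterfactual_trial"))
  keep <- trial$a0 == 1L & trial$a1 == 1L
  if (!any(keep))
    stop("empty conditioning set: no subject has a0 = a1 = 1", call. = FALSE)
  d <- trial[keep, , drop = FALSE]
  key <- interaction(d$s0, d$s1, drop = TRUE, lex.order = TRUE)
  n_tot <- nrow(d)
  f_joint <- as.vector(table(key)) / n_tot
  risk_z <- function(y) {
    p_y <- mean(y)
    if (p_y == 0) return(rep(0, nlevels(key)))
    f_given_y <- as.vector(table(key[y == 1])) / sum(y)
    f_given_y * p_y / f_joint
  }
  new_surface(s0 = as.vector(tapply(d$s0, key, `[`, 1)),
              s1 = as.vector(tapply(d$s1, key, `[`, 1)),
              r0 = risk_z(d$y0), r1 = risk_z(d$y1),
              n = as.vector(table(key)),
              conditioning = "general_A11", provenance = "oracle_bayes")
}

#' Risk-difference and relative-risk contrasts of a surface
#'
#' `RD(s0, s1) = R1 - R0` and `RR(s0, s1) = R1 / R0` per stratum. A
#' relative risk with `r0 = 0` is reported as `NA` with the `undefined`
#' flag set rather than as infinity, so surfaces stay serializable.
#'
#' @param surface An `estimand_surface`.
#' @param contrast_type `"RD"` or `"RR"`.
#' @return A `contrast_surface` data.frame with columns `s0`, `s1`,
#'   `value`, `undefined` and attribute `contrast_type`.
#' @export
risk_contrasts <- function(surface, contrast_type = c("RD", "RR")) {
  stopifnot(inherits(surface, "estimand_surface"))
  contrast_type <- match.arg(contrast_type)
  if (contrast_type == "RD") {
    value <- surface$r1 - surface$r0
    undefined <- rep(FALSE, nrow(surface))
  } else {
    undefined <- surface$r0 == 0
    value <- ifelse(undefined, NA_real_, surface$r1 / surface$r0)
  }
  structure(data.frame(s0 = surface$s0, s1 = surface$s1,
                       value = value, undefined = undefined),
            contrast_type = contrast_type,
            class = c("contrast_surface", "data.frame"))
}

#' Classify average causal necessity and sufficiency
#'
#' A principal surrogate must satisfy *average causal necessity* (ACN): no
#' treatment effect on the outcome in strata where treatment does not move
#' the biomarker (`s1 = s0`), and *average causal sufficiency* (ACS): a
#' treatment effect in every stratum where the biomarker moves by more
#' than a threshold `C >= 0`. These are exact statements about population
#' contrasts; on estimated surfaces they are operationalized with an
#' equality tolerance. In addition to the verdict at the supplied `C`,
#' the smallest `C` for which ACS passes is reported.
#'
#' @param contrast A `contrast_surface` (RD or RR).
#' @param c_threshold The ACS threshold `C` (default 0).
#' @param tol Equality tolerance on the contrast (default 0.02 for RD; for
#'   RR the tolerance is applied to `|RR - 1|`).
#' @return A `surrogate_verdict` list: `acn_pass`, `acs_pass` (logical or
#'   `NA` when not assessable), `acs_constant_c`, `acs_min_c`, `tolerance`,
#'   and a per-stratum `detail` table.
#' @export
classify_surrogate <- function(contrast, c_threshold = 0, tol = 0.02) {
  stopifnot(inherits(contrast, "contrast_surface"))
  if (c_threshold < 0) stop("`c_threshold` must be nonnegative", call. = FALSE)
  null_value <- if (attr(contrast, "contrast_type") == "RR") 1 else 0
  d <- unique(as.data.frame(contrast))      # verdicts invariant to duplication
  dist <- abs(d$s0 - d$s1)
  effect <- abs(d$value - null_value) > tol
  effect[is.na(d$value)] <- TRUE            # RR undefined: r0 = 0 < r1 possible
  diag_strata <- dist == 0
  acn_pass <- if (!any(diag_strata)) NA else all(!effect[diag_strata])
  eligible <- dist > c_threshold
  acs_pass <- if (!any(eligible)) NA else all(effect[eligible])
  # smallest C (among observed distances) for which ACS holds
  cand <- sort(unique(dist))
  acs_min_c <- NA_real_
  for (cc in cand) {
    el <- dist > cc
    if (any(el) && all(effect[el])) { acs_min_c <- cc; break }
  }
  detail <- data.frame(s0 = d$s0, s1 = d$s1, distance = dist,
                       value = d$value, effect = effect,
                       role = ifelse(diag_strata, "ACN",
                                     ifelse(eligible, "ACS", "none")))
  structure(list(acn_pass = acn_pass, acs_pass = acs_pass,
                 acs_constant_c = c_threshold, acs_min_c = acs_min_c,
                 tolerance = tol, detail = detail),
            class = "surrogate_verdict")
}

#' @export
print.surrogate_verdict <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not assessable" else if (v) "PASS" else "FAIL"
  cat("<surrogate_verdict>\n")
  cat("  average causal necessity: ", fmt(x$acn_pass), "\n")
  cat("  average causal sufficiency (C = ", x$acs_constant_c, "): ",
      fmt(x$acs_pass), "\n", sep = "")
  if (!is.na(x$acs_min_c))
    cat("  smallest C with ACS pass:", x$acs_min_c, "\n")
  cat("  tolerance:", x$tolerance, "\n")
  invisible(x)
}

#' Write an estimand or contrast surface as tidy CSV
#'
#' @param x An `estimand_surface` or `contrast_surface`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(x, path) {
  out <- as.data.frame(x)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
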