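#' Construct an observed trial table
#'
#' The realizable view of a two-arm randomized trial: each subject carries
#' the assigned arm `z`, the indicator `a_tau` that the biomarker was
#' defined at the measurement time, the biomarker `s` (NA exactly when
#' `a_tau == 0`), the binary clinical outcome `y`, an optional closeout
#' biomarker (defined only for placebo subjects who remained event-free),
#' and optional baseline covariates.
#'
#' @param z Assigned arm, 0/1.
#' @param s Biomarker at time `tau`; `NA` means undefined.
#' @param y Binary outcome.
#' @param a_tau Indicator that the biomarker is defined; inferred from `s`
#'   when `NULL`.
#' @param closeout_s Optional closeout biomarker, `NA` where not measured.
#' @param covariates Optional data.frame of baseline covariates.
#' @param subject_id Optional ids (default `seq_along(z)`).
#' @param tau Scalar measurement-time metadata shared by all subjects.
#' @param support Optional [biomarker_support] attached as an attribute.
#' @return A data.frame of class `observed_trial`.
#' @export
observed_trial <- function(z, s, y, a_tau = NULL, closeout_s = NULL,
                           covariates = NULL, subject_id = NULL,
                           tau = NA_real_, support = NULL) {
  n <- length(z)
  z <- as.integer(z); y <- as.integer(y); s <- as.numeric(s)
  if (!all(z %in% c(0L, 1L))) {
    bad <- which(!(z %in% c(0L, 1L)))[1]
    stop("`z` must be 0/1; offending row ", bad, call. = FALSE)
  }
  if (!all(y %in% c(0L, 1L))) {
    bad <- which(!(y %in% c(0L, 1L)))[1]
    stop("`y` must be 0/1; offending row ", bad, call. = FALSE)
  }
  if (is.null(a_tau)) a_tau <- as.integer(!is.na(s)) else a_tau <- as.integer(a_tau)
  if (any(is.na(s) & a_tau == 1L))
    stop("missing-but-defined biomarker values are not supported: rows ",
         paste(utils::head(which(is.na(s) & a_tau == 1L), 5), collapse = ", "),
         " have a_tau = 1 but no `s` value", call. = FALSE)
  if (any(!is.na(s) & a_tau == 0L))
    stop("`s` must be undefined exactly when a_tau = 0; rows ",
         paste(utils::head(which(!is.na(s) & a_tau == 0L), 5), collapse = ", "),
         " violate this", call. = FALSE)
  if (is.null(closeout_s)) closeout_s <- rep(NA_real_, n)
  closeout_s <- as.numeric(closeout_s)
  bad_co <- which(!is.na(closeout_s) & !(z == 0L & y == 0L))
  if (length(bad_co))
    stop("closeout_s may only be defined for z = 0, y = 0 subjects; rows ",
         paste(utils::head(bad_co, 5), collapse = ", "), " violate this",
         call. = FALSE)
  if (is.null(subject_id)) subject_id <- seq_len(n)
  out <- data.frame(subject_id = subject_id, z = z, a_tau = a_tau,
                    s = s, y = y, closeout_s = closeout_s)
  if (!is.null(covariates)) out <- cbind(out, covariates)
  structure(out, tau = tau, support = support,
            class = c("observed_trial", "data.frame"))
}

#' Construct a counterfactual trial table
#'
#' The full potential-outcome table: for every subject both biomarker
#' values `(s0, s1)` and both outcomes `(y0, y1)` under control and
#' treatment, with indicators `(a0, a1)` of whether the biomarker is
#' defined under each assignment. Only a simulator (or a crossover design)
#' can produce such a table; a parallel-arm trial reveals one coordinate of
#' each pair per subject.
#'
#' @param s0,s1 Potential biomarker values (`NA` = undefined).
#' @param y0,y1 Potential binary outcomes.
#' @param a0,a1 Defined-biomarker indicators; inferred from `s0`/`s1` when
#'   `NULL`.
#' @param covariates Optional data.frame of baseline covariates.
#' @param subject_id Optional ids.
#' @param tau Scalar measurement-time metadata.
#' @param support Optional [biomarker_support].
#' @return A data.frame of class `counterfactual_trial`.
#' @export
counterfactual_trial <- function(s0, s1, y0, y1, a0 = NULL, a1 = NULL,
                                 covariates = NULL, subject_id = NULL,
                                 tau = NA_real_, support = NULL) {
  n <- length(s0)
  s0 <- as.numeric(s0); s1 <- as.numeric(s1)
  y0 <- as.integer(y0); y1 <- as.integer(y1)
  if (!all(y0 %in% c(0L, 1L)) || !all(y1 %in% c(0L, 1L)))
    stop("`y0`, `y1` must be 0/1", call. = FALSE)
  if (is.null(a0)) a0 <- as.integer(!is.na(s0)) else a0 <- as.integer(a0)
  if (is.null(a1)) a1 <- as.integer(!is.na(s1)) else a1 <- as.integer(a1)
  if (any(is.na(s0) != (a0 == 0L)) || any(is.na(s1) != (a1 == 0L)))
    stop("s_z must be undefined exactly when a_z = 0", call. = FALSE)
  if (is.null(subject_id)) subject_id <- seq_len(n)
  out <- data.frame(subject_id = subject_id, a0 = a0, a1 = a1,
                    s0 = s0, s1 = s1, y0 = y0, y1 = y1)
  if (!is.null(covariates)) out <- cbind(out, covariates)
  structure(out, tau = tau, support = support,
            class = c("counterfactual_trial", "data.frame"))
}

canonical_cols <- c("subject_id", "z", "a_tau", "s", "y", "closeout_s")

#' Read an observed trial from CSV
#'
#' Reads a comma-separated trial table (header row required, UTF-8).
#' Undefined biomarkers are encoded with a reserved token
#' (default `"NA_UNDEFINED"`); a blank/NA biomarker on a row claiming a
#' defined measurement is rejected, because missing-but-defined values are
#' outside this package's scope. When no `a_tau` column is present it is
#' inferred: 0 exactly where `s` carries the undefined token.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping canonical column
#'   names (`z`, `s`, `y`, and optionally `subject_id`, `a_tau`,
#'   `closeout_s`) to the file's column names.
#' @param undefined_code Token encoding an undefined biomarker.
#' @param tau Measurement-time metadata to attach.
#' @param support Optional [biomarker_support] to attach.
#' @return An [observed_trial]; row order is preserved and every extra
#'   column is carried through as a covariate.
#' @export
read_observed_trial <- function(path, schema = NULL,
                                undefined_code = "NA_UNDEFINED",
                                tau = NA_real_, support = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (is.null(schema)) schema <- character(0)
  resolve <- function(canon) {
    col <- if (canon %in% names(schema)) schema[[canon]] else canon
    if (col %in% names(raw)) col else NA_character_
  }
  for (req in c("z", "s", "y"))
    if (is.na(resolve(req)))
      stop("required column `", req, "` (file column `",
           if (req %in% names(schema)) schema[[req]] else req,
           "`) not found in ", path, call. = FALSE)

  parse_marker <- function(x) {
    und <- !is.na(x) & x == undefined_code
    x[und | is.na(x) | x == ""] <- NA
    v <- suppressWarnings(as.numeric(x))
    if (any(!is.na(x) & is.na(v)))
      stop("non-numeric biomarker value in ", path, call. = FALSE)
    list(values = v, undefined = und)
  }
  sm <- parse_marker(raw[[resolve("s")]])
  z <- suppressWarnings(as.numeric(raw[[resolve("z")]]))
  y <- suppressWarnings(as.numeric(raw[[resolve("y")]]))
  if (any(is.na(z) | !(z %in% c(0, 1)))) {
    bad <- which(is.na(z) | !(z %in% c(0, 1)))[1]
    stop("`z` outside {0,1} at row ", bad, call. = FALSE)
  }
  a_tau <- if (!is.na(resolve("a_tau"))) {
    as.integer(raw[[resolve("a_tau")]])
  } else {
    blank_defined <- is.na(sm$values) & !sm$undefined
    if (any(blank_defined))
      stop("missing-but-defined biomarker at rows ",
           paste(utils::head(which(blank_defined), 5), collapse = ", "),
           "; undefined values must use the token `", undefined_code, "`",
           call. = FALSE)
    as.integer(!is.na(sm$values))
  }
  closeout_s <- if (!is.na(resolve("closeout_s")))
    parse_marker(raw[[resolve("closeout_s")]])$values else NULL
  subject_id <- if (!is.na(resolve("subject_id")))
    raw[[resolve("subject_id")]] else NULL
  used <- stats::na.omit(vapply(canonical_cols, resolve, character(1)))
  cov_cols <- setdiff(names(raw), used)
  covariates <- if (length(cov_cols)) {
    cv <- raw[cov_cols]
    cv[] <- lapply(cv, function(x) {
      v <- suppressWarnings(as.numeric(x))
      if (all(is.na(v) == is.na(x))) v else x
    })
    cv
  } else NULL
  observed_trial(z = z, s = sm$values, y = y, a_tau = a_tau,
                 closeout_s = closeout_s, covariates = covariates,
                 subject_id = subject_id, tau = tau, support = support)
}

#' Write an observed trial to CSV
#'
#' Inverse of [read_observed_trial]: undefined biomarkers are written as
#' the support's undefined token, unmeasured closeout values as blanks.
#'
#' @param trial An [observed_trial].
#' @param path Output path.
#' @param undefined_code Token for undefined biomarkers.
#' @return `path`, invisibly.
#' @export
write_observed_trial <- function(trial, path,
                                 undefined_code = "NA_UNDEFINED") {
  stopifnot(inherits(trial, "observed_trial"))
  out <- as.data.frame(trial)
  s <- format_num(out$s)
  s[is.na(out$s)] <- undefined_code
  out$s <- s
  co <- format_num(out$closeout_s)
  co[is.na(out$closeout_s)] <- ""
  out$closeout_s <- co
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Full-precision numeric formatting so CSV round-trips are bit-exact.
format_num <- function(x) {
  if (!is.numeric(x)) return(x)
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_
    else if (!is.finite(v)) as.character(v)
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Validate an observed trial
#'
#' Pure, side-effect-free diagnostics on the contracts that are checkable
#' from observed data: arm balance, the per-arm fraction of undefined
#' biomarkers (large fractions undermine the assumption that the biomarker
#' is defined on everyone), whether undefinedness is linked to the outcome,
#' standardized mean differences of baseline covariates across arms (the
#' observable shadow of ignorable treatment assignment), and per-arm event
#' rates.
#'
#' @param trial An [observed_trial].
#' @param sa1_cap Fraction of undefined biomarkers above which the
#'   all-defined assumption is flagged implausible (default 0.05).
#' @param smd_cap Absolute standardized-mean-difference threshold for the
#'   covariate-balance check (default 0.1).
#' @return A `validation_report`: a data.frame of checks
#'   (`check`, `pass`, `detail`) with summary statistics in attributes
#'   (`stats`), including `sa1_plausible`.
#' @export
validate_trial <- function(trial, sa1_cap = 0.05, smd_cap = 0.1) {
  stopifnot(inherits(trial, "observed_trial"))
  if (nrow(trial) == 0) stop("trial is empty", call. = FALSE)
  checks <- list()
  add <- function(name, pass, detail)
    checks[[length(checks) + 1L]] <<- data.frame(check = name, pass = pass,
                                                 detail = detail)
  n0 <- sum(trial$z == 0); n1 <- sum(trial$z == 1)
  add("arm_nonempty", n0 > 0 && n1 > 0,
      sprintf("n0=%d, n1=%d", n0, n1))

  frac_undef <- c(`0` = mean(trial$a_tau[trial$z == 0] == 0),
                  `1` = mean(trial$a_tau[trial$z == 1] == 0))
  frac_undef[is.nan(frac_undef)] <- 0
  sa1_plausible <- max(frac_undef) <= sa1_cap
  add("sa1_fraction_undefined", sa1_plausible,
      sprintf("arm0=%.4f, arm1=%.4f (cap %.2f)", frac_undef[1], frac_undef[2],
              sa1_cap))

  # Outcome-linked undefinedness: within each arm, compare the undefined
  # fraction between events and non-events.
  link <- vapply(c(0, 1), function(zz) {
    d <- trial[trial$z == zz, ]
    if (!any(d$y == 1) || !any(d$y == 0)) return(0)
    abs(mean(d$a_tau[d$y == 1] == 0) - mean(d$a_tau[d$y == 0] == 0))
  }, numeric(1))
  add("sa1_outcome_link", max(link) <= sa1_cap,
      sprintf("max |frac_undef(y=1) - frac_undef(y=0)| = %.4f", max(link)))

  cov_cols <- setdiff(names(trial), canonical_cols)
  cov_cols <- cov_cols[vapply(trial[cov_cols], is.numeric, logical(1))]
  smd <- numeric(0)
  if (length(cov_cols) && n0 > 1 && n1 > 1) {
    smd <- vapply(cov_cols, function(cc) {
      x0 <- trial[[cc]][trial$z == 0]; x1 <- trial[[cc]][trial$z == 1]
      sp <- sqrt((stats::var(x0) + stats::var(x1)) / 2)
      if (!is.finite(sp) || sp == 0) return(0)
      (mean(x1) - mean(x0)) / sp
    }, numeric(1))
    add("covariate_balance", all(abs(smd) < smd_cap),
        sprintf("max |SMD| = %.4f over %d covariates (cap %.2f)",
                max(abs(smd)), length(smd), smd_cap))
  }
  rates <- c(`0` = mean(trial$y[trial$z == 0]), `1` = mean(trial$y[trial$z == 1]))
  add("event_rates", TRUE,
      sprintf("arm0=%.4f, arm1=%.4f", rates[1], rates[2]))

  rep <- do.call(rbind, checks)
  structure(rep,
            stats = list(frac_undefined = frac_undef, smd = smd,
                         event_rates = rates, sa1_plausible = sa1_plausible,
                         n = c(`0` = n0, `1` = n1)),
            class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-24s %s\n", if (x$pass[i]) "ok" else "!!",
                x$check[i], x$detail[i]))
  invisible(x)
}
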