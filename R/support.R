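#' Construct a biomarker support
#'
#' Describes the discrete support on which per-stratum risks are estimated:
#' an ordered set of stratum labels, optional bin edges when the levels were
#' derived from a continuous marker, and the sentinel code used for a
#' biomarker that is *undefined* (for example because the clinical outcome
#' occurred before the measurement time `tau`, so no meaningful value
#' exists). An undefined biomarker is a different thing from a missing but
#' well-defined one; the latter is rejected throughout this package.
#'
#' @param levels Numeric vector of distinct, strictly increasing stratum
#'   labels.
#' @param edges Optional numeric vector of `length(levels) + 1` strictly
#'   increasing bin boundaries (present when the support was derived from a
#'   continuous marker).
#' @param undefined_code Character sentinel used in CSV files for an
#'   undefined biomarker. Internally undefined values are carried as `NA`.
#' @return An object of class `biomarker_support` with fields `levels`,
#'   `edges`, `undefined_code`, `k`.
#' @export
#' @examples
#' biomarker_support(0:4)
biomarker_support <- function(levels, edges = NULL,
                              undefined_code = "NA_UNDEFINED") {
  levels <- as.numeric(levels)
  if (anyNA(levels) || anyDuplicated(levels) || is.unsorted(levels, strictly = TRUE))
    stop("`levels` must be distinct, finite and strictly increasing", call. = FALSE)
  if (!is.null(edges)) {
    edges <- as.numeric(edges)
    if (length(edges) != length(levels) + 1L)
      stop("`edges` must have length(levels) + 1 boundaries", call. = FALSE)
    if (anyNA(edges) || is.unsorted(edges, strictly = TRUE))
      stop("`edges` must be strictly increasing", call. = FALSE)
  }
  if (!is.character(undefined_code) || length(undefined_code) != 1L)
    stop("`undefined_code` must be a single string", call. = FALSE)
  if (undefined_code %in% as.character(levels))
    stop("`undefined_code` must not collide with a level label", call. = FALSE)
  structure(list(levels = levels, edges = edges,
                 undefined_code = undefined_code, k = length(levels)),
            class = "biomarker_support")
}

#' @export
print.biomarker_support <- function(x, ...) {
  cat("<biomarker_support> K =", x$k, "levels:",
      paste(x$levels, collapse = ", "), "\n")
  if (!is.null(x$edges))
    cat("  bin edges:", paste(signif(x$edges, 4), collapse = ", "), "\n")
  cat("  undefined code:", x$undefined_code, "\n")
  invisible(x)
}

#' Discretize a continuous biomarker into K ordered strata
#'
#' Nonparametric identification of the per-stratum risk estimands is stated
#' for discrete biomarker supports, so continuous markers are binned before
#' estimation. Default bins are empirical quantile bins at probabilities
#' `j/k`; bins are left-closed and right-open with the last bin closed, and
#' a value tied with a bin edge falls in the lower bin.
#'
#' @param values Numeric vector; `NA` entries are treated as *undefined*
#'   biomarkers and passed through untouched (they map to `NA`).
#' @param k Number of strata (default 5).
#' @param edges Optional user-supplied bin boundaries (`k + 1` strictly
#'   increasing values); when absent, empirical quantiles are used.
#' @param undefined_code Sentinel recorded on the returned support.
#' @return A list with elements `support` (a [biomarker_support] whose
#'   levels are `0:(k-1)`) and `levels` (the per-value stratum labels, `NA`
#'   where the input was undefined).
#' @export
#' @examples
#' discretize_biomarker(rnorm(100), k = 4)$support
discretize_biomarker <- function(values, k = 5, edges = NULL,
                                 undefined_code = "NA_UNDEFINED") {
  values <- as.numeric(values)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  defined <- values[!is.na(values)]
  if (length(unique(defined)) < k)
    stop("degenerate support: fewer than `k` distinct defined values", call. = FALSE)
  if (is.null(edges)) {
    edges <- unname(stats::quantile(defined, probs = seq(0, 1, length.out = k + 1),
                                    type = 7, names = FALSE))
    if (anyDuplicated(edges))
      stop("degenerate support: quantile bin edges are not distinct; ",
           "supply `edges` or reduce `k`", call. = FALSE)
  } else {
    edges <- as.numeric(edges)
    if (length(edges) != k + 1L || is.unsorted(edges, strictly = TRUE))
      stop("`edges` must be ", k + 1L, " strictly increasing boundaries",
           call. = FALSE)
  }
  support <- biomarker_support(0:(k - 1), edges = edges,
                               undefined_code = undefined_code)
  list(support = support, levels = bin_values(values, support))
}

# Map numeric values onto a support's levels: by edges when present
# (clamping outside values into the first/last bin), else by nearest level.
bin_values <- function(values, support) {
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  if (!any(ok)) return(out)
  if (!is.null(support$edges)) {
    idx <- findInterval(values[ok], support$edges,
                        rightmost.closed = TRUE, all.inside = TRUE)
  } else {
    idx <- vapply(values[ok], function(v) which.min(abs(support$levels - v)),
                  integer(1))
  }
  out[ok] <- support$levels[idx]
  out
}

#' Serialize / deserialize a biomarker support as JSON
#'
#' @param support A [biomarker_support].
#' @param path File path.
#' @return `read_support` returns a [biomarker_support]; `write_support`
#'   returns `path` invisibly.
#' @export
write_support <- function(support, path) {
  stopifnot(inherits(support, "biomarker_support"))
  jsonlite::write_json(list(levels = support$levels, edges = support$edges,
                            undefined_code = support$undefined_code),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_support
#' @export
read_support <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  biomarker_support(x$levels, edges = x$edges, undefined_code = x$undefined_code)
}
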