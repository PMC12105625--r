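# Theory-versus-experiment calibration: OLS benchmark regression, signed
# and unsigned error metrics, censored-value policies, and the
# slope-and-anchor linear adjustment of computed potentials.

#' Paired theoretical/experimental observations
#'
#' @param compound Compound labels.
#' @param theoretical,experimental Values in the same unit (V or eV).
#' @param censoring Per-entry flag, `"exact"` or `"lower_bound"` (an
#'   experimental value reported only as "greater than").
#' @return A data.frame of class `paired_observations`.
#' @export
paired_observations <- function(compound, theoretical, experimental,
                                censoring = "exact") {
  n <- length(compound)
  stopifnot(n >= 2, length(theoretical) == n, length(experimental) == n,
            all(is.finite(theoretical)), all(is.finite(experimental)))
  censoring <- rep_len(censoring, n)
  if (!all(censoring %in% c("exact", "lower_bound")))
    stop("censoring flags must be 'exact' or 'lower_bound'")
  df <- data.frame(compound = as.character(compound),
                   theoretical = theoretical, experimental = experimental,
                   censoring = censoring, stringsAsFactors = FALSE)
  class(df) <- c("paired_observations", "data.frame")
  df
}

#' Resolve censored experimental entries before regression
#'
#' `at_bound` replaces a lower-bound entry by its bound value (the printed
#' ">x" becomes x); `drop` removes the entry. The applied policy is
#' recorded in the `bounds_policy` attribute.
#'
#' @param pairs A [paired_observations()] table.
#' @param policy `"at_bound"` or `"drop"`.
#' @return The resolved table (all entries flagged `"exact"`).
#' @export
resolve_bounds <- function(pairs, policy = c("at_bound", "drop")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(pairs))
  censored <- pairs$censoring == "lower_bound"
  out <- if (policy == "drop") pairs[!censored, , drop = FALSE] else pairs
  out$censoring <- "exact"
  rownames(out) <- NULL
  attr(out, "bounds_policy") <- policy
  out
}

#' Ordinary least-squares calibration of theory against experiment
#'
#' Fits experimental = slope * theoretical + intercept by OLS and reports
#' the squared Pearson correlation together with the signed mean error
#' (MSE, theoretical - experimental), mean unsigned error (MUE) and root
#' mean square error (RMSE).
#'
#' @param pairs A [paired_observations()] table with all censored entries
#'   resolved (see [resolve_bounds()]).
#' @return A `regression_fit` list: `slope`, `intercept`, `r_squared`,
#'   `mse`, `mue`, `rmse`, `n`.
#' @export
fit_linear <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 3)
  if (any(pairs$censoring != "exact"))
    stop("censored entries present; resolve them with resolve_bounds() first")
  if (stats::var(pairs$theoretical) == 0)
    stop("theoretical values have zero variance; no line can be fitted")
  fit <- stats::lm(experimental ~ theoretical, data = pairs)
  met <- error_metrics(pairs)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = stats::cor(pairs$theoretical, pairs$experimental)^2,
         mse = met$mse, mue = met$mue, rmse = met$rmse, n = nrow(pairs)),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "regression_fit (n = %d): slope %.3f, intercept %+.3f, R2 %.3f\n  MSE %+.3f  MUE %.3f  RMSE %.3f\n",
    x$n, x$slope, x$intercept, x$r_squared, x$mse, x$mue, x$rmse))
  invisible(x)
}

#' Signed and unsigned error metrics of a theory/experiment pairing
#'
#' @param pairs A [paired_observations()] table.
#' @return A list with `mse` (mean of theoretical - experimental), `mue`
#'   (mean absolute deviation) and `rmse`.
#' @export
error_metrics <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  d <- pairs$theoretical - pairs$experimental
  list(mse = mean(d), mue = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Slope-and-anchor adjustment rule
#'
#' @param slope_factor Multiplicative slope (typically a benchmark
#'   regression slope).
#' @param anchor_compound Label of the anchor compound.
#' @param anchor_experimental Its experimental potential, V.
#' @return An `adjustment_rule` list.
#' @export
adjustment_rule <- function(slope_factor, anchor_compound,
                            anchor_experimental) {
  stopifnot(is.finite(slope_factor), is.finite(anchor_experimental),
            is.character(anchor_compound), length(anchor_compound) == 1)
  structure(list(slope_factor = slope_factor,
                 anchor_compound = anchor_compound,
                 anchor_experimental = anchor_experimental),
            class = "adjustment_rule")
}

#' Linear adjustment of raw computed potentials
#'
#' Scales each raw value by the rule's slope factor and shifts the whole
#' series so that the anchor compound lands exactly on its experimental
#' value: intercept = E_exp(anchor) - slope * raw(anchor), adjusted(c) =
#' slope * raw(c) + intercept.
#'
#' @param raw_values Named numeric vector of raw potentials, V, containing
#'   the anchor compound.
#' @param rule An [adjustment_rule()].
#' @return A list with `adjusted` (named vector), `scaled` (slope-only
#'   values, before anchoring), `derived_intercept` and the `rule`.
#' @export
linear_adjust <- function(raw_values, rule) {
  stopifnot(inherits(rule, "adjustment_rule"), is.numeric(raw_values),
            !is.null(names(raw_values)))
  if (!rule$anchor_compound %in% names(raw_values))
    stop("anchor compound '", rule$anchor_compound,
         "' is missing from raw_values")
  scaled <- rule$slope_factor * raw_values
  intercept <- rule$anchor_experimental - scaled[[rule$anchor_compound]]
  list(adjusted = scaled + intercept, scaled = scaled,
       derived_intercept = intercept, rule = rule)
}
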