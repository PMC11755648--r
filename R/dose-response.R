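#' Dose-response series
#'
#' Container for a single dose-response experiment: either bacterial
#' viability (% of the zero-dose control OD600, doses in mg/L) or
#' Aliivibrio fischeri luminescence inhibition at 15 min (% inhibition,
#' doses as sample dilution in % v/v).
#'
#' @param dose strictly positive doses (logarithms are taken).
#' @param response percent response, finite.
#' @param kind `"viability"` or `"luminescence_inhibition"`.
#' @param replicate optional replicate identifiers.
#' @return Data frame of class `"dose_response"` with a `kind` attribute.
#' @examples
#' dose_response(c(10, 100, 1000), c(90, 50, 10), kind = "viability")
#' @export
dose_response <- function(dose, response,
                          kind = c("viability", "luminescence_inhibition"),
                          replicate = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(dose) || any(!is.finite(dose)) || any(dose <= 0))
    stop("'dose' must be strictly positive (log scale is used)", call. = FALSE)
  if (!is.numeric(response) || any(!is.finite(response)))
    stop("'response' must be finite", call. = FALSE)
  if (length(dose) != length(response))
    stop("'dose' and 'response' must have equal length", call. = FALSE)
  if (length(unique(dose)) < 3L)
    stop("at least 3 distinct doses are required", call. = FALSE)
  df <- data.frame(dose = as.numeric(dose), response = as.numeric(response))
  df$replicate <- if (is.null(replicate)) "1" else as.character(replicate)
  structure(df, kind = kind, class = c("dose_response", "data.frame"))
}

# Shared log-linear machinery: response = a + b * log10(dose), solved at 50.
# The trend must be inhibitory (b < 0 for viability, b > 0 for inhibition).
loglinear_50 <- function(series, increasing) {
  fit <- stats::lm(response ~ log10(dose), data = series)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  # slopes within numerical noise of zero count as no trend
  if (!is.finite(b) || (increasing && b <= 1e-8) || (!increasing && b >= -1e-8))
    stop(errorCondition("no dose response: regression slope has the wrong sign or is zero",
                        class = c("ibpkin_no_dose_response", "error")))
  x50 <- 10^((50 - a) / b)
  extrap <- x50 < min(series$dose) || x50 > max(series$dose) ||
    !(min(series$response) <= 50 && max(series$response) >= 50)
  list(value = x50, intercept = a, slope = b, extrapolated = extrap,
       r2 = suppressWarnings(summary(fit)$r.squared))
}

#' Estimate IC50 from growth-viability data
#'
#' Ordinary least squares of viability (%) on log10 dose,
#' `viability = a + b * log10(dose)`, solved at 50% viability:
#' `IC50 = 10^((50 - a) / b)`.  This is the log-linear interpolation
#' used for growth inhibition of degrader strains; the slope must be
#' negative (viability falls with dose) or a condition of class
#' `"ibpkin_no_dose_response"` is signaled.  An IC50 outside the tested
#' dose range, or responses that do not bracket 50%, set the
#' `extrapolated` flag.
#'
#' @param series a [dose_response()] of kind `"viability"`.
#' @return List of class `"ic50_estimate"`: `ic50` (mg/L), regression
#'   `intercept` and `slope`, `extrapolated` flag and regression `r2`.
#' @examples
#' s <- dose_response(c(10, 100, 1000), c(90, 50, 10), kind = "viability")
#' estimate_ic50(s)$ic50 # 100
#' @export
estimate_ic50 <- function(series) {
  stopifnot(inherits(series, "dose_response"))
  if (attr(series, "kind") != "viability")
    stop("estimate_ic50 expects a viability series", call. = FALSE)
  res <- loglinear_50(series, increasing = FALSE)
  structure(list(ic50 = res$value, intercept = res$intercept,
                 slope = res$slope, extrapolated = res$extrapolated,
                 r2 = res$r2),
            class = "ic50_estimate")
}

#' Estimate EC50 from luminescence-inhibition data
#'
#' The same log-linear machinery as [estimate_ic50()] applied to Microtox
#' serial-dilution data: inhibition (%) regressed on log10 of the dilution
#' (% v/v) and solved at 50% inhibition.  The slope must be positive
#' (inhibition grows with dose).
#'
#' @param series a [dose_response()] of kind `"luminescence_inhibition"`
#'   with doses as dilution percentages.
#' @return List of class `"ec50_estimate"` with `ec50` (% v/v) and the same
#'   regression fields as [estimate_ic50()].
#' @examples
#' s <- dose_response(c(12.5, 25, 50, 100), c(20, 35, 50, 65),
#'                    kind = "luminescence_inhibition")
#' estimate_ec50(s)$ec50 # 50
#' @export
estimate_ec50 <- function(series) {
  stopifnot(inherits(series, "dose_response"))
  if (attr(series, "kind") != "luminescence_inhibition")
    stop("estimate_ec50 expects a luminescence-inhibition series", call. = FALSE)
  res <- loglinear_50(series, increasing = TRUE)
  structure(list(ec50 = res$value, intercept = res$intercept,
                 slope = res$slope, extrapolated = res$extrapolated,
                 r2 = res$r2),
            class = "ec50_estimate")
}

#' @export
print.ic50_estimate <- function(x, ...) {
  cat(sprintf("IC50 = %.4g mg/L%s (viability = %.2f %+.2f*log10(dose), R2 = %.3f)\n",
              x$ic50, if (x$extrapolated) " [extrapolated]" else "",
              x$intercept, x$slope, x$r2))
  invisible(x)
}

#' @export
print.ec50_estimate <- function(x, ...) {
  cat(sprintf("EC50 = %.4g %% v/v%s (inhibition = %.2f %+.2f*log10(dilution), R2 = %.3f)\n",
              x$ec50, if (x$extrapolated) " [extrapolated]" else "",
              x$intercept, x$slope, x$r2))
  invisible(x)
}

#' Toxic Units
#'
#' `TU = 100 / EC50` with EC50 in % v/v: the number of times the sample
#' must be diluted to halve the luminescence response.  Higher TU means a
#' more toxic undiluted sample; TU = 1 when the undiluted sample is exactly
#' at the EC50.
#'
#' @param ec50 EC50 as % v/v, strictly positive.
#' @return TU, dimensionless.
#' @examples
#' toxic_units(50)    # 2
#' toxic_units(44.44) # 2.25
#' @export
toxic_units <- function(ec50) {
  if (!is.numeric(ec50) || any(!is.finite(ec50)) || any(ec50 <= 0))
    stop("'ec50' must be strictly positive", call. = FALSE)
  100 / ec50
}

#' Persoone acute-toxicity classes
#'
#' Ordered factor levels of the hazard classification used for Microtox
#' results, from non-toxic to very highly toxic.
#' @export
PERSOONE_CLASSES <- c("no toxicity", "slight acute toxicity",
                      "acute toxicity", "high acute toxicity",
                      "very high acute toxicity")

#' Classify acute toxicity from Toxic Units
#'
#' Persoone hazard banding: TU < 0.4 no toxicity; 0.4 <= TU < 1 slight
#' acute; 1 <= TU < 10 acute; 10 <= TU < 100 high acute; TU >= 100 very
#' high acute.  Boundaries are left-closed so every non-negative TU maps to
#' exactly one class.
#'
#' @param tu Toxic Units, non-negative; vectorized.
#' @return Ordered factor with levels [PERSOONE_CLASSES].
#' @examples
#' classify_persoone(c(0.6, 5.68, 17.9))
#' @export
classify_persoone <- function(tu) {
  if (!is.numeric(tu) || any(!is.finite(tu)) || any(tu < 0))
    stop("'tu' must be non-negative", call. = FALSE)
  cut(tu, breaks = c(-Inf, 0.4, 1, 10, 100, Inf), right = FALSE,
      labels = PERSOONE_CLASSES, ordered_result = TRUE)
}

#' Full toxicity assessment of a Microtox series
#'
#' Runs [estimate_ec50()], converts to Toxic Units and assigns the Persoone
#' class, bundling the three into one record.
#'
#' @param series a [dose_response()] of kind `"luminescence_inhibition"`.
#' @return List of class `"toxicity_result"` with `ec50` (% v/v), `tu`,
#'   `persoone_class` and the underlying `ec50_estimate`.
#' @export
assess_toxicity <- function(series) {
  est <- estimate_ec50(series)
  tu <- toxic_units(est$ec50)
  structure(list(ec50 = est$ec50, tu = tu,
                 persoone_class = classify_persoone(tu),
                 estimate = est),
            class = "toxicity_result")
}

#' @export
print.toxicity_result <- function(x, ...) {
  cat(sprintf("EC50 = %.4g %% v/v, TU = %.3g: %s\n",
              x$ec50, x$tu, as.character(x$persoone_class)))
  invisible(x)
}

#' Read a dose-response CSV
#'
#' Columns `kind`, `dose`, `response` and optional `replicate`; `kind` must
#' be constant within the file.
#'
#' @param path file path.
#' @return A [dose_response()].
#' @export
read_dose_response_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("kind", "dose", "response"), names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  kind <- unique(raw$kind)
  if (length(kind) != 1L)
    stop("'kind' must be constant within one file", call. = FALSE)
  dose_response(as.numeric(raw$dose), as.numeric(raw$response), kind = kind,
                replicate = if ("replicate" %in% names(raw)) raw$replicate)
}
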