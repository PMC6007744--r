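## Sedimentation-velocity species bookkeeping: per-point buffer
## standardization, infinite-dilution extrapolation with 95% confidence
## intervals, species-fraction summaries, CSV interchange.

#' Extrapolate a species series to infinite dilution
#'
#' Linear least squares of an apparent quantity (s or M) against loading
#' concentration; the intercept is the infinite-dilution value. With
#' \code{weighted = TRUE} (the default when uncertainties are available)
#' points are weighted by inverse variance. 95\% confidence intervals come
#' from the t distribution on n - 2 degrees of freedom. Points above
#' \code{excludeAbove} (e.g. concentrations showing non-ideal
#' sedimentation) can be excluded explicitly; the function never drops
#' points silently.
#'
#' @param series A \linkS4class{SpeciesSeries}.
#' @param quantity "s" (default) or "M".
#' @param weighted Inverse-variance weighting; default TRUE when all
#'   uncertainties are positive. Zero/missing uncertainties fall back to
#'   unweighted fitting with a warning.
#' @param excludeAbove Optional concentration cutoff, mg/ml.
#' @return An \linkS4class{ExtrapolationResult}.
#' @examples
#' ser <- simulateSVSeries(2.70, 0.005, 12.77, 0.9, c(1, 2, 4))
#' extrapolateToZeroConc(ser) # intercept 2.70 exactly
#' @export
extrapolateToZeroConc <- function(series, quantity = c("s", "M"),
                                  weighted = NULL, excludeAbove = NULL) {
  stopifnot(is(series, "SpeciesSeries"))
  quantity <- match.arg(quantity)
  r <- series@records
  if (!is.null(excludeAbove)) r <- r[r$conc_mg_ml <= excludeAbove, , drop = FALSE]
  if (nrow(r) < 2L) stop("need at least 2 concentrations to extrapolate")
  y <- if (quantity == "s") r$s_app_S else r$M_kDa
  sd <- if (quantity == "s") r$s_sd else r$M_sd
  if (is.null(weighted)) weighted <- all(is.finite(sd)) && all(sd > 0)
  if (weighted && (!all(is.finite(sd)) || any(sd <= 0))) {
    warning("zero or missing uncertainties; falling back to unweighted fit")
    weighted <- FALSE
  }
  fit <- if (weighted) stats::lm(y ~ conc, data.frame(y = y, conc = r$conc_mg_ml),
                                 weights = 1 / sd^2)
         else stats::lm(y ~ conc, data.frame(y = y, conc = r$conc_mg_ml))
  cf <- stats::coef(fit)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  ci[!is.finite(ci)] <- rep(cf, 2L)[!is.finite(ci)]  # exact fits: zero width
  new("ExtrapolationResult", quantity = quantity,
      intercept = unname(cf[1L]), interceptCI = unname(ci[1L, ]),
      slope = unname(cf[2L]), slopeCI = unname(ci[2L, ]),
      nPoints = nrow(r), weighted = weighted,
      standardized = series@standardized)
}

#' Standardize a species series to water at 20 C
#'
#' Applies the buffer correction factor of \code{\link{standardizeS}} to
#' every apparent sedimentation coefficient and its uncertainty (masses
#' are untouched) and flags the series as standardized. Because the factor
#' is concentration-independent, standardization and infinite-dilution
#' extrapolation commute.
#'
#' @param series A \linkS4class{SpeciesSeries} with buffer and vbar set.
#' @return The standardized \linkS4class{SpeciesSeries}.
#' @export
standardizeSeries <- function(series) {
  stopifnot(is(series, "SpeciesSeries"))
  if (series@standardized) return(series)
  factor <- standardizeS(1, series@buffer, series@vbar)
  series@records$s_app_S <- series@records$s_app_S * factor
  series@records$s_sd <- series@records$s_sd * factor
  series@standardized <- TRUE
  series
}

#' Species-fraction summary
#'
#' Per-species minimum, maximum and mean molecular fraction across the
#' shared concentration grid. The fractions of all species at each
#' concentration must sum to 1 within \code{tolerance}; violations raise a
#' validation error listing the offending concentrations.
#'
#' @param seriesList List of \linkS4class{SpeciesSeries} on the same
#'   concentration grid.
#' @param tolerance Allowed deviation of the per-concentration fraction
#'   sum from 1 (default 0.02).
#' @return data.frame with columns species, min, max, mean.
#' @export
fractionSummary <- function(seriesList, tolerance = 0.02) {
  stopifnot(length(seriesList) >= 1L,
            all(vapply(seriesList, is, logical(1L), "SpeciesSeries")))
  grids <- lapply(seriesList, function(s) sort(s@records$conc_mg_ml))
  if (!all(vapply(grids, function(g)
        isTRUE(all.equal(g, grids[[1L]])), logical(1L))))
    stop("all series must share the same concentration grid")
  conc <- grids[[1L]]
  fr <- vapply(seriesList, function(s) {
    r <- s@records
    r$fraction[order(r$conc_mg_ml)]
  }, numeric(length(conc)))
  fr <- matrix(fr, nrow = length(conc))
  sums <- rowSums(fr)
  bad <- abs(sums - 1) > tolerance
  if (any(bad))
    stop("species fractions do not sum to 1 at concentration(s) ",
         paste(conc[bad], collapse = ", "),
         " (sums ", paste(sprintf("%.3f", sums[bad]), collapse = ", "), ")")
  data.frame(
    species = vapply(seriesList, function(s) s@speciesLabel, character(1L)),
    min = apply(fr, 2L, min), max = apply(fr, 2L, max),
    mean = colMeans(fr), stringsAsFactors = FALSE)
}

#' Read / write species-series CSV
#'
#' Tabular interchange for per-concentration species results, with columns
#' conc_mg_ml, s_app_S, s_sd, M_kDa, M_sd, fraction, fraction_sd.
#'
#' @param path CSV path.
#' @param speciesLabel Label attached to the series.
#' @param buffer \linkS4class{SolventConditions} attached to the series.
#' @param vbar Partial specific volume, cm^3/g.
#' @return \code{readSpeciesSeries}: a \linkS4class{SpeciesSeries};
#'   \code{writeSpeciesSeries}: invisibly, \code{path}.
#' @export
readSpeciesSeries <- function(path, speciesLabel = "other",
                              buffer = waterAt20C(), vbar = 0.541) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(r$fraction_sd)) r$fraction_sd <- 0
  new("SpeciesSeries", records = r, speciesLabel = speciesLabel,
      buffer = buffer, vbar = vbar, vbarSD = 0, standardized = FALSE)
}

#' @rdname readSpeciesSeries
#' @param series A \linkS4class{SpeciesSeries}.
#' @export
writeSpeciesSeries <- function(series, path) {
  utils::write.csv(series@records, path, row.names = FALSE)
  invisible(path)
}
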