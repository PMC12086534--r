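#' Fit a linear calibration curve
#'
#' Ordinary least-squares line of instrument response against known quantity,
#' as used both for internal-standard concentration curves and for body-water
#' enrichment standards. Slope, intercept and the correlation coefficient r
#' are returned, mirroring routine assay reporting.
#'
#' @param known Known quantities (>= 2 distinct values).
#' @param response Measured responses (analyte/IS area ratio, or acetone
#'   signal ratio).
#' @param weights `"none"` (default) or `"1/x"` for inverse-quantity
#'   weighting.
#' @param require_positive_slope All shipped assays respond positively;
#'   a non-positive fitted slope is rejected unless this is `FALSE`.
#' @return Object of class `"calibration_curve"`: list with `slope`,
#'   `intercept`, `r`, `r2`, `range` (of known quantities), `n_points`.
#' @export
#' @examples
#' fit_calibration(0:3, c(0.01, 1.02, 1.98, 3.01))
fit_calibration <- function(known, response,
                            weights = c("none", "1/x"),
                            require_positive_slope = TRUE) {
  weights <- match.arg(weights)
  stopifnot(length(known) == length(response), length(known) >= 2)
  if (length(unique(known)) < 2) stop("degenerate calibration: identical known quantities")
  w <- if (weights == "1/x") 1 / pmax(known, min(known[known > 0])) else NULL
  fit <- stats::lm(response ~ known, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  flat <- stats::sd(response) < 1e-12 * max(abs(response), 1)
  if (require_positive_slope && (flat || slope <= 0))
    stop("calibration slope is not positive (flat or inverted response)")
  r <- suppressWarnings(stats::cor(known, response))
  structure(list(slope = slope, intercept = intercept,
                 r = r, r2 = r^2,
                 range = range(known), n_points = length(known)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> response = %.6g x + %.6g (r = %.5f, %d pts, range [%g, %g])\n",
              x$slope, x$intercept, x$r, x$n_points, x$range[1], x$range[2]))
  invisible(x)
}

#' Invert a calibration curve at a measured response
#'
#' @param curve A `"calibration_curve"`.
#' @param response Measured response(s).
#' @return Quantities; attribute `"flags"` lists `"extrapolated"` for
#'   responses inverting outside the standards' range.
#' @export
invert_calibration <- function(curve, response) {
  q <- (response - curve$intercept) / curve$slope
  flags <- ifelse(q < curve$range[1] - 1e-12 | q > curve$range[2] + 1e-12,
                  "extrapolated", "")
  structure(q, flags = flags)
}

#' Body-water deuterium enrichment from acetone-exchange standards
#'
#' Serum deuterium exchanges into acetone; gravimetric standards of known
#' 2H mol-fraction excess define a linear signal-ratio calibration which is
#' inverted at each sample's ratio.
#'
#' @param sample_ratio Acetone signal ratio(s) for the sample(s).
#' @param standards Data frame with columns `known_frac` (2H mol-fraction
#'   excess, in `[0, 0.10]`) and `ratio`.
#' @param allow_extrapolation If `FALSE` (default) a sample outside the
#'   standards' range is still returned but flagged `"extrapolated_p"`.
#' @return Numeric vector of 2H mol-fraction excess values with attribute
#'   `"flags"`.
#' @export
water_enrichment <- function(sample_ratio, standards,
                             allow_extrapolation = FALSE) {
  stopifnot(all(c("known_frac", "ratio") %in% names(standards)))
  if (nrow(standards) < 2) stop("need at least 2 water standards")
  if (any(standards$known_frac < 0 | standards$known_frac > 0.10))
    stop("water standards must lie in [0, 0.10] mol-fraction excess")
  curve <- fit_calibration(standards$known_frac, standards$ratio)
  p <- invert_calibration(curve, sample_ratio)
  flags <- ifelse(attr(p, "flags") == "extrapolated", "extrapolated_p", "")
  if (!allow_extrapolation && any(flags != ""))
    warning("sample ratio outside the standards' range; extrapolated")
  structure(as.numeric(p), flags = flags, curve = curve)
}

#' Concentration from analyte/internal-standard peak areas
#'
#' Response = analyte area / internal-standard area; concentration =
#' (response - intercept) / slope. Negative concentrations (blank-level
#' responses below the curve intercept) are floored at 0 and flagged rather
#' than rejected.
#'
#' @param analyte_area,is_area Peak areas; `is_area` must be positive.
#' @param curve A `"calibration_curve"` whose response is the area ratio.
#' @return Concentrations with attribute `"flags"` (`"negative_conc"` where
#'   floored).
#' @export
quantify <- function(analyte_area, is_area, curve) {
  if (any(is_area <= 0)) stop("internal standard missing (area <= 0)")
  conc <- (analyte_area / is_area - curve$intercept) / curve$slope
  flags <- ifelse(conc < 0, "negative_conc", "")
  structure(pmax(conc, 0), flags = flags)
}

#' Body-mass-normalized total compartment content
#'
#' Concentration x compartment mass / body mass: total intestinal or fecal
#' bile acid (or fecal energy) corrected for body weight.
#'
#' @param concentration Analyte concentration (per gram of compartment).
#' @param compartment_mass Total compartment mass (g).
#' @param body_mass Body mass (g).
#' @return Total per gram body mass.
#' @export
total_content <- function(concentration, compartment_mass, body_mass) {
  if (any(is.na(concentration)) || any(is.na(compartment_mass)) ||
      any(is.na(body_mass)))
    stop("missing field: concentration, compartment_mass and body_mass are required")
  stopifnot(all(concentration >= 0), all(compartment_mass > 0),
            all(body_mass > 0))
  concentration * compartment_mass / body_mass
}
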