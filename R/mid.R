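#' Mass isotopomer distribution (MID)
#'
#' The central data structure of the package: fractional abundances of an ion's
#' isotopologues at mass shifts m0..mK, together with the probability mass
#' beyond mK (`truncated_mass`). Values are non-negative and
#' `sum(values) + truncated_mass == 1` within tolerance.
#'
#' @param values Numeric vector of fractions indexed by mass shift 0..K.
#' @param truncated_mass Probability beyond shift K; defaults to
#'   `1 - sum(values)`.
#' @return An object of class `"mid"` (a list with `values` and
#'   `truncated_mass`).
#' @export
#' @examples
#' mid(c(0.9, 0.08, 0.015, 0.005))
mid <- function(values, truncated_mass = NULL) {
  values <- as.numeric(values)
  if (is.null(truncated_mass)) truncated_mass <- 1 - sum(values)
  if (abs(truncated_mass) < 1e-12) truncated_mass <- max(truncated_mass, 0)
  out <- structure(list(values = values, truncated_mass = truncated_mass),
                   class = "mid")
  validate_mid(out)
  out
}

validate_mid <- function(x) {
  v <- x$values
  if (any(v < -1e-12)) stop("MID values must be non-negative")
  if (x$truncated_mass < -1e-12) stop("MID truncated_mass must be non-negative")
  if (abs(sum(v) + x$truncated_mass - 1) > 1e-9)
    stop("MID values + truncated_mass must sum to 1 (got ",
         format(sum(v) + x$truncated_mass, digits = 12), ")")
  invisible(x)
}

#' @export
print.mid <- function(x, ...) {
  k <- seq_along(x$values) - 1L
  cat("<mid> ", paste0("m", k, "=", signif(x$values, 5), collapse = " "),
      if (x$truncated_mass > 0)
        paste0(" (truncated beyond m", max(k), ": ",
               signif(x$truncated_mass, 4), ")"),
      "\n", sep = "")
  invisible(x)
}

#' @rdname mid
#' @param x A `mid` object.
#' @export
mid_values <- function(x) {
  if (inherits(x, "mid")) x$values else as.numeric(x)
}

as_mid <- function(x) {
  if (inherits(x, "mid")) x else mid(x)
}

#' Convolve two mass isotopomer distributions
#'
#' Truncated convolution: the result keeps shifts 0..K (K taken from the
#' inputs, which must agree in length) and accumulates everything beyond K
#' into `truncated_mass`. Mass already truncated in either input stays
#' truncated, so the bookkeeping is exact.
#'
#' @param a,b `mid` objects (or plain fraction vectors) of equal length.
#' @return A `mid` of the same length.
#' @export
convolve_mid <- function(a, b) {
  va <- mid_values(a); vb <- mid_values(b)
  if (length(va) != length(vb))
    stop("convolve_mid: inputs must have the same length")
  K <- length(va) - 1L
  out <- numeric(K + 1L)
  for (i in 0:K) {
    # mass shift i = sum over j of a[j] * b[i - j]
    j <- 0:i
    out[i + 1L] <- sum(va[j + 1L] * vb[i - j + 1L])
  }
  mid(out)
}

# distribution of one atom of `element`, truncated at K
element_pattern <- function(element, K, isotopes = isotope_table()) {
  rows <- isotopes[isotopes$element == element, , drop = FALSE]
  if (!nrow(rows))
    stop("unknown element symbol in formula: ", element)
  v <- numeric(K + 1L)
  keep <- rows$mass_shift <= K
  v[rows$mass_shift[keep] + 1L] <- rows$abundance[keep]
  mid(v)
}

#' Natural-abundance MID of an elemental formula
#'
#' Computes the mass-shift distribution of an ion at natural isotope
#' abundance by repeated convolution of per-atom isotope patterns, truncated
#' at shift `K` with the excess recorded in `truncated_mass`.
#'
#' @param formula Formula string in Hill notation (e.g. `"C16H31O2"`) or a
#'   named count vector.
#' @param K Highest mass shift retained (default 3, matching m0--m3
#'   acquisition).
#' @param isotopes Isotope abundance table, see [isotope_table()].
#' @return A `mid` of length `K + 1`.
#' @export
#' @examples
#' natural_mid("C16H31O2")
natural_mid <- function(formula, K = 3L, isotopes = isotope_table()) {
  stopifnot(K >= 1)
  counts <- parse_formula(formula)
  acc <- mid(c(1, numeric(K)))  # empty convolution is the identity
  for (el in names(counts)) {
    pat <- element_pattern(el, K, isotopes)
    for (i in seq_len(counts[[el]])) acc <- convolve_mid(acc, pat)
  }
  acc
}
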