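#' Natural isotope abundance table
#'
#' Returns the packaged table of stable-isotope abundances used throughout the
#' package. One row per isotope: element symbol, nominal mass shift relative to
#' the lightest isotope, and fractional abundance. The shipped table carries
#' IUPAC representative values for C, H, N, O and S, which cover the monitored
#' ions of the default analyte panel (taurine-conjugated bile acid anions, the
#' palmitate carboxylate ion, and the m/z 247 cholesterol fragment).
#'
#' @param path Optional path to an alternative CSV with columns
#'   `element`, `mass_shift`, `abundance`. Abundances must sum to 1 per element.
#' @return A data.frame with columns `element`, `mass_shift`, `abundance`.
#' @export
#' @examples
#' head(isotope_table())
isotope_table <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .d2o_cache$isotopes
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "isotopes.csv", package = "d2otrace",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    validate_isotope_table(tab)
    .d2o_cache$isotopes <- tab
    return(tab)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_isotope_table(tab)
  tab
}

.d2o_cache <- new.env(parent = emptyenv())

validate_isotope_table <- function(tab) {
  stopifnot(all(c("element", "mass_shift", "abundance") %in% names(tab)))
  if (any(tab$mass_shift < 0) || any(tab$abundance < 0 | tab$abundance > 1))
    stop("isotope table has out-of-range mass shifts or abundances")
  sums <- tapply(tab$abundance, tab$element, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-12]
  if (length(bad))
    stop("isotope abundances do not sum to 1 for element(s): ",
         paste(bad, collapse = ", "))
  for (el in unique(tab$element)) {
    sh <- tab$mass_shift[tab$element == el]
    if (sh[1] != 0 || is.unsorted(sh, strictly = TRUE))
      stop("isotope mass shifts must start at 0 and increase for element ", el)
  }
  invisible(tab)
}

#' Natural 2H abundance of the configured isotope table
#' @param isotopes Isotope table, see [isotope_table()].
#' @return Fractional abundance of deuterium.
#' @export
natural_2h_abundance <- function(isotopes = isotope_table()) {
  x <- isotopes[isotopes$element == "H" & isotopes$mass_shift == 1, "abundance"]
  if (!length(x)) 0 else x
}

#' Parse an elemental formula in Hill notation
#'
#' Converts a formula string such as `"C26H44NO7S"` into a named vector of
#' per-element atom counts. A missing count means 1 (`"N"` is one nitrogen).
#'
#' @param x Formula string, or an already-parsed named count vector (returned
#'   unchanged after validation).
#' @return Named integer vector of atom counts.
#' @export
#' @examples
#' parse_formula("C16H31O2")
parse_formula <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x)) || any(x < 0) || any(x != round(x)))
      stop("formula counts must be a named non-negative integer vector")
    return(x[x > 0])
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  pieces <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(nchar(pieces)) != nchar(x))
    stop("cannot parse formula: ", x)
  els <- sub("[0-9]*$", "", pieces)
  cnt <- as.integer(ifelse(grepl("[0-9]", pieces),
                           sub("^[A-Za-z]+", "", pieces), "1"))
  counts <- tapply(cnt, els, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

# remove n hydrogens from a parsed formula (used by the replace-exchange-H
# forward-model variant)
formula_drop_h <- function(counts, n) {
  counts <- parse_formula(counts)
  h <- counts["H"]
  if (is.na(h) || h < n)
    stop("formula has fewer hydrogens (", ifelse(is.na(h), 0, h),
         ") than the requested exchangeable count (", n, ")")
  counts["H"] <- h - n
  counts[counts > 0]
}
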