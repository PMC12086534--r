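#' Build a natural-abundance correction matrix
#'
#' Assembles the lower-triangular operator that maps a label-only isotopologue
#' distribution onto the observed, natural-abundance-convolved distribution.
#' Column j is the natural MID shifted down by j rows, so applying the matrix
#' performs the truncated convolution with the natural distribution, and
#' solving against it removes the natural-isotope contribution. The natural
#' MID may be theoretical (from [natural_mid()]) or empirical (measured on
#' unlabeled baseline samples, see [average_baseline_mids()]).
#'
#' @param natural A `mid` (or fraction vector) of length K+1; must have
#'   positive m0.
#' @param provenance `"theoretical"` or `"empirical"` -- recorded on the
#'   matrix for audit.
#' @return A (K+1) x (K+1) lower-triangular matrix with attribute
#'   `"provenance"`.
#' @export
#' @examples
#' build_correction_matrix(natural_mid("C16H31O2"))
build_correction_matrix <- function(natural,
                                    provenance = c("theoretical", "empirical")) {
  provenance <- match.arg(provenance)
  v <- mid_values(as_mid(natural))
  if (v[1] <= 0)
    stop("natural MID has m0 = 0; correction matrix would be singular")
  K <- length(v) - 1L
  M <- matrix(0, K + 1L, K + 1L)
  for (j in 0:K) M[(j:K) + 1L, j + 1L] <- v[seq_len(K - j + 1L)]
  attr(M, "provenance") <- provenance
  M
}

#' Average unlabeled baseline spectra into an empirical natural MID
#'
#' Each row of raw intensities is normalized to fractions, then the rows are
#' averaged. Pooling several unlabeled samples damps baseline noise before
#' the correction matrix is built.
#'
#' @param raws Numeric matrix (or single vector): one row of m0..mK
#'   intensities per unlabeled sample.
#' @return A `mid`.
#' @export
average_baseline_mids <- function(raws) {
  if (is.null(dim(raws))) raws <- matrix(raws, nrow = 1)
  if (any(raws < 0)) stop("baseline intensities must be non-negative")
  rs <- rowSums(raws)
  if (any(rs <= 0)) stop("empty spectrum in baseline table")
  mid(colMeans(raws / rs))
}

#' Correct raw isotopologue intensities for natural abundance
#'
#' Normalizes the raw m0..mK intensities to fractions and solves
#' `correction %*% x = raw_normalized` for the label-only distribution `x`.
#' The default solver is non-negative least squares, which guards against
#' noise-induced negative isotopologue fractions; plain triangular
#' back-substitution is available via `method = "solve"`. The solution is
#' renormalized to sum to 1.
#'
#' @param raw Non-negative intensity vector m0..mK (any positive scale; the
#'   result is invariant to rescaling).
#' @param correction Matrix from [build_correction_matrix()].
#' @param method `"nnls"` (default) or `"solve"`.
#' @param tol Residual tolerance; a larger solver residual is recorded as a
#'   `"high_residual"` flag rather than an error.
#' @return A `mid` carrying attributes `residual` (L2 norm of the solver
#'   residual on normalized fractions) and `flags` (character vector).
#' @export
correct_mid <- function(raw, correction, method = c("nnls", "solve"),
                        tol = 1e-8) {
  method <- match.arg(method)
  raw <- as.numeric(raw)
  if (length(raw) != ncol(correction))
    stop("raw vector length does not match correction matrix size")
  if (any(raw < 0)) stop("raw intensities must be non-negative")
  if (sum(raw) <= 0) stop("empty spectrum")
  y <- raw / sum(raw)
  if (method == "nnls") {
    fit <- pracma::lsqnonneg(correction, y)
    x <- fit$x
  } else {
    x <- forwardsolve(correction, y)
  }
  resid <- sqrt(sum((correction %*% pmax(x, 0) - y)^2))
  flags <- character(0)
  if (method == "solve" && any(x < -tol)) flags <- c(flags, "negative_fraction")
  x <- pmax(x, 0)
  if (sum(x) <= 0) stop("correction produced an all-zero distribution")
  if (resid > tol) flags <- c(flags, "high_residual")
  out <- mid(x / sum(x), truncated_mass = 0)
  attr(out, "residual") <- resid
  attr(out, "flags") <- flags
  out
}
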