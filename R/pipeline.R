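#' Run the full tracer analysis over a study
#'
#' End-to-end orchestration of the measurement model's inverse: body-water
#' calibration, per-analyte natural-abundance correction (empirical baseline
#' by default, theoretical from the formula otherwise), deuterium enrichment,
#' fractional synthesis, internal-standard quantification and
#' newly-synthesized pool amounts. One tidy row per sample x analyte; every
#' row carries provenance (correction mode, p source, solver residual,
#' flags). Deterministic given its inputs.
#'
#' @param study A `"synthetic_study"` (from [simulate_study()] /
#'   [read_study()]) or a directory of its CSV tables.
#' @param correction `"empirical"` (average of unlabeled baseline spectra;
#'   default when a baseline table exists) or `"theoretical"` (from the
#'   analyte formula).
#' @param p_source `"per_animal"` (each sample's own acetone measurement,
#'   falling back to the cohort mean when absent) or `"cohort_mean"`.
#' @param truncation Fractional-synthesis estimator: `"correct"` (default;
#'   exact inversion of the m0..mK-truncated binomial) or `"none"` (the plain
#'   enrichment / (p n) ratio).
#' @param method Correction solver passed to [correct_mid()].
#' @param K Highest mass shift; defaults to the study's acquired channels.
#' @param tol Solver residual tolerance.
#' @return Tibble with corrected m0..mK fractions, `enrichment`, `p`,
#'   `n`, `f_pct`, `conc_ug_g`, `new_ug_g`, `residual`, `flags` and
#'   provenance columns. Attribute `"qc"` holds the water and concentration
#'   calibration parameters for audit.
#' @export
#' @examples
#' res <- run_analysis(simulate_study(preset_study("vwr_mice")))
#' head(res)
run_analysis <- function(study,
                         correction = c("empirical", "theoretical"),
                         p_source = c("per_animal", "cohort_mean"),
                         truncation = c("correct", "none"),
                         method = c("nnls", "solve"),
                         K = NULL, tol = 1e-8) {
  if (is.character(study)) study <- read_study(study)
  correction <- if (is.null(study$baseline) && missing(correction))
    "theoretical" else match.arg(correction)
  p_source <- match.arg(p_source)
  truncation <- match.arg(truncation)
  method <- match.arg(method)
  panel <- study$panel
  if (is.null(K)) K <- study$K %||% 3L
  acols <- paste0("area_m", 0:K)
  stopifnot(all(acols %in% names(study$areas)))

  # --- body water enrichment ---------------------------------------------
  if (is.null(study$water_standards) || is.null(study$water_samples))
    stop("sample lacking p: no water-enrichment tables in study")
  p_all <- water_enrichment(study$water_samples$ratio, study$water_standards,
                            allow_extrapolation = TRUE)
  w_curve <- attr(p_all, "curve")
  p_flags <- attr(p_all, "flags")
  p_tab <- tibble::tibble(sample_id = study$water_samples$sample_id,
                          p = as.numeric(p_all), p_flag = p_flags)
  p_cohort <- mean(p_tab$p)

  # --- correction matrices per analyte -----------------------------------
  cms <- lapply(seq_len(nrow(panel)), function(a) {
    id <- panel$analyte_id[a]
    if (correction == "empirical") {
      bl <- study$baseline[study$baseline$analyte_id == id, acols, drop = FALSE]
      if (!nrow(bl)) stop("no baseline spectra for analyte ", id)
      build_correction_matrix(average_baseline_mids(as.matrix(bl)),
                              provenance = "empirical")
    } else {
      build_correction_matrix(natural_mid(panel$formula[a], K),
                              provenance = "theoretical")
    }
  })
  names(cms) <- panel$analyte_id

  # --- concentration calibration curves ----------------------------------
  curves <- NULL
  if (!is.null(study$curve_standards)) {
    curves <- lapply(split(study$curve_standards,
                           study$curve_standards$analyte_id),
                     function(d) fit_calibration(d$known_conc, d$response))
  }

  # --- per sample x analyte ----------------------------------------------
  ar <- study$areas
  miss <- setdiff(unique(ar$analyte_id), panel$analyte_id)
  if (length(miss))
    stop("missing analyte definition: ", paste(miss, collapse = ", "))
  n_by <- stats::setNames(panel$n_exchangeable, panel$analyte_id)

  out <- lapply(seq_len(nrow(ar)), function(i) {
    id <- ar$analyte_id[i]
    raw <- as.numeric(ar[i, acols])
    corr <- correct_mid(raw, cms[[id]], method = method, tol = tol)
    e <- analyte_enrichment(corr)
    j <- match(ar$sample_id[i], p_tab$sample_id)
    p_i <- if (p_source == "per_animal" && !is.na(j)) p_tab$p[j] else p_cohort
    p_used <- if (p_source == "per_animal" && !is.na(j)) "per_animal" else "cohort_mean"
    f <- fractional_synthesis(e, p_i, n_by[[id]], truncation = truncation, K = K)
    flags <- attr(corr, "flags")
    if (!is.na(j) && nzchar(p_tab$p_flag[j])) flags <- c(flags, p_tab$p_flag[j])
    if (f > 100) flags <- c(flags, "f_gt_100")
    conc <- NA_real_
    if (!is.null(curves) && id %in% names(curves)) {
      q <- quantify(sum(raw), ar$area_is[i], curves[[id]])
      conc <- as.numeric(q)
      if (nzchar(attr(q, "flags")[1])) flags <- c(flags, attr(q, "flags")[1])
    }
    tibble::tibble(
      sample_id = ar$sample_id[i], analyte_id = id,
      !!!stats::setNames(as.list(mid_values(corr)), paste0("m", 0:K)),
      enrichment = e, p = p_i, n = n_by[[id]], f_pct = f,
      conc_ug_g = conc, new_ug_g = new_pool_amount(f, conc),
      residual = attr(corr, "residual"),
      correction = correction, p_source = p_used,
      truncation = truncation,
      flags = paste(flags, collapse = ","))
  })
  res <- do.call(rbind, out)
  if (!is.null(study$metadata))
    res <- merge_metadata(res, study$metadata)
  attr(res, "qc") <- list(
    water_curve = unclass(w_curve)[c("slope", "intercept", "r")],
    p_cohort_mean = p_cohort,
    conc_curves = lapply(curves, function(cv) unclass(cv)[c("slope", "intercept", "r")]),
    correction = correction, p_source = p_source, truncation = truncation,
    K = K, solver = method)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merge_metadata <- function(res, metadata) {
  keep <- setdiff(names(metadata), names(res))
  m <- metadata[, c("sample_id", keep), drop = FALSE]
  out <- merge(as.data.frame(res), as.data.frame(m),
               by = "sample_id", all.x = TRUE, sort = FALSE)
  out <- out[order(match(paste(out$sample_id, out$analyte_id),
                         paste(res$sample_id, res$analyte_id))), ]
  tibble::as_tibble(out)
}

#' Estimate an analyte's exchangeable-hydrogen count from a study
#'
#' Pools the analyte's corrected MIDs across labeled samples and runs
#' [estimate_n()] at the cohort-mean body-water enrichment, returning the
#' pooled estimate, its residual profile over the candidate grid, and the
#' m2/m1 closed-form diagnostic.
#'
#' Pooling averages the samples' normalized raw spectra before the
#' non-negative correction; averaging first lets instrument noise cancel
#' before the non-negativity constraint can censor it, which keeps the pooled
#' estimate unbiased.
#'
#' @inheritParams run_analysis
#' @param analyte Analyte id present in the study's panel.
#' @param candidates Candidate grid (default 1:40).
#' @param per_sample Also return per-sample estimates (default `FALSE`;
#'   the pooled value is the per-analyte assignment).
#' @return An `"n_estimate"`; with `per_sample = TRUE` the element
#'   `n_hat_per_sample` is added.
#' @export
run_estimate_n <- function(study, analyte,
                           correction = c("empirical", "theoretical"),
                           candidates = 1:40, K = NULL,
                           method = c("nnls", "solve"),
                           per_sample = FALSE) {
  if (is.character(study)) study <- read_study(study)
  correction <- match.arg(correction)
  method <- match.arg(method)
  panel <- study$panel
  a <- match(analyte, panel$analyte_id)
  if (is.na(a)) stop("missing analyte definition: ", analyte)
  if (is.null(K)) K <- study$K %||% 3L
  acols <- paste0("area_m", 0:K)
  ar <- study$areas[study$areas$analyte_id == analyte, , drop = FALSE]
  if (!nrow(ar)) stop("no labeled samples for analyte ", analyte)
  cm <- if (correction == "empirical") {
    bl <- study$baseline[study$baseline$analyte_id == analyte, acols,
                         drop = FALSE]
    build_correction_matrix(average_baseline_mids(as.matrix(bl)), "empirical")
  } else {
    build_correction_matrix(natural_mid(panel$formula[a], K), "theoretical")
  }
  raws <- as.matrix(ar[, acols])
  pooled_raw <- colMeans(raws / rowSums(raws))
  pooled <- correct_mid(pooled_raw, cm, method = method)
  p <- mean(water_enrichment(study$water_samples$ratio,
                             study$water_standards,
                             allow_extrapolation = TRUE))
  est <- estimate_n(list(pooled), p, candidates = candidates)
  if (per_sample)
    est$n_hat_per_sample <- vapply(seq_len(nrow(raws)), function(i)
      estimate_n(list(correct_mid(raws[i, ], cm, method = method)), p,
                 candidates = candidates)$n_hat, numeric(1))
  est
}
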