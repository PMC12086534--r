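#' Default analyte panel
#'
#' The monitored-ion definitions used by the synthetic generator and pipeline:
#' five taurine-conjugated bile acids quantified by LC-MS/MS (MRM, common
#' product ion m/z 80 from the taurine sulfonate), the palmitate carboxylate
#' ion, and the m/z 247 cholesterol fragment. `n_exchangeable` is the number
#' of deuterium-exchangeable hydrogen positions per analyte; pool means are
#' plausible liver concentrations for the synthetic generator.
#'
#' @param path Optional alternative CSV with the same columns.
#' @return Tibble: `analyte_id`, `formula`, `n_exchangeable`, `precursor_mz`,
#'   `product_mz`, `pool_mean_ug_g`, `pool_cv`.
#' @export
#' @examples
#' analyte_panel()
analyte_panel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "analyte_panel.csv", package = "d2otrace",
                        mustWork = TRUE)
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("analyte_id", "formula", "n_exchangeable") %in% names(tab)))
  if (any(tab$n_exchangeable < 1)) stop("every analyte needs n >= 1")
  tab
}

#' Describe a synthetic tracer study
#'
#' Bundles everything the generator needs: group sizes, the true fractional
#' synthesis of each analyte in each group, the analyte panel, body-water
#' enrichment distribution, and noise levels. Validated up front so
#' [simulate_study()] can assume a coherent design.
#'
#' @param groups Tibble/data.frame with columns `group`, `size` and optionally
#'   `sex`; one simulated arm per row.
#' @param f_true Data frame of true fractional synthesis in percent: one row
#'   per row of `groups` (matched by position), one column per analyte id.
#' @param analytes Analyte panel (default [analyte_panel()]), possibly
#'   subset to the columns of `f_true`.
#' @param p_mean,p_sd Body-water 2H mol-fraction excess distribution across
#'   animals (defaults 0.04 and 0.002: the ~4 percent dosing target).
#' @param f_bio_cv Biological coefficient of variation of f across animals
#'   (logit-normal; default 0.10).
#' @param area_cv Multiplicative (lognormal) instrument noise per isotopologue
#'   peak area (default 0.05).
#' @param pool_shrink Multiplier applied to every analyte pool mean (used by
#'   the knockout preset to shrink bile acid pools; default 1).
#' @param baseline_n Number of unlabeled baseline animals (default 3).
#' @param water_standards Known 2H mol-fraction excess of the gravimetric
#'   acetone standards (default 0, 1, 2, 4, 6 percent).
#' @param water_rel_noise Relative noise on acetone signal ratios (default
#'   0.005).
#' @param is_area_mean Mean internal-standard peak area (default 5e5).
#' @param seed Integer seed (default 20250407).
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(groups, f_true, analytes = analyte_panel(),
                          p_mean = 0.04, p_sd = 0.002,
                          f_bio_cv = 0.10, area_cv = 0.05,
                          pool_shrink = 1,
                          baseline_n = 3L,
                          water_standards = c(0, 0.01, 0.02, 0.04, 0.06),
                          water_rel_noise = 0.005,
                          is_area_mean = 5e5,
                          seed = 20250407L) {
  groups <- tibble::as_tibble(groups)
  if (!"sex" %in% names(groups)) groups$sex <- "M"
  f_true <- as.data.frame(f_true, check.names = FALSE)
  analytes <- analytes[analytes$analyte_id %in% names(f_true), , drop = FALSE]
  cfg <- structure(list(groups = groups, f_true = f_true, analytes = analytes,
                        p_mean = p_mean, p_sd = p_sd, f_bio_cv = f_bio_cv,
                        area_cv = area_cv, pool_shrink = pool_shrink,
                        baseline_n = as.integer(baseline_n),
                        water_standards = water_standards,
                        water_rel_noise = water_rel_noise,
                        is_area_mean = is_area_mean,
                        seed = as.integer(seed)),
                   class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  bad <- character(0)
  if (!all(c("group", "size") %in% names(cfg$groups))) bad <- c(bad, "groups")
  else if (any(cfg$groups$size < 1)) bad <- c(bad, "groups$size")
  if (nrow(cfg$f_true) != nrow(cfg$groups)) bad <- c(bad, "f_true (rows)")
  if (any(unlist(cfg$f_true) < 0) || any(unlist(cfg$f_true) > 100))
    bad <- c(bad, "f_true (range 0-100)")
  if (!nrow(cfg$analytes)) bad <- c(bad, "analytes (none match f_true columns)")
  if (any(!names(cfg$f_true) %in% cfg$analytes$analyte_id))
    bad <- c(bad, "f_true (unknown analyte column)")
  if (cfg$p_mean <= 0 || cfg$p_mean >= 1 || cfg$p_sd < 0) bad <- c(bad, "p_mean/p_sd")
  if (cfg$f_bio_cv < 0 || cfg$area_cv < 0) bad <- c(bad, "f_bio_cv/area_cv")
  if (cfg$pool_shrink <= 0) bad <- c(bad, "pool_shrink")
  if (cfg$baseline_n < 1) bad <- c(bad, "baseline_n")
  if (length(cfg$water_standards) < 2) bad <- c(bad, "water_standards")
  if (length(bad))
    stop("invalid cohort config; offending fields: ", paste(bad, collapse = ", "))
  invisible(cfg)
}

# mean-1 multiplicative lognormal draws; cv = 0 returns exactly 1
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

logit <- function(x) log(x / (1 - x))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Study design presets
#'
#' Ready-made [cohort_config()] objects whose group structures mirror the
#' three study designs the analysis supports: high- vs low-aerobic-capacity
#' rats (strain x diet x feeding status, 8 groups of 8), voluntary-wheel-
#' running mice (sedentary vs exercised, 8 per group), and inducible
#' liver-specific Cyp7a1 knockout mice (4 groups in both sexes, 6-8 per
#' group, with bile acid pools shrunk in the knockout). Effect sizes are
#' synthetic defaults chosen to be qualitatively plausible (high-capacity and
#' exercised arms synthesize more); they are not measured values.
#'
#' @param name One of `"hcr_lcr_1wk"`, `"vwr_mice"`, `"lcyp7a1ko"`.
#' @param seed Integer seed stored in the config.
#' @return A `"cohort_config"`.
#' @export
#' @examples
#' preset_study("vwr_mice")$groups
preset_study <- function(name = c("hcr_lcr_1wk", "vwr_mice", "lcyp7a1ko"),
                         seed = 20250407L) {
  name <- match.arg(name)
  panel <- analyte_panel()
  ba <- c("T-CA", "T-aMCA", "T-bMCA", "T-CDCA", "T-DCA")
  if (name == "vwr_mice") {
    groups <- tibble::tibble(group = c("SED", "VWR"), size = c(8L, 8L))
    f_true <- rbind(
      SED = c(`T-CA` = 12, `T-aMCA` = 10, `T-bMCA` = 8, `T-CDCA` = 9, `T-DCA` = 4),
      VWR = c(`T-CA` = 20, `T-aMCA` = 15, `T-bMCA` = 13, `T-CDCA` = 13, `T-DCA` = 7))
    return(cohort_config(groups, as.data.frame(f_true),
                         analytes = panel[panel$analyte_id %in% ba, ],
                         seed = seed))
  }
  if (name == "lcyp7a1ko") {
    groups <- tibble::tibble(
      group = rep(c("Ctrl_SED", "Ctrl_VWR", "KO_SED", "KO_VWR"), times = 2),
      sex = rep(c("M", "F"), each = 4),
      size = c(8L, 8L, 7L, 7L, 7L, 7L, 6L, 6L))
    # fraction-new similar across genotypes (pools shrink instead); VWR raises T-CA
    base <- c(`T-CA` = 12, `T-aMCA` = 10, `T-bMCA` = 8, `T-CDCA` = 9, `T-DCA` = 4)
    vwr <- base * c(1.6, 1.2, 1.2, 1.1, 1.3)
    f_true <- do.call(rbind, list(base, vwr, base, vwr, base, vwr, base, vwr))
    colnames(f_true) <- names(base)
    cfg <- cohort_config(groups, as.data.frame(f_true),
                         analytes = panel[panel$analyte_id %in% ba, ],
                         pool_shrink = 0.3, seed = seed)
    # only the knockout arms carry shrunken pools; handled at draw time
    cfg$pool_shrink_groups <- c("KO_SED", "KO_VWR")
    return(cfg)
  }
  # hcr_lcr_1wk: strain x diet x feeding status, n = 8 per group, full panel
  grid <- expand.grid(strain = c("HCR", "LCR"), diet = c("LFD", "HFD"),
                      fed = c("FED", "FASTED"), stringsAsFactors = FALSE)
  groups <- tibble::tibble(
    group = paste(grid$strain, grid$diet, grid$fed, sep = "_"), size = 8L)
  f_row <- function(strain, diet, fed) {
    hi <- strain == "HCR"
    hfd <- diet == "HFD"
    fasted <- fed == "FASTED"
    ba_f <- c(`T-CA` = 14, `T-aMCA` = 12, `T-bMCA` = 10, `T-CDCA` = 10,
              `T-DCA` = 5) *
      (if (hi) 1.5 else 1) * (if (hfd) 0.7 else 1)
    if (fasted) ba_f <- ba_f * c(1.25, 0.75, 0.75, 0.75, 0.75)
    dnl <- (if (hi) 16 else 12) * (if (hfd) 0.3 else 1) * (if (fasted) 0.5 else 1)
    chol <- (if (hi) 9 else 6) * (if (fasted) 0.7 else 1)
    c(ba_f, palmitate = dnl, cholesterol = chol)
  }
  f_true <- do.call(rbind, Map(f_row, grid$strain, grid$diet, grid$fed))
  rownames(f_true) <- groups$group
  cohort_config(groups, as.data.frame(f_true), analytes = panel, seed = seed)
}

#' Simulate a complete synthetic tracer study
#'
#' The generative twin of the measurement model: draws per-animal body-water
#' enrichment, per-animal/per-analyte true fractional synthesis (logit-normal
#' around the group mean) and pool concentration (lognormal), computes the
#' observed isotopologue distribution with [forward_observed_mid()], scales it
#' through a per-analyte internal-standard calibration line, and applies
#' multiplicative lognormal noise per peak area. Also emits unlabeled baseline
#' samples, acetone water-enrichment standards and per-animal ratios,
#' concentration-curve standards, sample metadata, and a ground-truth table
#' (never consumed by the pipeline).
#'
#' @param config A [cohort_config()].
#' @param seed Seed overriding `config$seed`.
#' @param K Highest acquired mass shift (default 3: m0-m3 channels).
#' @return Object of class `"synthetic_study"`: list of tibbles `areas`,
#'   `baseline`, `water_standards`, `water_samples`, `curve_standards`,
#'   `metadata`, `truth`.
#' @export
#' @examples
#' st <- simulate_study(preset_study("vwr_mice"))
#' head(st$areas)
simulate_study <- function(config, seed = config$seed, K = 3L) {
  validate_cohort_config(config)
  set.seed(seed)
  panel <- config$analytes
  n_animals <- sum(config$groups$size)
  grp_idx <- rep(seq_len(nrow(config$groups)), config$groups$size)
  sample_id <- sprintf("S%03d", seq_len(n_animals))
  group <- config$groups$group[grp_idx]
  sex <- config$groups$sex[grp_idx]

  # acetone water calibration: ratio = intercept + slope * p (6 exchanging H)
  w_slope <- 6; w_intercept <- 0.0032
  wstd <- tibble::tibble(
    known_frac = config$water_standards,
    ratio = (w_intercept + w_slope * config$water_standards) *
      rlnorm_cv(length(config$water_standards), config$water_rel_noise))

  # per-animal body water enrichment, truncated to (0, 1)
  p_true <- stats::rnorm(n_animals, config$p_mean, config$p_sd)
  while (any(p_true <= 0 | p_true >= 1))
    p_true[p_true <= 0 | p_true >= 1] <-
      stats::rnorm(sum(p_true <= 0 | p_true >= 1), config$p_mean, config$p_sd)
  wsamp <- tibble::tibble(
    sample_id = sample_id,
    ratio = (w_intercept + w_slope * p_true) *
      rlnorm_cv(n_animals, config$water_rel_noise))

  # fixed per-analyte concentration calibration lines + standards tables
  n_a <- nrow(panel)
  c_slope <- stats::runif(n_a, 0.8, 1.2) / panel$pool_mean_ug_g
  c_intercept <- stats::runif(n_a, 0, 0.02)
  curve_standards <- do.call(rbind, lapply(seq_len(n_a), function(a) {
    known <- panel$pool_mean_ug_g[a] * c(0.1, 0.25, 0.5, 1, 2, 4)
    tibble::tibble(
      analyte_id = panel$analyte_id[a], known_conc = known,
      response = (c_intercept[a] + c_slope[a] * known) *
        rlnorm_cv(length(known), config$water_rel_noise))
  }))

  shrink_groups <- config$pool_shrink_groups
  nats <- lapply(panel$formula, natural_mid, K = K)

  rows <- vector("list", n_animals * n_a)
  truth <- vector("list", n_animals * n_a)
  k <- 0L
  for (i in seq_len(n_animals)) {
    for (a in seq_len(n_a)) {
      k <- k + 1L
      fg <- config$f_true[grp_idx[i], panel$analyte_id[a]] / 100
      f_i <- if (config$f_bio_cv > 0 && fg > 0 && fg < 1)
        inv_logit(stats::rnorm(1, logit(fg), config$f_bio_cv)) else fg
      shrink <- if (!is.null(shrink_groups) && group[i] %in% shrink_groups)
        config$pool_shrink else if (is.null(shrink_groups)) config$pool_shrink else 1
      pool_i <- panel$pool_mean_ug_g[a] * shrink *
        rlnorm_cv(1, panel$pool_cv[a])
      obs <- forward_observed_mid(f_i, p_true[i], panel$n_exchangeable[a],
                                  panel$formula[a], K = K)
      # response the instrument reports: area ratio on the acquired channels
      resp <- c_intercept[a] + c_slope[a] * pool_i
      is_area <- config$is_area_mean * rlnorm_cv(1, config$area_cv)
      total <- resp * is_area
      shares <- mid_values(obs) / sum(mid_values(obs))
      areas <- total * shares * rlnorm_cv(K + 1L, config$area_cv)
      rows[[k]] <- tibble::tibble(
        sample_id = sample_id[i], analyte_id = panel$analyte_id[a],
        !!!stats::setNames(as.list(areas), paste0("area_m", 0:K)),
        area_is = is_area)
      truth[[k]] <- tibble::tibble(
        sample_id = sample_id[i], analyte_id = panel$analyte_id[a],
        group = group[i], sex = sex[i],
        f_true_pct = f_i * 100, p_true = p_true[i], pool_ug_g = pool_i)
    }
  }
  areas <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)

  # unlabeled baseline animals: natural-abundance spectra with the same noise
  base_rows <- vector("list", config$baseline_n * n_a)
  k <- 0L
  for (i in seq_len(config$baseline_n)) {
    for (a in seq_len(n_a)) {
      k <- k + 1L
      is_area <- config$is_area_mean * rlnorm_cv(1, config$area_cv)
      total <- (c_intercept[a] + c_slope[a] * panel$pool_mean_ug_g[a]) * is_area
      shares <- mid_values(nats[[a]]) / sum(mid_values(nats[[a]]))
      areas_b <- total * shares * rlnorm_cv(K + 1L, config$area_cv)
      base_rows[[k]] <- tibble::tibble(
        sample_id = sprintf("B%02d", i), analyte_id = panel$analyte_id[a],
        !!!stats::setNames(as.list(areas_b), paste0("area_m", 0:K)),
        area_is = is_area)
    }
  }

  metadata <- tibble::tibble(
    sample_id = sample_id, group = group, sex = sex,
    body_mass_g = round(stats::rnorm(n_animals, 30, 2), 2),
    liver_mass_g = round(stats::rnorm(n_animals, 1.3, 0.12), 3))

  structure(list(areas = areas, baseline = do.call(rbind, base_rows),
                 water_standards = wstd, water_samples = wsamp,
                 curve_standards = tibble::as_tibble(curve_standards),
                 metadata = metadata, truth = truth,
                 panel = panel, K = K, seed = seed),
            class = "synthetic_study")
}

#' Write / read a synthetic study as plain CSV tables
#'
#' Emits the exact CSV dialect [run_analysis()] reads. The truth table is
#' written alongside for scoring but is never consumed by the pipeline.
#'
#' @param study A `"synthetic_study"`.
#' @param dir Output directory (created if needed).
#' @return `write_study()` returns `dir` invisibly; `read_study()` returns a
#'   `"synthetic_study"` (without truth if absent).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("areas", "baseline", "water_standards", "water_samples",
            "curve_standards", "metadata", "truth", "panel")
  for (t in tabs)
    if (!is.null(study[[t]]))
      utils::write.csv(study[[t]], file.path(dir, paste0(t, ".csv")),
                       row.names = FALSE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  rd <- function(f) {
    path <- file.path(dir, paste0(f, ".csv"))
    if (file.exists(path))
      tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                        check.names = FALSE))
    else NULL
  }
  out <- list(areas = rd("areas"), baseline = rd("baseline"),
              water_standards = rd("water_standards"),
              water_samples = rd("water_samples"),
              curve_standards = rd("curve_standards"),
              metadata = rd("metadata"), truth = rd("truth"),
              panel = rd("panel"))
  if (is.null(out$panel)) out$panel <- analyte_panel()
  out$K <- sum(grepl("^area_m[0-9]+$", names(out$areas))) - 1L
  structure(out, class = "synthetic_study")
}
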