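two_group_config <- function(f_a = 10, f_b = 20, seed = 20250407,
                             analyte = "T-CDCA", ...) {
  f <- data.frame(x = c(f_a, f_b), check.names = FALSE)
  names(f) <- analyte
  cohort_config(tibble::tibble(group = c("A", "B"), size = c(8L, 8L)),
                f, seed = seed, ...)
}

test_that("config validation names the offending fields", {
  expect_error(two_group_config(f_b = 150), "f_true")
  expect_error(cohort_config(tibble::tibble(group = "A", size = 0L),
                             data.frame(`T-CA` = 10, check.names = FALSE)),
               "size")
  expect_error(two_group_config(analyte = "nonexistent"), "analyte")
})

test_that("a noise-free null study emits exactly the natural MID", {
  cfg <- two_group_config(f_a = 0, f_b = 0, f_bio_cv = 0, area_cv = 0,
                          water_rel_noise = 0)
  st <- simulate_study(cfg)
  nat <- mid_values(natural_mid("C26H44NO6S", K = 3))
  shares <- as.matrix(st$areas[, paste0("area_m", 0:3)])
  shares <- shares / rowSums(shares)
  want <- nat / sum(nat)
  expect_lt(max(abs(sweep(shares, 2, want))), 1e-12)
  expect_true(all(st$areas$area_is > 0))
})

test_that("same config and seed give identical studies; seeds differ", {
  cfg <- two_group_config()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_study(cfg, seed = 99L)
  expect_false(identical(s1$areas, s3$areas))
})

test_that("truth table covers every emitted sample x analyte with positive areas", {
  st <- simulate_study(preset_study("vwr_mice"))
  key_a <- paste(st$areas$sample_id, st$areas$analyte_id)
  key_t <- paste(st$truth$sample_id, st$truth$analyte_id)
  expect_setequal(key_a, key_t)
  expect_true(all(as.matrix(st$areas[, paste0("area_m", 0:3)]) > 0))
})

test_that("presets mirror the three study designs", {
  vwr <- preset_study("vwr_mice")
  expect_equal(nrow(vwr$groups), 2)
  expect_true(all(vwr$groups$size == 8))

  hcr <- preset_study("hcr_lcr_1wk")
  expect_equal(nrow(hcr$groups), 8)   # strain x diet x feeding status
  expect_true(all(hcr$groups$size == 8))
  expect_equal(nrow(hcr$analytes), 7) # bile acids + palmitate + cholesterol

  ko <- preset_study("lcyp7a1ko")
  expect_equal(length(unique(ko$groups$group)), 4)
  expect_setequal(unique(ko$groups$sex), c("M", "F"))
  expect_true(all(ko$groups$size >= 6 & ko$groups$size <= 8))
  expect_error(preset_study("nope"))
})

test_that("knockout preset shrinks bile acid pools only in knockout arms", {
  st <- simulate_study(preset_study("lcyp7a1ko"))
  pools <- aggregate(pool_ug_g ~ group + analyte_id, st$truth, mean)
  tca <- pools[pools$analyte_id == "T-CA", ]
  ko_mean <- mean(tca$pool_ug_g[grepl("^KO", tca$group)])
  ctrl_mean <- mean(tca$pool_ug_g[grepl("^Ctrl", tca$group)])
  expect_lt(ko_mean, 0.6 * ctrl_mean)
})

test_that("a 10% vs 20% design separates by more than 5 points downstream", {
  st <- simulate_study(two_group_config(10, 20))
  res <- run_analysis(st)
  means <- tapply(res$f_pct, res$group, mean)
  expect_gt(means[["B"]] - means[["A"]], 5)
})

test_that("estimate dispersion grows with configured noise", {
  spread_at <- function(cv) {
    sds <- sapply(1:12, function(i) {
      st <- simulate_study(two_group_config(area_cv = cv, f_bio_cv = 0,
                                            seed = 1000L + i))
      sd(run_analysis(st)$f_pct)
    })
    mean(sds)
  }
  s_low <- spread_at(0.01); s_mid <- spread_at(0.05); s_high <- spread_at(0.12)
  expect_lt(s_low, s_mid)
  expect_lt(s_mid, s_high)
})
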