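test_that("forward model degenerates to the natural MID without label", {
  nat <- natural_mid("C16H31O2", K = 3)
  f0 <- forward_observed_mid(0, 0.04, 22, "C16H31O2")
  expect_equal(mid_values(f0), mid_values(nat), tolerance = 1e-15)
  p0 <- forward_observed_mid(0.3, 0, 22, "C16H31O2")
  expect_equal(mid_values(p0), mid_values(nat), tolerance = 1e-15)
})

test_that("forward model matches label-placement enumeration oracles", {
  # excess convention, small molecule, n = 4
  got <- mid_values(forward_observed_mid(0.3, 0.04, 4, "C2H6O", K = 3))
  want <- oracle_forward_enum(0.3, 0.04, 4, "C2H6O", K = 3)
  expect_lt(max(abs(got - want)), 1e-10)

  # n = 10 exchange positions on a 6-non-H-atom-or-fewer backbone
  got10 <- mid_values(forward_observed_mid(0.3, 0.04, 10, "C4H10", K = 3))
  want10 <- oracle_forward_enum(0.3, 0.04, 10, "C4H10", K = 3)
  expect_lt(max(abs(got10 - want10)), 1e-10)

  # replace-exchange-positions convention against its own oracle
  gr <- mid_values(forward_observed_mid(0.3, 0.04, 4, "C2H6O", K = 3,
                                        exchange = "replace"))
  wr <- oracle_forward_enum(0.3, 0.04, 4, "C2H6O", K = 3, exchange = "replace")
  expect_lt(max(abs(gr - wr)), 1e-10)

  # the two conventions agree closely at tracer-level enrichment
  expect_lt(max(abs(got - gr)), 1e-3)
})

test_that("forward model flags severe truncation", {
  ok <- forward_observed_mid(0.5, 0.04, 22, "C16H31O2")
  expect_length(attr(ok, "flags"), 0)
  bad <- forward_observed_mid(1, 0.3, 22, "C16H31O2")
  expect_equal(attr(bad, "flags"), "severe_truncation")
})

test_that("analyte enrichment is the label-weighted isotopologue sum", {
  expect_equal(analyte_enrichment(c(1, 0, 0, 0)), 0)
  expect_equal(analyte_enrichment(c(0, 0, 0, 1)), 3)
  expect_equal(analyte_enrichment(c(0.85, 0.10, 0.04, 0.01)), 0.21)
})

test_that("fractional synthesis implements the enrichment ratio", {
  expect_equal(fractional_synthesis(0, 0.04, 22), 0)
  expect_equal(fractional_synthesis(0.04 * 22, 0.04, 22), 100)
  expect_equal(fractional_synthesis(0.088, 0.04, 22), 10)
  expect_error(fractional_synthesis(0.1, 0, 22), "water enrichment")
})

test_that("fractional synthesis is algebraically invertible", {
  set.seed(1)
  for (i in 1:20) {
    e <- runif(1, 0, 1); p <- runif(1, 0.01, 0.06); n <- sample(5:30, 1)
    f <- fractional_synthesis(e, p, n)
    expect_equal(f * (p * n) / 100, e, tolerance = 1e-12)
  }
})

test_that("truncation-aware estimator is exact where the plain one is biased", {
  # noiseless measured enrichment of a corrected, renormalized K=3 MID
  for (n in c(10, 14, 18, 20, 22)) for (p in c(0.02, 0.04, 0.05)) {
    f <- 0.25
    b <- dbinom(0:3, n, p)
    x <- (1 - f) * c(1, 0, 0, 0) + f * b
    e <- analyte_enrichment(x / sum(x))
    expect_equal(fractional_synthesis(e, p, n, truncation = "correct"),
                 100 * f, tolerance = 1e-9)
    # plain estimator under-reads by exactly the binomial tail loss
    f_plain <- fractional_synthesis(e, p, n)
    expect_lte(f_plain, 100 * f + 1e-12)
  }
})

test_that("plain-estimator truncation bias shrinks monotonically with K", {
  biases <- sapply(3:8, function(K)
    abs(truncation_bias(22, 0.05, K)$relative_bias))
  expect_true(all(diff(biases) < 0))
  expect_lt(biases[length(biases)], 1e-4)
  expect_gt(biases[1], 0.05)  # at K=3 the loss is material for n=22, p=5%
})

test_that("enrichment grows linearly in f and monotonically in p", {
  fs <- seq(0.05, 0.6, by = 0.05)
  es <- sapply(fs, function(f)
    analyte_enrichment(forward_observed_mid(f, 0.04, 18, "C26H44NO6S")))
  slopes <- diff(es) / diff(fs)
  expect_lt(diff(range(slopes)) / mean(slopes), 1e-9)  # linear in f
  ps <- c(0.01, 0.02, 0.04, 0.05)
  ep <- sapply(ps, function(p)
    analyte_enrichment(forward_observed_mid(0.2, p, 18, "C26H44NO6S")))
  expect_true(all(diff(ep) > 0))
})

test_that("estimate_n recovers assigned n exactly from noiseless MIDs", {
  mk_mids <- function(n, fm, p = 0.04, fs = c(0.05, 0.1, 0.2)) {
    M <- build_correction_matrix(natural_mid(fm, K = 3))
    lapply(fs, function(f)
      correct_mid(mid_values(forward_observed_mid(f, p, n, fm)), M))
  }
  est <- estimate_n(mk_mids(22, "C16H31O2"), p = 0.04)
  expect_equal(est$n_hat, 22)
  expect_equal(est$ratio_diagnostic, 22, tolerance = 1e-6)
  # residual is zero only at the true candidate
  expect_lt(est$profile$rss[est$profile$candidate == 22], 1e-18)
  expect_gt(min(est$profile$rss[est$profile$candidate != 22]), 1e-12)

  # taurochenodeoxycholate channel: n = 18
  expect_equal(estimate_n(mk_mids(18, "C26H44NO6S"), p = 0.04)$n_hat, 18)

  # Bernoulli labeling: all excess in m1
  expect_equal(estimate_n(mk_mids(1, "C2H6O"), p = 0.04)$n_hat, 1)
})

test_that("estimate_n refuses unlabeled data and reports ties", {
  M <- build_correction_matrix(natural_mid("C16H31O2", K = 3))
  blank <- correct_mid(mid_values(natural_mid("C16H31O2", K = 3)), M)
  expect_error(estimate_n(list(blank), p = 0.04), "insufficient labeling")
})

test_that("pooled n estimation is unbiased under instrument noise", {
  # 5% CV per isotopologue area, 8 samples pooled before correction;
  # integer-exact recovery at this noise level is variance-limited, so the
  # guarantee tested is unbiasedness plus +/-2 interval coverage
  set.seed(20250407)
  cv <- 0.05; s <- sqrt(log(1 + cv^2))
  for (case in list(list(n = 10, fm = "C26H44NO6S"),
                    list(n = 18, fm = "C26H44NO6S"))) {
    M <- build_correction_matrix(natural_mid(case$fm, K = 3))
    obs <- mid_values(forward_observed_mid(0.3, 0.04, case$n, case$fm))
    hats <- replicate(60, {
      raws <- t(sapply(1:8, function(i) {
        a <- obs * exp(rnorm(4, -s^2 / 2, s)); a / sum(a)
      }))
      estimate_n(list(correct_mid(colMeans(raws), M)), 0.04)$n_hat
    })
    expect_lt(abs(mean(hats) - case$n), 0.5)
    expect_gte(mean(abs(hats - case$n) <= 2), 0.70)
  }
})

test_that("new pool amount is the bilinear product of f and pool size", {
  expect_equal(new_pool_amount(0, 123), 0)
  expect_equal(new_pool_amount(100, 52.79), 52.79)
  expect_equal(new_pool_amount(25, 80), 20)
  expect_equal(new_pool_amount(2 * 25, 80), 2 * new_pool_amount(25, 80))
  expect_error(new_pool_amount(-1, 80))
})
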