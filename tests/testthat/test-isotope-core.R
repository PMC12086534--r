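test_that("formula parsing handles Hill notation, implicit counts, and errors", {
  expect_equal(parse_formula("C16H31O2"), c(C = 16L, H = 31L, O = 2L))
  expect_equal(parse_formula("C26H44NO7S"),
               c(C = 26L, H = 44L, N = 1L, O = 7L, S = 1L))
  expect_equal(parse_formula(""), setNames(integer(0), character(0)))
  expect_error(parse_formula("C16x"), "cannot parse")
  expect_error(natural_mid("Xx2"), "unknown element")
})

test_that("natural_mid handles trivial formulas", {
  empty <- natural_mid("", K = 3)
  expect_equal(mid_values(empty), c(1, 0, 0, 0))
  expect_equal(empty$truncated_mass, 0)

  one_c <- natural_mid("C", K = 3)
  iso <- isotope_table()
  r13 <- iso$abundance[iso$element == "C" & iso$mass_shift == 1] /
    iso$abundance[iso$element == "C" & iso$mass_shift == 0]
  expect_equal(mid_values(one_c)[2] / mid_values(one_c)[1], r13)
})

test_that("natural_mid matches the multinomial oracle for the palmitate ion", {
  got <- mid_values(natural_mid("C16H31O2", K = 3))
  want <- oracle_natural_multinom(16, 31, 2, K = 3)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("natural_mid matches per-atom enumeration on small formulas", {
  for (f in c("CH4", "C2H2O", "CHNOS", "H2O", "C3S")) {
    got <- mid_values(natural_mid(f, K = 3))
    want <- oracle_natural_enum(f, K = 3)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("natural_mid mass bookkeeping closes for random large formulas", {
  set.seed(20250407)
  for (i in 1:25) {
    fm <- random_formula(200)
    m <- natural_mid(fm, K = 3)
    expect_lt(abs(sum(mid_values(m)) + m$truncated_mass - 1), 1e-9)
    expect_true(all(mid_values(m) >= 0))
  }
})

test_that("convolution of disjoint sub-formulas reproduces the full formula", {
  whole <- natural_mid("C5H8O3", K = 3)
  parts <- convolve_mid(natural_mid("C5", K = 3), natural_mid("H8O3", K = 3))
  expect_lt(max(abs(mid_values(whole) - mid_values(parts))), 1e-12)
  expect_lt(abs(whole$truncated_mass - parts$truncated_mass), 1e-12)
})

test_that("correction matrix has the shift structure and rejects m0 = 0", {
  expect_equal(build_correction_matrix(mid(c(1, 0, 0, 0))), diag(4),
               ignore_attr = TRUE)
  M <- build_correction_matrix(mid(c(0.9, 0.1, 0, 0)))
  expect_equal(unname(M[, 1]), c(0.9, 0.1, 0, 0))
  expect_equal(unname(M[, 3]), c(0, 0, 0.9, 0.1))
  expect_equal(unname(M[, 4]), c(0, 0, 0, 0.9))
  expect_true(all(M[upper.tri(M)] == 0))
  expect_error(build_correction_matrix(c(0, 0.6, 0.4, 0)), "singular")
})

test_that("correct_mid normalizes, inverts the baseline, and flags errors", {
  M <- build_correction_matrix(mid(c(1, 0, 0, 0)))
  expect_equal(mid_values(correct_mid(c(8, 1, 1, 0), M)),
               c(0.8, 0.1, 0.1, 0))

  nat <- natural_mid("C26H44NO7S", K = 3)
  Mn <- build_correction_matrix(nat)
  base <- correct_mid(mid_values(nat), Mn)
  expect_lt(max(abs(mid_values(base) - c(1, 0, 0, 0))), 1e-9)

  expect_error(correct_mid(c(0, 0, 0, 0), Mn), "empty spectrum")
})

test_that("correct_mid is invariant to positive rescaling of intensities", {
  nat <- natural_mid("C16H31O2", K = 3)
  M <- build_correction_matrix(nat)
  obs <- mid_values(forward_observed_mid(0.15, 0.04, 22, "C16H31O2"))
  a <- mid_values(correct_mid(obs, M))
  b <- mid_values(correct_mid(obs * 3.7e6, M))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("noiseless roundtrip recovers the label-only mixture", {
  # matrix correction of the forward-simulated spectrum returns
  # (1-f) d0 + f Binom(n, p), renormalized over m0..m3
  for (case in list(c(0.2, 0.04, 22), c(0.05, 0.02, 10), c(0.6, 0.05, 18))) {
    f <- case[1]; p <- case[2]; n <- case[3]
    fm <- if (n == 22) "C16H31O2" else "C26H44NO6S"
    nat <- natural_mid(fm, K = 3)
    M <- build_correction_matrix(nat)
    got <- mid_values(correct_mid(mid_values(forward_observed_mid(f, p, n, fm)), M))
    b <- dbinom(0:3, n, p)
    want <- (1 - f) * c(1, 0, 0, 0) + f * b
    want <- want / sum(want)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("solver methods agree on noiseless data; empirical baseline averages", {
  nat <- natural_mid("C26H44NO7S", K = 3)
  M <- build_correction_matrix(nat)
  obs <- mid_values(forward_observed_mid(0.1, 0.04, 14, "C26H44NO7S"))
  expect_equal(mid_values(correct_mid(obs, M, method = "nnls")),
               mid_values(correct_mid(obs, M, method = "solve")),
               tolerance = 1e-9)

  raws <- rbind(mid_values(nat) * 1e5, mid_values(nat) * 3e5)
  avg <- average_baseline_mids(raws)
  expect_equal(mid_values(avg), mid_values(nat) / sum(mid_values(nat)),
               tolerance = 1e-12)
})

test_that("MID invariants are enforced", {
  expect_error(mid(c(-0.1, 1.1, 0, 0)), "non-negative")
  expect_error(mid(c(0.5, 0.1, 0, 0), truncated_mass = 0.1), "sum to 1")
  expect_silent(validate_mid <- mid(c(0.9, 0.05, 0.03, 0.01), 0.01))
})
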