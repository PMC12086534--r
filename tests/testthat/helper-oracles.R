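# Independent brute-force oracles: exhaustive enumeration over isotope
# placements, no convolution or binomial shortcuts. Only feasible for small
# formulas; used to pin the fast implementations.

# Per-atom enumeration: every atom independently takes one of its element's
# isotopes; probabilities multiply, mass shifts add.
oracle_natural_enum <- function(formula, K, isotopes = isotope_table()) {
  counts <- parse_formula(formula)
  shifts <- list(); probs <- list()
  for (el in names(counts)) {
    rows <- isotopes[isotopes$element == el, , drop = FALSE]
    for (i in seq_len(counts[[el]])) {
      shifts[[length(shifts) + 1L]] <- rows$mass_shift
      probs[[length(probs) + 1L]] <- rows$abundance
    }
  }
  if (!length(shifts)) return(c(1, numeric(K)))
  idx <- do.call(expand.grid, lapply(shifts, seq_along))
  tot_shift <- Reduce(`+`, lapply(seq_along(shifts),
                                  function(a) shifts[[a]][idx[[a]]]))
  tot_prob <- Reduce(`*`, lapply(seq_along(probs),
                                 function(a) probs[[a]][idx[[a]]]))
  vapply(0:K, function(k) sum(tot_prob[tot_shift == k]), numeric(1))
}

# Closed-form multinomial oracle for C/H/O formulas (handles large atom
# counts like the palmitate ion): sums dbinom/dmultinom terms over all heavy-
# isotope count combinations reaching each shift.
oracle_natural_multinom <- function(nC, nH, nO, K, isotopes = isotope_table()) {
  ab <- function(el, s) {
    x <- isotopes$abundance[isotopes$element == el & isotopes$mass_shift == s]
    if (length(x)) x else 0
  }
  aC <- ab("C", 1); aH <- ab("H", 1); aO1 <- ab("O", 1); aO2 <- ab("O", 2)
  out <- numeric(K + 1)
  for (k13 in 0:K) for (k2 in 0:K) for (k17 in 0:K) for (k18 in 0:K) {
    v <- k13 + k2 + k17 + 2 * k18
    if (v > K || k13 > nC || k2 > nH || k17 + k18 > nO) next
    pr <- stats::dbinom(k13, nC, aC) * stats::dbinom(k2, nH, aH) *
      stats::dmultinom(c(nO - k17 - k18, k17, k18),
                       prob = c(1 - aO1 - aO2, aO1, aO2))
    out[v + 1] <- out[v + 1] + pr
  }
  out
}

# Label-placement enumeration for the forward model: each of the n exchange
# positions independently carries an extra deuterium with probability p_lab.
# "excess" convention: the label adds onto the full natural distribution.
oracle_forward_enum <- function(f, p, n, formula, K,
                                isotopes = isotope_table(),
                                exchange = c("excess", "replace")) {
  exchange <- match.arg(exchange)
  if (exchange == "excess") {
    nat <- oracle_natural_enum(formula, K, isotopes)
    p_lab <- p
  } else {
    counts <- parse_formula(formula)
    counts["H"] <- counts["H"] - n
    nat <- oracle_natural_enum(counts[counts > 0], K, isotopes)
    p_lab <- p + isotopes$abundance[isotopes$element == "H" &
                                      isotopes$mass_shift == 1]
  }
  # enumerate all 2^n label patterns
  pat <- as.matrix(do.call(expand.grid, rep(list(0:1), n)))
  w <- apply(pat, 1, function(r) prod(ifelse(r == 1, p_lab, 1 - p_lab)))
  k_lab <- rowSums(pat)
  lab <- vapply(0:K, function(k) sum(w[k_lab == k]), numeric(1))
  # elementary truncated convolution by double sum
  labeled <- numeric(K + 1)
  for (i in 0:K) for (j in 0:i)
    labeled[i + 1] <- labeled[i + 1] + nat[j + 1] * lab[i - j + 1]
  if (exchange == "excess") {
    (1 - f) * nat + f * labeled
  } else {
    nat_full <- oracle_natural_enum(formula, K, isotopes)
    (1 - f) * nat_full + f * labeled
  }
}

# random plausible formula for property tests
random_formula <- function(max_atoms = 200) {
  els <- c("C", "H", "N", "O", "S")
  repeat {
    cnt <- c(sample(0:30, 1), sample(0:60, 1), sample(0:3, 1),
             sample(0:8, 1), sample(0:2, 1))
    if (sum(cnt) >= 1 && sum(cnt) <= max_atoms) break
  }
  stats::setNames(cnt, els)[cnt > 0]
}
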