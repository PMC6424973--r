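phl <- ring_substrate("phloroglucinol", "C6H6O3",
                      c("1" = "OH", "3" = "OH", "5" = "OH"))

test_that("halide-pool enumeration matches the observed product sets", {
  # Cl/I pool: all mono and di states including the hetero Cl-I product
  cli <- enumerate_halogenation_states(phl, c("Cl", "I"))
  labs <- sort(vapply(cli, function(p) paste(p$halogens, collapse = ""),
                      character(1)))
  expect_equal(labs, sort(c("Cl", "I", "ClCl", "II", "ClI")))
  # Br/I pool with the observed restrictions: mono-Br, mono-I, di-I only
  bri <- enumerate_halogenation_states(phl, c("Br", "I"),
                                       per_halide_caps = c(Br = 1),
                                       forbidden_combos = list(c("Br", "I")))
  labs <- sort(vapply(bri, function(p) paste(p$halogens, collapse = ""),
                      character(1)))
  expect_equal(labs, sort(c("Br", "I", "II")))
  # fluoride never yields product
  expect_length(enumerate_halogenation_states(phl, "F"), 0)
  expect_error(enumerate_halogenation_states(phl, "Cl", max_total = 3),
               "trihalogenation")
  expect_error(enumerate_halogenation_states(phl, c("Cl", "At")),
               "unknown halide")
})

test_that("enumeration size matches the closed form before caps", {
  # |pool| mono states + C(|pool|+1, 2) di states
  for (pool in list("Cl", c("Cl", "Br"), c("Cl", "Br", "I"))) {
    n <- length(pool)
    states <- enumerate_halogenation_states(phl, pool)
    expect_length(states, n + choose(n + 1, 2))
  }
})

test_that("monoisotopic masses and adducts match an independent mass table", {
  expect_equal(monoisotopic_mass("C6H6O3"), 126.0317, tolerance = 1e-4)
  expect_equal(adduct_mz("C6H5ClO3", "negative"), 158.9854,
               tolerance = 1e-4)
  expect_equal(adduct_mz("C6H6O3", "positive") -
                 adduct_mz("C6H6O3", "negative"),
               2 * 1.007276467)
  expect_error(monoisotopic_mass("C6H6Xx3"), "unknown element")
})

test_that("each chlorination shifts the mass by Cl minus H", {
  set.seed(21)
  shift <- 34.96885271 - 1.0078250319
  for (i in 1:10) {
    f <- sprintf("C%dH%dN%dO%d", sample(4:20, 1), sample(4:20, 1),
                 sample(0:3, 1), sample(1:6, 1))
    sub <- ring_substrate("x", f, c("1" = "OH"))
    p1 <- halogenation_product(sub, "Cl")
    p2 <- halogenation_product(sub, c("Cl", "Cl"))
    expect_equal(monoisotopic_mass(p1$formula),
                 monoisotopic_mass(f) + shift)
    expect_equal(monoisotopic_mass(p2$formula),
                 monoisotopic_mass(f) + 2 * shift)
  }
})

test_that("halogen isotope envelopes match brute-force convolution", {
  # no polyisotopic halogen: single base peak
  pat <- isotope_pattern(halogenation_product(phl, "I"))
  expect_equal(nrow(pat), 1)
  expect_equal(pat$abundance, 100)
  # one Cl: M+2 at ~32.0% of M
  pat <- isotope_pattern(halogenation_product(phl, "Cl"))
  expect_equal(pat$abundance[2] / pat$abundance[1], 24.24 / 75.76,
               tolerance = 1e-6)
  expect_equal(pat$shift[2], 1.99705, tolerance = 1e-4)
  # two Br: ~51.4 : 100 : 48.7 with base peak at M+2
  pat <- isotope_pattern(halogenation_product(phl, c("Br", "Br")))
  expect_equal(pat$abundance, c(51.40352, 100, 48.63863), tolerance = 1e-4)
  # exhaustive: every product of a 3-halide enumeration equals the oracle
  for (p in enumerate_halogenation_states(phl, c("Cl", "Br", "I"))) {
    pat <- isotope_pattern(p)
    ora <- oracle_isotopes(p$formula)
    expect_equal(pat$shift, ora$shift, tolerance = 1e-6)
    expect_equal(pat$abundance, ora$ab, tolerance = 1e-8)
  }
  # full mode also convolves 13C, oracle over Cl, Br and C atoms
  p <- halogenation_product(phl, c("Cl", "Br"))
  pat <- isotope_pattern(p, mode = "full")
  ora <- oracle_isotopes(p$formula, elements = c("Cl", "Br", "C"))
  ora <- ora[ora$ab >= 0.01, ]
  expect_equal(nrow(pat), nrow(ora))
  expect_equal(pat$abundance, ora$ab, tolerance = 1e-6)
})

test_that("XIC matching honours the closed tolerance window", {
  prods <- enumerate_halogenation_states(phl, c("Cl", "I"))
  mzs <- vapply(prods, adduct_mz, numeric(1), mode = "negative")
  # exact masses all match; 0.049 off matches; 0.051 off does not
  hit <- xic_match(mzs[1], prods, "negative", tolerance = 0.05)
  expect_true(any(abs(hit$delta) < 1e-9))
  expect_equal(nrow(xic_match(mzs[1] + 0.049, prods, "negative", 0.05)), 1)
  expect_equal(nrow(xic_match(mzs[1] + 0.051, prods, "negative", 0.05)), 0)
  # synthetic peak list: the 5 product peaks plus 3 decoys 0.2 Da away
  peaks <- c(mzs, mzs[1:3] + 0.2)
  asg <- xic_match(peaks, prods, "negative", tolerance = 0.05)
  expect_equal(nrow(asg), 5)
  expect_setequal(asg$label, vapply(prods, `[[`, character(1), "label"))
  # candidates outside the 80-600 m/z window are never assigned
  tiny <- ring_substrate("tiny", "C2H4O", c("1" = "OH"))
  small <- halogenation_product(tiny, "Cl") # [M-H]- ~ 76.98 < 80
  expect_equal(nrow(xic_match(adduct_mz(small, "negative"), list(small),
                              "negative", 0.05)), 0)
  expect_warning(out <- xic_match(100, list(), "negative", 0.05), "empty")
  expect_equal(nrow(out), 0)
  expect_error(xic_match(100, prods, "negative", tolerance = 0), "positive")
})

test_that("halogenation products respect the two-halogen limit", {
  expect_error(halogenation_product(phl, c("Cl", "Cl", "Cl")),
               "at most two")
  p <- halogenation_product(phl, c("Cl", "I"))
  expect_equal(p$formula[["H"]], 4)
  expect_equal(p$formula[["Cl"]], 1)
  expect_equal(p$formula[["I"]], 1)
})
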