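test_that("Km arithmetic and its inverse are exact", {
  expect_equal(km_of(kd = 5.3, kcat = 2.3, ka = 100), 0.076)
  expect_equal(km_of(0, 0, 50), 0)
  expect_equal(micro_from_macro(2.3, 0.076, 100),
               c(ka = 100, kd = 5.3, kcat = 2.3))
  expect_equal(micro_from_macro(0, 0.5, 40), c(ka = 40, kd = 20, kcat = 0))
  # round trip both ways over random valid inputs
  set.seed(42)
  for (i in 1:25) {
    kcat <- runif(1, 0, 5)
    km <- 10^runif(1, -2, 3)
    ka <- 10^runif(1, log10(kcat / km + 0.1), 3)
    m <- micro_from_macro(kcat, km, ka)
    expect_equal(km_of(m[["kd"]], m[["kcat"]], m[["ka"]]), km)
  }
  expect_error(km_of(1, 1, 0), "invalid parameterization")
  expect_error(micro_from_macro(2.3, 0.076, 10), "larger 'ka'")
})

test_that("sequential scheme has the forced two-cycle structure", {
  sch <- sequential_scheme(kcat = c(2.3, 0.40), km = c(0.076, 0.11))
  expect_setequal(sch$species$name, c("E", "S", "ES", "P1", "EP1", "P2"))
  expect_equal(nrow(sch$reactions), 6)
  expect_equal(sch$topology, "sequential")
  # cycle-1 Km recomputed from the scheme's microscopic constants
  expect_equal(km_of(sch$rates[["kd1"]], sch$rates[["kcat1"]],
                     sch$rates[["ka1"]]), 0.076)
  expect_error(sequential_scheme(kcat = c(-1, 0.4), km = c(0.1, 0.1)),
               "kcat")
  expect_error(sequential_scheme(kcat = 2.3, km = c(0.1, 0.1)),
               "both cycles")
})

test_that("schemes conserve enzyme and moieties reaction by reaction", {
  set.seed(7)
  for (i in 1:10) {
    sch <- random_sequential()
    expect_silent(validate_scheme(sch))
    enz <- setNames(sch$species$role %in% c("enzyme", "complex"),
                    sch$species$name)
    moi <- setNames(sch$species$moiety, sch$species$name)
    for (j in seq_len(nrow(sch$reactions))) {
      r <- sch$reactions[j, ]
      reac <- na.omit(c(r$r1, r$r2))
      prod <- na.omit(c(r$p1, r$p2))
      expect_equal(sum(enz[reac]), sum(enz[prod]))
      expect_equal(sum(moi[reac]), sum(moi[prod]))
    }
  }
  sch <- branched_scheme(c(0.35, 0.22), 1.1, c(0.95, 1.0), c(18, 15))
  expect_silent(validate_scheme(sch))
})

test_that("branched scheme partitions one shared ES complex", {
  sch <- branched_scheme(kcat1 = c(0.35, 0.22), km1 = 1.1,
                         kcat2 = c(0.95, 1.0), km2 = c(18, 15))
  expect_setequal(sch$species$name,
                  c("E", "S", "ES", "P1a", "P1b", "EP1a", "EP1b", "P2"))
  expect_equal(sum(sch$reactions$r1 == "ES" &
                     sch$reactions$kind == "catalytic"), 2)
  # both branches converge on the same P2
  expect_equal(sum(sch$reactions$p2 %in% "P2"), 2)
  # shared first-cycle Km covers both partition channels
  expect_equal((sch$rates[["kd1"]] + sch$rates[["kcat1a"]] +
                  sch$rates[["kcat1b"]]) / sch$rates[["ka1"]], 1.1)
  expect_error(branched_scheme(kcat1 = 0.35, km1 = 1.1,
                               kcat2 = c(0.95, 1.0), km2 = c(18, 15)),
               "both branches")
})

test_that("branched limiting case kcat1b = 0 reproduces sequential dynamics", {
  seqs <- sequential_scheme(kcat = c(0.35, 0.95), km = c(1.1, 18))
  bran <- branched_scheme(kcat1 = c(0.35, 0), km1 = 1.1,
                          kcat2 = c(0.95, 1.0), km2 = c(18, 15))
  times <- c(0, 5, 15, 30, 60, 120, 240, 360)
  fs <- species_fractions(integrate_scheme(seqs, c(E = 6, S = 500), times))
  fb <- species_fractions(integrate_scheme(bran, c(E = 6, S = 500), times))
  expect_equal(fb$P1b, rep(0, length(times)))
  expect_equal(fb$S, fs$S, tolerance = 1e-6)
  expect_equal(fb$P1a, fs$P1, tolerance = 1e-6)
  expect_equal(fb$P2, fs$P2, tolerance = 1e-6)
})

test_that("early-time mono branch fractions follow the kcat partition ratio", {
  # one committed complex partitions its flux as kcat1a : kcat1b, so the
  # mono class totals (free + enzyme-bound cargo) keep that ratio while
  # second-cycle consumption is still symmetric and small
  sch <- branched_scheme(kcat1 = c(0.9, 0.3), km1 = 2,
                         kcat2 = c(0.05, 0.05), km2 = c(50, 50), ka = 2)
  times <- c(0, 0.5, 1, 2)
  fr <- species_fractions(integrate_scheme(sch, c(E = 6, S = 500), times))
  ratio <- fr$P1a[-1] / fr$P1b[-1]
  expect_equal(ratio, rep(3, 3), tolerance = 1e-3)
  # verified against fine-step independent integration
  ork <- oracle_rk4(sch, c(E = 6, S = 500), times, h = 1e-3)
  r_oracle <- (ork[4, "P1a"] + ork[4, "EP1a"]) /
    (ork[4, "P1b"] + ork[4, "EP1b"])
  expect_equal(unname(r_oracle), 3, tolerance = 1e-3)
})

test_that("equal-branch scheme matches sequential with summed kcat", {
  set.seed(11)
  for (i in 1:5) {
    k <- runif(1, 0.1, 1)
    km1 <- 10^runif(1, -0.5, 1.5)
    k2 <- runif(1, 0.05, 0.5)
    km2 <- 10^runif(1, 0, 2)
    seqs <- sequential_scheme(kcat = c(2 * k, k2), km = c(km1, km2))
    bran <- branched_scheme(kcat1 = c(k, k), km1 = km1,
                            kcat2 = c(k2, k2), km2 = c(km2, km2))
    times <- c(0, 10, 40, 100)
    fs <- species_fractions(integrate_scheme(seqs, c(E = 6, S = 500), times))
    fb <- species_fractions(integrate_scheme(bran, c(E = 6, S = 500), times))
    expect_equal(fb$P1a + fb$P1b, fs$P1, tolerance = 1e-5)
    expect_equal(fb$S, fs$S, tolerance = 1e-5)
  }
})

test_that("invalid rate constants are rejected by name", {
  expect_error(micro_from_macro(-1, 0.5), "kcat")
  expect_error(sequential_scheme(c(1, 1), km = c(0, 1)), "km")
  expect_error(branched_scheme(c(1, -0.1), 1, c(1, 1), c(1, 1)), "kcat1")
})
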