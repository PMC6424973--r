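# Fitting tests. The slower, paper-scale recovery checks live in
# test-acceptance.R; here we exercise correctness properties on the
# cheapest configurations that show them.

test_that("noiseless self-consistency: the fit returns the generating values", {
  sch <- pltm_scheme("3", "Cl")
  tc <- simulate_timecourses(sch, assay_design("chlorination",
                                               replicates = 1),
                             sd = 0, seed = 1)
  fit <- fit_kinetics(tc, starts = 1)
  truth <- table1_truth("3")
  rr <- recovery_report(truth, fit, tol = 1e-3)
  expect_true(all(rr$within_tol))
  expect_lt(fit$ssr, 1e-8)
  expect_true(fit$converged)
})

test_that("the objective is minimal at the generating parameters (noiseless)", {
  sch <- pltm_scheme("11", "Cl")
  tc <- simulate_timecourses(sch, assay_design("chlorination", t720 = TRUE,
                                               replicates = 1),
                             sd = 0, seed = 1)
  truth <- table1_truth("11")
  fit <- suppressWarnings(
    fit_kinetics(tc, starts = 1, start = truth, maxiter = 0))
  obj <- function(lp) sum(fit$objective(lp)^2)
  at_truth <- obj(log10(truth))
  expect_lt(at_truth, 1e-10)
  set.seed(4)
  for (i in 1:20) {
    pert <- log10(truth) + runif(length(truth), -0.3, 0.3)
    expect_gte(obj(pert), at_truth)
  }
})

test_that("the objective is invariant to row and replicate order", {
  sch <- pltm_scheme("3", "Cl")
  tc <- simulate_timecourses(sch, assay_design("chlorination"), sd = 2,
                             seed = 5)
  truth <- table1_truth("3")
  f1 <- suppressWarnings(
    fit_kinetics(tc, starts = 1, start = truth, maxiter = 0))
  set.seed(1)
  shuffled <- tc[sample(nrow(tc)), ]
  attributes(shuffled)[c("design", "classes")] <-
    attributes(tc)[c("design", "classes")]
  class(shuffled) <- class(tc)
  f2 <- suppressWarnings(
    fit_kinetics(shuffled, starts = 1, start = truth, maxiter = 0))
  expect_equal(f1$ssr, f2$ssr)
  # swapped replicate labels
  swapped <- tc
  swapped$replicate <- 3 - swapped$replicate
  f3 <- suppressWarnings(
    fit_kinetics(swapped, starts = 1, start = truth, maxiter = 0))
  expect_equal(f1$ssr, f3$ssr)
})

test_that("estimates are positive by construction and SEs behave", {
  sch <- pltm_scheme("3", "Cl")
  tc <- simulate_timecourses(sch, assay_design("chlorination"), sd = 2,
                             seed = 3)
  fit <- fit_kinetics(tc, starts = 2, seed = 1)
  expect_true(all(coef(fit) > 0))
  expect_true(all(is.na(fit$se) | fit$se >= 0))
  if (fit$identifiable) {
    v <- vcov(fit)
    expect_equal(v, t(v), tolerance = 1e-8)
    expect_true(all(eigen(v, only.values = TRUE)$values > -1e-8))
    # tight-binding regime: Km is far less identifiable than kcat
    rel_se <- fit$se / coef(fit)
    expect_gt(rel_se[["km1"]], 5 * rel_se[["kcat1"]])
  }
})

test_that("derived efficiencies match estimate ratios and the delta method
           agrees with Monte-Carlo propagation", {
  # fabricated converged fit: moderate, well-conditioned covariance
  est <- c(kcat1 = 2.3, km1 = 8, kcat2 = 0.4, km2 = 1)
  cl <- diag(c(0.02, 0.03, 0.02, 0.03)^2)
  cl[1, 2] <- cl[2, 1] <- 0.0001
  dimnames(cl) <- list(names(est), names(est))
  fit <- structure(list(estimates = est, cov_log = cl,
                        topology = "sequential"),
                   class = "halokin_fit")
  eff <- derived_efficiencies(fit)
  expect_equal(eff$efficiency, c(2.3 / 8, 0.4 / 1))
  # Monte-Carlo oracle: sample log10 parameters from the covariance
  set.seed(8)
  ch <- chol(cl)
  draws <- matrix(rnorm(1e5 * 4), ncol = 4) %*% ch
  draws <- sweep(draws, 2, log10(est), "+")
  mc_se1 <- sd(10^(draws[, 1] - draws[, 2]))
  mc_se2 <- sd(10^(draws[, 3] - draws[, 4]))
  expect_equal(eff$se[1], mc_se1, tolerance = 0.05)
  expect_equal(eff$se[2], mc_se2, tolerance = 0.05)
  # zero covariance propagates zero SE
  fit$cov_log <- cl * 0
  expect_equal(derived_efficiencies(fit)$se, c(0, 0))
  # undefined covariance: efficiency reported without SE
  fit$cov_log <- NULL
  eff <- derived_efficiencies(fit)
  expect_equal(eff$efficiency, c(2.3 / 8, 0.4 / 1))
  expect_true(all(is.na(eff$se)))
})

test_that("recovery_report flags errors and topology mismatches", {
  est <- c(kcat1 = 2.3, km1 = 0.076, kcat2 = 0.4, km2 = 0.11)
  fit <- structure(list(estimates = est), class = "halokin_fit")
  rr <- recovery_report(est, fit)
  expect_equal(rr$rel_error, rep(0, 4))
  expect_true(all(rr$within_tol))
  rr <- recovery_report(est * c(1.2, 1, 1, 1), fit, tol = 0.15)
  expect_false(rr$within_tol[rr$parameter == "kcat1"])
  expect_error(recovery_report(c(kcat1a = 1), fit), "topology mismatch")
})

test_that("asymptotic standard errors agree with a parametric bootstrap", {
  # checked on the well-conditioned turnover numbers (the Gauss-Newton
  # quadratic approximation is meaningless along a Km ridge)
  sch <- pltm_scheme("3", "Cl")
  tc <- simulate_timecourses(sch, assay_design("chlorination"), sd = 2,
                             seed = 2)
  fit <- fit_kinetics(tc, starts = 3, seed = 1)
  expect_true(fit$identifiable)
  boots <- simulate(fit, nsim = 20, seed = 11, sd = 2)
  bk <- vapply(boots, function(b) {
    coef(fit_kinetics(b, starts = 1, start = coef(fit)))[c("kcat1", "kcat2")]
  }, numeric(2))
  # robust spread: single-start refits occasionally hop to a secondary
  # optimum, which would dominate a plain standard deviation
  for (p in c("kcat1", "kcat2")) {
    ratio <- fit$se[[p]] / mad(bk[p, ])
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 2)
  }
})

test_that("confidence intervals do not shrink as noise grows", {
  sch <- pltm_scheme("11", "Cl")
  d <- assay_design("chlorination", t720 = TRUE)
  truth <- table1_truth("11")
  ses <- vapply(c(0.5, 2, 5), function(sd) {
    tc <- simulate_timecourses(sch, d, sd = sd, seed = 6)
    fit <- fit_kinetics(tc, starts = 1, start = truth)
    fit$se[["kcat1"]]
  }, numeric(1))
  expect_true(all(diff(ses) > 0))
})

test_that("fit methods are mutually consistent", {
  sch <- pltm_scheme("3", "Cl")
  tc <- simulate_timecourses(sch, assay_design("chlorination"), sd = 2,
                             seed = 4)
  truth <- table1_truth("3")
  fit <- fit_kinetics(tc, starts = 1, start = truth)
  expect_equal(deviance(fit), sum(residuals(fit)^2))
  obsm <- do.call(rbind, halokin:::tcs_matrices(tc)$mats)
  expect_equal(fitted(fit) + residuals(fit), obsm)
  pr <- predict(fit, times = c(0, 10, 20))
  expect_equal(dim(pr), c(3L, 4L))
  expect_equal(rowSums(pr[, -1]), rep(100, 3), tolerance = 1e-6)
  rep <- fit_report(fit)
  expect_match(rep$kcat_min[1], "±")
  expect_output(print(summary(fit)), "Catalytic efficiencies")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  # simulate() is reproducible
  s1 <- simulate(fit, nsim = 1, seed = 3)[[1]]
  s2 <- simulate(fit, nsim = 1, seed = 3)[[1]]
  expect_identical(s1$fraction_pct, s2$fraction_pct)
})
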