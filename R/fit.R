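#' Global progress-curve fit of two-cycle halogenation kinetics
#'
#' Fits a sequential or branched two-cycle mass-action scheme to percent
#' species fractions by global nonlinear regression: the unweighted sum of
#' squared residuals between observed and model fractions is minimized
#' over every observable class, time point and replicate simultaneously.
#' Free parameters are log10 turnover numbers and Michaelis constants per
#' step (positivity by construction); the association rate `ka` is not
#' identifiable from fractions and is held fixed. Optimization is
#' Levenberg-Marquardt (`minpack.lm::nls.lm`) with data-driven initial
#' guesses and seeded multi-start; standard errors come from the
#' Gauss-Newton covariance at the optimum.
#'
#' @param data A `timecourse_set` (from [simulate_timecourses()] or
#'   [read_timecourse_csv()]) with classes `S`, `P1`, `P2` (sequential) or
#'   `S`, `P1a`, `P1b`, `P2` (branched).
#' @param s0,e0 Initial substrate and enzyme concentrations (uM); taken
#'   from the data's design attribute when present.
#' @param ka Fixed association rate constant (uM^-1 min^-1).
#' @param starts Number of multi-start optimizations (first start uses the
#'   data-driven guess, the rest are seeded log-scale jitters of it).
#' @param seed Seed for the multi-start jitter.
#' @param start Optional named vector of starting values on the natural
#'   scale (overrides the data-driven guess).
#' @param weights Optional named numeric vector of per-class residual
#'   weights; default unweighted (all species are on the same percent
#'   scale).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return An object of class `halokin_fit`; see [coef.halokin_fit()],
#'   [summary.halokin_fit()], [predict.halokin_fit()],
#'   [derived_efficiencies()]. Non-convergence is flagged in
#'   `$converged`, never thrown; a singular Gauss-Newton covariance sets
#'   `$identifiable = FALSE` with `NA` standard errors.
#' @examples
#' sch <- sequential_scheme(c(2.3, 0.40), c(0.076, 0.11))
#' tc <- simulate_timecourses(sch, assay_design("chlorination"), sd = 0,
#'                            seed = 1)
#' fit <- fit_kinetics(tc, starts = 1)
#' coef(fit)
#' @export
fit_kinetics <- function(data, s0 = NULL, e0 = NULL, ka = 100, starts = 5,
                         seed = 1, start = NULL, weights = NULL,
                         maxiter = 100) {
  obs <- tcs_matrices(data)
  design <- attr(data, "design")
  if (is.null(s0)) s0 <- design$s0
  if (is.null(e0)) e0 <- design$e0
  if (is.null(s0) || is.null(e0)) {
    stop("supply 's0' and 'e0' (no design attribute on the data)",
         call. = FALSE)
  }
  topology <- if (all(c("P1a", "P1b") %in% obs$classes)) "branched"
              else "sequential"
  pnames <- if (topology == "sequential") {
    c("kcat1", "km1", "kcat2", "km2")
  } else {
    c("kcat1a", "kcat1b", "km1", "kcat2a", "km2a", "kcat2b", "km2b")
  }
  expected <- if (topology == "sequential") c("S", "P1", "P2")
              else c("S", "P1a", "P1b", "P2")
  if (!identical(obs$classes, expected)) {
    stop("data classes (", paste(obs$classes, collapse = ", "),
         ") do not match the ", topology, " scheme", call. = FALSE)
  }
  w <- rep(1, length(obs$classes))
  if (!is.null(weights)) {
    w <- weights[obs$classes]
    if (anyNA(w)) stop("'weights' must name every class", call. = FALSE)
  }
  wmat <- matrix(sqrt(w), length(obs$times), length(obs$classes),
                 byrow = TRUE)

  build <- scheme_builder(topology, ka)
  n_eval <- 0L
  resid_fun <- function(lp) {
    n_eval <<- n_eval + 1L
    model <- tryCatch({
      sch <- build(10^lp)
      traj <- integrate_scheme(sch, c(E = e0, S = s0), obs$times)
      fr <- species_fractions(traj)
      as.matrix(fr[, obs$classes, drop = FALSE])
    }, error = function(e) NULL)
    if (is.null(model)) {
      return(rep(1e3, length(obs$times) * length(obs$classes) *
                   length(obs$mats)))
    }
    unlist(lapply(obs$mats, function(m) as.vector((m - model) * wmat)))
  }

  guess <- if (!is.null(start)) {
    log10(start[pnames])
  } else {
    initial_guess(obs, s0, e0, topology, resid_fun)
  }
  names(guess) <- pnames
  lower <- ifelse(grepl("^kcat", pnames), -4, -3)
  upper <- ifelse(grepl("^kcat", pnames), 3, 4)
  guess <- pmin(pmax(guess, lower + 0.01), upper - 0.01)

  set.seed(seed %% 2147483646L + 1L)
  best <- NULL
  for (s in seq_len(max(1L, starts))) {
    p0 <- if (s == 1L) guess else {
      pmin(pmax(guess + stats::runif(length(guess), -0.5, 0.5),
                lower + 0.01), upper - 0.01)
    }
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-10, ftol = 1e-12,
                           ## finite-difference step must stay well above
                           ## the ODE solver's relative tolerance
                           epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    stop("all optimization starts failed; check the data and scheme",
         call. = FALSE)
  }

  lp_hat <- stats::setNames(best$par, pnames)
  est <- stats::setNames(10^lp_hat, pnames)
  r_hat <- resid_fun(lp_hat)
  ssr <- sum(r_hat^2)
  n <- length(r_hat)
  p <- length(lp_hat)
  df <- n - p
  converged <- best$info %in% c(1, 2, 3, 4)

  ## Gauss-Newton covariance on the log10 scale (central differences)
  J <- jacobian_num(resid_fun, lp_hat)
  s2 <- ssr / df
  cov_log <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  identifiable <- !is.null(cov_log) && all(is.finite(cov_log)) &&
    all(diag(cov_log) >= 0)
  if (identifiable) {
    dimnames(cov_log) <- list(pnames, pnames)
    se <- log(10) * est * sqrt(diag(cov_log))
  } else {
    if (!is.null(cov_log)) cov_log <- NULL
    se <- stats::setNames(rep(NA_real_, p), pnames)
    warning("singular Gauss-Newton covariance: standard errors undefined ",
            "(identifiability warning)", call. = FALSE)
  }

  structure(list(
    estimates = est, se = se, cov_log = cov_log, ssr = ssr, sigma = sqrt(s2),
    n_obs = n, df = df, converged = converged, info = best$info,
    message = best$message, n_eval = n_eval, topology = topology, ka = ka,
    s0 = s0, e0 = e0, times = obs$times, classes = obs$classes,
    n_replicates = length(obs$mats), data = data,
    identifiable = identifiable, objective = resid_fun
  ), class = "halokin_fit")
}

## closure mapping a natural-scale macro parameter vector to a scheme
scheme_builder <- function(topology, ka) {
  if (topology == "sequential") {
    function(p) {
      p <- unname(p)
      sequential_scheme(kcat = p[c(1, 3)], km = p[c(2, 4)], ka = ka)
    }
  } else {
    function(p) {
      p <- unname(p)
      branched_scheme(kcat1 = p[1:2], km1 = p[3],
                      kcat2 = p[c(4, 6)], km2 = p[c(5, 7)], ka = ka)
    }
  }
}

## data-driven starting values on the log10 scale:
## kcat from the maximal finite-difference slope of product formation / E0,
## Km from a 1-D log-spaced grid scan at the kcat guess (ties -> smaller Km)
initial_guess <- function(obs, s0, e0, topology, resid_fun) {
  avg <- Reduce(`+`, obs$mats) / length(obs$mats)
  slope_of <- function(y) {
    dy <- diff(y) / diff(obs$times)
    max(dy, 1e-4)
  }
  ## percent/min -> uM/min -> per-enzyme turnover
  to_kcat <- function(sl) max(sl / 100 * s0 / e0, 1e-3)
  if (topology == "sequential") {
    k1 <- to_kcat(slope_of(100 - avg[, "S"]))
    k2 <- to_kcat(slope_of(avg[, "P2"]))
    base <- c(log10(k1), 0, log10(k2), 0)
    base[2] <- grid_scan_km(base, 2, resid_fun)
    base[4] <- grid_scan_km(base, 4, resid_fun)
  } else {
    ktot <- to_kcat(slope_of(100 - avg[, "S"]))
    fa <- max(avg[, "P1a"] + 0.5 * avg[, "P2"])
    fb <- max(avg[, "P1b"] + 0.5 * avg[, "P2"])
    share_a <- fa / (fa + fb)
    k1a <- max(ktot * share_a, 1e-3)
    k1b <- max(ktot * (1 - share_a), 1e-3)
    k2 <- to_kcat(slope_of(avg[, "P2"])) / 2
    base <- c(log10(k1a), log10(k1b), 0, log10(k2), 0, log10(k2), 0)
    base[3] <- grid_scan_km(base, 3, resid_fun)
    base[5] <- grid_scan_km(base, 5, resid_fun)
    base[7] <- grid_scan_km(base, 7, resid_fun)
  }
  base
}

grid_scan_km <- function(base, idx, resid_fun,
                         grid = seq(-2, 3, by = 0.5)) {
  ssr <- vapply(grid, function(g) {
    p <- base
    p[idx] <- g
    sum(resid_fun(p)^2)
  }, numeric(1))
  grid[which.min(ssr)] # which.min ties break toward the smaller Km
}

## numeric Jacobian of a vector function, central differences
jacobian_num <- function(f, x, h = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Catalytic efficiencies with propagated uncertainty
#'
#' Computes `kcat/Km` per step with a first-order (delta-method) standard
#' error from the fit's full log-scale covariance. When the covariance is
#' undefined the efficiencies are reported without standard errors.
#'
#' @param fit A `halokin_fit`.
#' @return data.frame with columns `step`, `efficiency`
#'   (min^-1 uM^-1) and `se`.
#' @export
derived_efficiencies <- function(fit) {
  pairs <- if (fit$topology == "sequential") {
    list(`1` = c("kcat1", "km1"), `2` = c("kcat2", "km2"))
  } else {
    list(`1a` = c("kcat1a", "km1"), `1b` = c("kcat1b", "km1"),
         `2a` = c("kcat2a", "km2a"), `2b` = c("kcat2b", "km2b"))
  }
  out <- data.frame(step = names(pairs), efficiency = NA_real_,
                    se = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(pairs)) {
    kc <- pairs[[i]][1]
    km <- pairs[[i]][2]
    eff <- fit$estimates[[kc]] / fit$estimates[[km]]
    out$efficiency[i] <- eff
    if (!is.null(fit$cov_log)) {
      v <- fit$cov_log[kc, kc] + fit$cov_log[km, km] -
        2 * fit$cov_log[kc, km]
      out$se[i] <- eff * log(10) * sqrt(max(v, 0))
    }
  }
  out
}

#' Parameter-recovery report
#'
#' Compares fitted macroscopic constants against the generating truth,
#' reporting per-parameter relative errors and flagging parameters outside
#' a tolerance.
#'
#' @param truth Named numeric vector of true values; names must match
#'   `coef(fit)` (a name mismatch signals a topology mismatch).
#' @param fit A `halokin_fit`.
#' @param tol Relative-error flag threshold (default 0.15).
#' @return data.frame with `parameter`, `true`, `estimate`, `rel_error`,
#'   `within_tol`.
#' @export
recovery_report <- function(truth, fit, tol = 0.15) {
  est <- coef(fit)
  if (!setequal(names(truth), names(est))) {
    stop("topology mismatch: truth has parameters ",
         paste(names(truth), collapse = ", "), " but the fit has ",
         paste(names(est), collapse = ", "), call. = FALSE)
  }
  truth <- truth[names(est)]
  rel <- abs(est - truth) / truth
  data.frame(parameter = names(est), true = unname(truth),
             estimate = unname(est), rel_error = unname(rel),
             within_tol = unname(rel <= tol), stringsAsFactors = FALSE)
}
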