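#' @export
coef.halokin_fit <- function(object, ...) object$estimates

#' @export
deviance.halokin_fit <- function(object, ...) object$ssr

#' Natural-scale covariance of the fitted constants
#'
#' Delta-transformed from the log10-scale Gauss-Newton covariance.
#' Returns `NULL` when the covariance is undefined.
#' @param object A `halokin_fit`.
#' @param ... Unused.
#' @export
vcov.halokin_fit <- function(object, ...) {
  if (is.null(object$cov_log)) return(NULL)
  d <- diag(log(10) * object$estimates,
            nrow = length(object$estimates))
  v <- d %*% object$cov_log %*% d
  dimnames(v) <- dimnames(object$cov_log)
  v
}

#' @export
print.halokin_fit <- function(x, ...) {
  cat("Global progress-curve fit (", x$topology, " two-cycle scheme)\n",
      sep = "")
  cat(x$n_obs, "observations:", length(x$times), "time points x",
      length(x$classes), "classes x", x$n_replicates, "replicate(s)\n")
  cat("ka fixed at", x$ka, "uM^-1 min^-1; S0 =", x$s0, "uM, E0 =", x$e0,
      "uM\n")
  est <- format(signif(x$estimates, 3))
  se <- ifelse(is.na(x$se), "NA", format(signif(x$se, 2)))
  cat("Estimates (kcat in min^-1, Km in uM):\n")
  print(data.frame(estimate = est, se = se), right = TRUE)
  cat("Residual SSR:", signif(x$ssr, 4), " sigma:", signif(x$sigma, 3),
      "percentage points\n")
  if (!x$converged) cat("WARNING: optimizer did not converge (info ",
                        x$info, ": ", x$message, ")\n", sep = "")
  if (!x$identifiable) {
    cat("WARNING: singular covariance; standard errors undefined\n")
  }
  invisible(x)
}

#' Summarize a progress-curve fit
#'
#' @param object A `halokin_fit`.
#' @param ... Unused.
#' @return A `summary.halokin_fit` with the parameter table (estimate,
#'   SE) and the derived catalytic efficiencies.
#' @export
summary.halokin_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$estimates, se = object$se)
  structure(list(fit = object, parameters = tab,
                 efficiencies = derived_efficiencies(object)),
            class = "summary.halokin_fit")
}

#' @export
print.summary.halokin_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCatalytic efficiencies (min^-1 uM^-1):\n")
  eff <- x$efficiencies
  eff$efficiency <- signif(eff$efficiency, 3)
  eff$se <- signif(eff$se, 2)
  print(eff, row.names = FALSE)
  invisible(x)
}

#' Model species fractions at the fitted parameters
#'
#' @param object A `halokin_fit`.
#' @param times Time grid (min); defaults to a fine grid over the data's
#'   range.
#' @param ... Unused.
#' @return data.frame of percent fractions as in [species_fractions()].
#' @export
predict.halokin_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) {
    times <- seq(0, max(object$times), length.out = 201)
  }
  sch <- scheme_builder(object$topology, object$ka)(object$estimates)
  species_fractions(
    integrate_scheme(sch, c(E = object$e0, S = object$s0), times))
}

#' @export
fitted.halokin_fit <- function(object, ...) {
  fr <- predict(object, times = object$times)
  m <- as.matrix(fr[, object$classes, drop = FALSE])
  do.call(rbind, replicate(object$n_replicates, m, simplify = FALSE))
}

#' @export
residuals.halokin_fit <- function(object, ...) {
  obs <- tcs_matrices(object$data)
  do.call(rbind, obs$mats) - fitted(object)
}

#' Plot observed fractions and fitted progress curves
#'
#' Observed percent fractions (points, one symbol per replicate) overlaid
#' with the fitted model curves per observable class.
#'
#' @param x A `halokin_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.halokin_fit <- function(x, ...) {
  fr <- predict(x)
  cols <- stats::setNames(seq_along(x$classes) + 1L, x$classes)
  graphics::plot(NA, xlim = range(x$times), ylim = c(0, 100),
                 xlab = "time (min)", ylab = "fraction of species (%)", ...)
  d <- x$data
  for (cl in x$classes) {
    graphics::lines(fr$time_min, fr[[cl]], col = cols[[cl]], lwd = 2)
    sub <- d[d$class == cl, ]
    graphics::points(sub$time_min, sub$fraction_pct, col = cols[[cl]],
                     pch = sub$replicate)
  }
  graphics::legend("right", legend = x$classes, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Simulate new datasets from a fitted model
#'
#' Parametric simulation: regenerates noisy replicate time courses at the
#' fitted parameters under the original design, with noise sd equal to the
#' fit's residual sigma (the basis of parametric bootstrapping).
#'
#' @param object A `halokin_fit`.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param sd Noise sd in percentage points; defaults to the residual sigma.
#' @param ... Unused.
#' @return List of `timecourse_set` objects (length `nsim`).
#' @export
simulate.halokin_fit <- function(object, nsim = 1, seed = 1, sd = NULL,
                                 ...) {
  if (is.null(sd)) sd <- object$sigma
  sch <- scheme_builder(object$topology, object$ka)(object$estimates)
  design <- attr(object$data, "design")
  if (is.null(design)) {
    design <- assay_design("chlorination", s0 = object$s0, e0 = object$e0,
                           times = object$times,
                           replicates = object$n_replicates)
  }
  lapply(seq_len(nsim), function(i) {
    simulate_timecourses(sch, design, sd = sd,
                         seed = (seed + 7919L * i) %% 2147483646L)
  })
}
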