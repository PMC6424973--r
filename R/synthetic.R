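#' Optimized halogenation assay design
#'
#' The default designs mirror the optimized in vitro assay: substrate at
#' 0.5 mM for chlorination and bromination or 0.25 mM for iodination,
#' enzyme at 6 uM, duplicate reactions, quenched at fixed times
#' (0, 5, 15, 30, 60, 120, 240 and 360 min for chlorination/bromination,
#' optionally extended to 720 min for slow substrates; 0, 30, 60, 120, 240
#' and 480 min for iodination).
#'
#' @param mode One of `"chlorination"`, `"bromination"`, `"iodination"`.
#' @param s0,e0 Initial substrate and enzyme concentrations (uM);
#'   defaults from the mode.
#' @param times Quench time grid (min), sorted and starting at 0;
#'   defaults from the mode.
#' @param replicates Number of replicate reactions (default 2).
#' @param t720 If `TRUE`, append an additional 720 min quench point.
#' @return An `assay_design` list with fields `s0`, `e0`, `times`,
#'   `replicates`, `halide`.
#' @examples
#' assay_design("chlorination")
#' assay_design("iodination")$s0 # 250 uM
#' @export
assay_design <- function(mode = c("chlorination", "bromination", "iodination"),
                         s0 = NULL, e0 = 6, times = NULL, replicates = 2,
                         t720 = FALSE) {
  mode <- match.arg(mode)
  halide <- c(chlorination = "Cl", bromination = "Br", iodination = "I")[[mode]]
  if (is.null(s0)) s0 <- if (mode == "iodination") 250 else 500
  if (is.null(times)) {
    times <- if (mode == "iodination") {
      c(0, 30, 60, 120, 240, 480)
    } else {
      c(0, 5, 15, 30, 60, 120, 240, 360)
    }
  }
  if (t720) times <- union(times, 720)
  times <- sort(unique(times))
  if (times[1] != 0) stop("time grid must start at 0", call. = FALSE)
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  structure(list(s0 = s0, e0 = e0, times = times, replicates = replicates,
                 halide = halide, mode = mode),
            class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Assay design (", x$mode, "): S0 = ", x$s0, " uM, E0 = ", x$e0,
      " uM, ", x$replicates, " replicate(s)\n", sep = "")
  cat("quench times (min):", paste(x$times, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate noisy replicate time courses
#'
#' Integrates the scheme under the assay design and emits the HPLC
#' observable with additive Gaussian noise on the percent fractions
#' (clipped to \[0, 100\] and renormalized to sum 100). Noise is drawn
#' from one per-replicate stream derived from `seed` by a counter, so
#' adding replicates never perturbs the draws of earlier ones. With
#' `sd = 0` the observations equal the model fractions exactly.
#'
#' @param scheme A [kinetic_scheme].
#' @param design An [assay_design()].
#' @param sd Noise standard deviation in percentage points (default 2).
#' @param seed Integer seed; mandatory so every synthetic set is
#'   reproducible.
#' @return A `timecourse_set`: long data.frame with columns `replicate`,
#'   `time_min`, `class`, `fraction_pct`; attributes record design,
#'   generating scheme, sd and seed.
#' @examples
#' sch <- sequential_scheme(c(2.3, 0.4), c(0.076, 0.11))
#' tc <- simulate_timecourses(sch, assay_design("chlorination"), sd = 2,
#'                            seed = 7)
#' head(tc)
#' @export
simulate_timecourses <- function(scheme, design, sd = 2, seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (sd < 0) stop("'sd' must be non-negative", call. = FALSE)
  traj <- integrate_scheme(scheme, c(E = design$e0, S = design$s0),
                           design$times)
  fr <- species_fractions(traj)
  cls <- setdiff(names(fr), "time_min")
  model <- as.matrix(fr[, cls, drop = FALSE])
  reps <- vector("list", design$replicates)
  for (r in seq_len(design$replicates)) {
    obs <- model
    if (sd > 0) {
      ## independent stream per replicate, derived from the shared seed
      set.seed((seed + r * 1000003L) %% 2147483646L + 1L)
      noise <- matrix(stats::rnorm(length(obs), 0, sd), nrow(obs), ncol(obs))
      obs <- pmin(pmax(obs + noise, 0), 100)
      ## degenerate draw (every class clipped to 0): fall back to a
      ## uniform composition rather than dividing by zero
      dead <- rowSums(obs) == 0
      obs[dead, ] <- 100 / ncol(obs)
      obs <- obs * 100 / rowSums(obs)
      obs <- pmin(pmax(obs, 0), 100) # shave float round-off
    }
    reps[[r]] <- data.frame(
      replicate = r,
      time_min = rep(design$times, times = length(cls)),
      class = rep(cls, each = length(design$times)),
      fraction_pct = as.vector(obs),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, reps)
  structure(out,
            class = c("timecourse_set", "data.frame"),
            design = design, scheme = scheme, sd = sd, seed = seed,
            classes = cls)
}

#' @export
print.timecourse_set <- function(x, ...) {
  d <- attr(x, "design")
  cat("Time-course set:", length(unique(x$replicate)), "replicate(s),",
      length(unique(x$time_min)), "time points, classes:",
      paste(attr(x, "classes"), collapse = ", "), "\n")
  if (!is.null(d)) {
    cat("S0 =", d$s0, "uM, E0 =", d$e0, "uM\n")
  }
  print(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("... and", nrow(x) - 8, "more rows\n")
  invisible(x)
}

## observed fractions of one timecourse_set as a list of matrices
## (one per replicate, times x classes) in a fixed canonical order
tcs_matrices <- function(data) {
  cls <- sort(unique(data$class))
  ord <- c("S", "P1", "P1a", "P1b", "P2")
  cls <- cls[order(match(cls, ord))]
  times <- sort(unique(data$time_min))
  reps <- sort(unique(data$replicate))
  mats <- lapply(reps, function(r) {
    m <- matrix(NA_real_, length(times), length(cls),
                dimnames = list(NULL, cls))
    sub <- data[data$replicate == r, ]
    m[cbind(match(sub$time_min, times), match(sub$class, cls))] <-
      sub$fraction_pct
    if (anyNA(m)) {
      stop("replicate ", r, " is missing class/time combinations",
           call. = FALSE)
    }
    m
  })
  list(times = times, classes = cls, replicates = reps, mats = mats)
}
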