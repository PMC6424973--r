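#' Read a species-fraction time-course CSV
#'
#' Expects the long fixture layout: header
#' `replicate,time_min,class,fraction_pct`, UTF-8, "." decimal separator.
#' Per replicate and time point the class fractions must sum to about
#' 100 (within 5 percentage points, the scale of HPLC integration losses);
#' such rows are accepted and renormalized to exactly 100, with a warning
#' when the deviation is material. Anything further off is rejected.
#'
#' @param path CSV file path.
#' @return A `timecourse_set`.
#' @export
read_timecourse_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate", "time_min", "class", "fraction_pct")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("replicate", "time_min", "fraction_pct")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("non-numeric value in column '", col, "' at line ", bad + 1L,
           call. = FALSE)
    }
    raw[[col]] <- v
  }
  key <- paste(raw$replicate, raw$time_min, raw$class)
  if (anyDuplicated(key)) {
    stop("duplicate (replicate, time, class) row at line ",
         which(duplicated(key))[1] + 1L, call. = FALSE)
  }
  grp <- paste(raw$replicate, raw$time_min)
  sums <- tapply(raw$fraction_pct, grp, sum)
  off <- abs(sums - 100)
  if (any(off > 5)) {
    bad <- names(sums)[which.max(off)]
    stop("fractions sum to ", signif(sums[[bad]], 6),
         " (outside 100 +- 5) for replicate/time ", bad, call. = FALSE)
  }
  if (any(off > 1e-6)) {
    warning("fraction sums off 100 by up to ", signif(max(off), 3),
            "; renormalized", call. = FALSE)
  }
  raw$fraction_pct <- raw$fraction_pct * 100 / sums[grp]
  out <- raw[order(raw$replicate, match(raw$class, sort(unique(raw$class))),
                   raw$time_min), need]
  rownames(out) <- NULL
  structure(out, class = c("timecourse_set", "data.frame"),
            classes = sort(unique(out$class)))
}

#' Write a time-course set to CSV
#'
#' Inverse of [read_timecourse_csv()] (lossless round trip).
#'
#' @param data A `timecourse_set` (or compatible data.frame).
#' @param path Output path.
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @export
write_timecourse_csv <- function(data, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("'", path, "' exists; pass overwrite = TRUE", call. = FALSE)
  }
  cols <- c("replicate", "time_min", "class", "fraction_pct")
  utils::write.csv(as.data.frame(data)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a fraction table to CSV
#'
#' Columns `time_min` then one column per class, percent values with 4
#' decimals.
#'
#' @param fractions data.frame from [species_fractions()].
#' @param path Output path.
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @export
write_fractions_csv <- function(fractions, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("'", path, "' exists; pass overwrite = TRUE", call. = FALSE)
  }
  out <- fractions
  num <- setdiff(names(out), "time_min")
  out[num] <- lapply(out[num], function(v) sprintf("%.4f", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scheme/experiment configuration file
#'
#' Flat TOML-style key-value text: sections `[design]`,
#' `[parameters.cycle1]`, `[parameters.cycle2]` and, for branched schemes,
#' `[parameters.cycle1b]`/`[parameters.cycle2b]` (in which case `cycle1`
#' and `cycle2` describe branch a). Keys: `kcat` (min^-1), `km` (uM),
#' optional `ka` (uM^-1 min^-1); design keys `mode`, `s0`, `e0`,
#' `replicates`, `t720`.
#'
#' @param path Config file path.
#' @return List with elements `scheme` ([kinetic_scheme]) and `design`
#'   ([assay_design()]).
#' @export
read_scheme_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  conf <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      conf[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(gsub('^"|"$', "", trimws(paste(kv[-1], collapse = "="))))
      num <- suppressWarnings(as.numeric(val))
      conf[[section]][[key]] <- if (is.na(num)) val else num
    } else {
      stop("cannot parse config line: ", ln, call. = FALSE)
    }
  }
  cyc <- function(nm) conf[[paste0("parameters.", nm)]]
  c1 <- cyc("cycle1")
  c2 <- cyc("cycle2")
  if (is.null(c1) || is.null(c2)) {
    stop("config must contain [parameters.cycle1] and [parameters.cycle2]",
         call. = FALSE)
  }
  ka <- function(x) if (is.null(x$ka)) 100 else x$ka
  c1b <- cyc("cycle1b")
  c2b <- cyc("cycle2b")
  scheme <- if (is.null(c1b)) {
    sequential_scheme(kcat = c(c1$kcat, c2$kcat), km = c(c1$km, c2$km),
                      ka = c(ka(c1), ka(c2)))
  } else {
    if (is.null(c2b)) {
      stop("branched config needs [parameters.cycle2b] as well",
           call. = FALSE)
    }
    branched_scheme(kcat1 = c(c1$kcat, c1b$kcat), km1 = c1$km,
                    kcat2 = c(c2$kcat, c2b$kcat), km2 = c(c2$km, c2b$km),
                    ka = c(ka(c1), ka(c2), ka(c2b)))
  }
  d <- conf[["design"]]
  if (is.null(d)) d <- list()
  design <- assay_design(
    mode = if (is.null(d$mode)) "chlorination" else d$mode,
    s0 = d$s0, e0 = if (is.null(d$e0)) 6 else d$e0,
    replicates = if (is.null(d$replicates)) 2 else d$replicates,
    t720 = isTRUE(d$t720 == "true") || isTRUE(d$t720 == 1))
  list(scheme = scheme, design = design)
}

#' Read substrate descriptors
#'
#' CSV with columns `name`, `formula` (Hill notation) and `positions`
#' (e.g. `"1:OH,3:OH,5:CH3"`).
#'
#' @param path CSV file path.
#' @return Named list of [ring_substrate()] objects.
#' @export
read_substrates <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "positions")
  if (!all(need %in% names(raw))) {
    stop("substrate file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(raw)), function(i) {
    pairs <- strsplit(strsplit(raw$positions[i], ",")[[1]], ":")
    pos <- stats::setNames(vapply(pairs, `[`, character(1), 2),
                           vapply(pairs, `[`, character(1), 1))
    ring_substrate(raw$name[i], raw$formula[i], pos)
  })
  stats::setNames(out, raw$name)
}

## "value +- SE" with the SE at 2 significant figures and the value
## rounded to the SE's decimal place
format_pm <- function(value, se) {
  if (is.na(se)) return(format(signif(value, 3)))
  se2 <- signif(se, 2)
  digits <- max(0, -floor(log10(se2)) + 1)
  paste0(formatC(value, format = "f", digits = digits), " ± ",
         formatC(se2, format = "f", digits = digits))
}

#' Fit report in a kinetics-table layout
#'
#' One row per catalytic step with `kcat`, `Km` and the derived
#' efficiency, each formatted as value plus/minus SE (SE at 2 significant
#' figures).
#'
#' @param fit A `halokin_fit`.
#' @return data.frame with columns `step`, `kcat_min`, `km_uM`,
#'   `efficiency` (formatted strings).
#' @export
fit_report <- function(fit) {
  eff <- derived_efficiencies(fit)
  est <- coef(fit)
  se <- fit$se
  steps <- eff$step
  kc <- paste0("kcat", steps)
  km <- if (fit$topology == "sequential") paste0("km", steps) else
    c("km1", "km1", "km2a", "km2b")
  data.frame(
    step = steps,
    kcat_min = mapply(format_pm, est[kc], se[kc]),
    km_uM = mapply(format_pm, est[km], se[km]),
    efficiency = mapply(format_pm, eff$efficiency, eff$se),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a fit report to disk
#'
#' @param fit A `halokin_fit`.
#' @param path Output path.
#' @param format `"text"` (plain-text table) or `"csv"`.
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @export
write_fit_report <- function(fit, path, format = c("text", "csv"),
                             overwrite = FALSE) {
  format <- match.arg(format)
  if (file.exists(path) && !overwrite) {
    stop("'", path, "' exists; pass overwrite = TRUE", call. = FALSE)
  }
  rep <- fit_report(fit)
  if (format == "csv") {
    utils::write.csv(rep, path, row.names = FALSE)
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(
      paste("Global progress-curve fit:", fit$topology, "scheme"),
      paste0("ka fixed at ", fit$ka, " uM^-1 min^-1; SSR = ",
             signif(fit$ssr, 4)),
      "",
      utils::capture.output(print(rep, row.names = FALSE))
    ), con)
  }
  invisible(path)
}
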