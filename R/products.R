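## Monoisotopic atomic masses (Da) and isotope data, IUPAC/CODATA values.
## Pinned here as the single source for all mass arithmetic.
ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  F = 18.9984031627,
  Cl = 34.96885271,
  Br = 78.9183376,
  I = 126.904473
)
PROTON_MASS <- 1.007276467 # proton, electron-corrected

## two-isotope data for the convolved elements: (abundance %, mass shift Da)
ISOTOPE2 <- list(
  Cl = list(ab = c(75.76, 24.24) / 100, shift = 36.96590260 - 34.96885271),
  Br = list(ab = c(50.69, 49.31) / 100, shift = 80.9162906 - 78.9183376),
  C  = list(ab = c(98.93, 1.07) / 100,  shift = 13.003354835 - 12.0)
)

#' Parse a Hill-notation molecular formula
#'
#' @param formula String such as `"C6H6O3"` or `"C6H5ClO3"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C6H6O3")
#' @export
parse_formula <- function(formula) {
  if (is.list(formula) || is.numeric(formula)) return(formula)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (length(parts) == 0 || sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(ifelse(grepl("[0-9]", parts),
                         sub("^[A-Za-z]+", "", parts), "1"))
  counts <- tapply(n, el, sum)
  stats::setNames(as.integer(counts), names(counts))
}

## element counts -> Hill notation (C, H, then alphabetical)
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  el <- names(counts)
  ord <- c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  paste0(ord, ifelse(counts[ord] > 1, counts[ord], ""), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of standard monoisotopic atomic masses.
#'
#' @param formula Hill-notation string or named element-count vector.
#'   Supported elements: C, H, N, O, S, F, Cl, Br, I.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C6H6O3") # phloroglucinol, ~126.0317
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(ATOMIC_MASS))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("negative element count", call. = FALSE)
  sum(ATOMIC_MASS[names(counts)] * counts)
}

#' Adduct m/z of a product ion
#'
#' `[M-H]-` is M minus a proton mass; `[M+H]+` is M plus a proton mass.
#'
#' @param formula Formula (string or counts) or a `halogenation_product`.
#' @param mode `"negative"` (`[M-H]-`) or `"positive"` (`[M+H]+`).
#' @return m/z in Da.
#' @examples
#' adduct_mz("C6H5ClO3", "negative") # ~158.9854
#' @export
adduct_mz <- function(formula, mode = c("negative", "positive")) {
  mode <- match.arg(mode)
  if (inherits(formula, "halogenation_product")) formula <- formula$formula
  m <- monoisotopic_mass(formula)
  if (mode == "negative") m - PROTON_MASS else m + PROTON_MASS
}

#' Ring substrate descriptor
#'
#' Abstract six-position aromatic ring: each position carries a
#' substituent label (`"H"` marks a halogenatable position), plus the
#' molecular formula of the whole molecule.
#'
#' @param name Substrate name.
#' @param formula Hill-notation molecular formula.
#' @param positions Named character vector or list mapping position
#'   numbers (1-6) to substituent labels, e.g. `c("1" = "OH", "3" = "OH")`;
#'   unspecified positions default to `"H"`.
#' @return A `ring_substrate` object.
#' @examples
#' ring_substrate("resorcinol", "C6H6O2", c("1" = "OH", "3" = "OH"))
#' @export
ring_substrate <- function(name, formula, positions) {
  subst <- rep("H", 6)
  pos <- as.integer(names(positions))
  if (anyNA(pos) || any(pos < 1 | pos > 6)) {
    stop("positions must be numbered 1-6", call. = FALSE)
  }
  subst[pos] <- unlist(positions, use.names = FALSE)
  counts <- parse_formula(formula)
  if (any(counts < 0)) stop("formula counts must be non-negative",
                            call. = FALSE)
  structure(list(name = name, formula = counts, substituents = subst),
            class = "ring_substrate")
}

#' @export
print.ring_substrate <- function(x, ...) {
  lab <- paste0(seq_len(6), ":", x$substituents)
  cat("Ring substrate", x$name, "(", format_formula(x$formula), ")\n")
  cat(" ", paste(lab[x$substituents != "H"], collapse = ", "), "\n")
  invisible(x)
}

HALIDES <- c("F", "Cl", "Br", "I")

#' Enumerate halogenation states under a halide pool
#'
#' All mono- and di-halogenated states (multisets of size 1 to
#' `max_total`) drawn from the pool. The enzyme adds at most two halogens
#' (trihalogenation is sterically excluded), and fluorination never
#' yields product, so F may appear in the pool but contributes no states.
#' Observed per-substrate restrictions (e.g. bromination stopping at the
#' mono stage) are supplied as data via `per_halide_caps` and
#' `forbidden_combos`, not derived.
#'
#' @param substrate A [ring_substrate()].
#' @param pool Character vector of halide symbols offered to the enzyme.
#' @param max_total Maximum total halogens (must be <= 2).
#' @param per_halide_caps Named integer vector, e.g. `c(Br = 1)`.
#' @param forbidden_combos List of length-2 character vectors naming
#'   hetero-pairs that are never formed, e.g. `list(c("Br", "I"))`.
#' @return List of `halogenation_product` objects, each with halogen
#'   counts, derived formula (each halogenation replaces one H with X)
#'   and a label.
#' @examples
#' phl <- ring_substrate("phloroglucinol", "C6H6O3",
#'                       c("1" = "OH", "3" = "OH", "5" = "OH"))
#' length(enumerate_halogenation_states(phl, c("Cl", "I"))) # 5
#' @export
enumerate_halogenation_states <- function(substrate, pool, max_total = 2,
                                          per_halide_caps = NULL,
                                          forbidden_combos = NULL) {
  unknown <- setdiff(pool, HALIDES)
  if (length(unknown)) {
    stop("unknown halide symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (max_total > 2) {
    stop("'max_total' cannot exceed 2: trihalogenation is never observed",
         call. = FALSE)
  }
  productive <- setdiff(pool, "F")
  states <- list()
  for (x in productive) states[[length(states) + 1L]] <- c(x)
  if (max_total >= 2 && length(productive)) {
    for (i in seq_along(productive)) {
      for (j in i:length(productive)) {
        states[[length(states) + 1L]] <- c(productive[i], productive[j])
      }
    }
  }
  keep <- vapply(states, function(st) {
    counts <- table(factor(st, levels = HALIDES))
    if (!is.null(per_halide_caps)) {
      for (h in names(per_halide_caps)) {
        if (counts[[h]] > per_halide_caps[[h]]) return(FALSE)
      }
    }
    if (!is.null(forbidden_combos)) {
      for (fc in forbidden_combos) {
        if (all(fc %in% st) && length(unique(st)) == 2) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  states <- states[keep]
  lapply(states, function(st) halogenation_product(substrate, st))
}

#' Construct a halogenated product of a ring substrate
#'
#' @param substrate A [ring_substrate()].
#' @param halogens Character vector of added halogens (length <= 2),
#'   e.g. `c("Cl", "I")`.
#' @param positions Optional integer vector of assigned ring positions.
#' @return A `halogenation_product` with the derived formula (one H is
#'   replaced per added halogen).
#' @export
halogenation_product <- function(substrate, halogens, positions = NULL) {
  if (length(halogens) > 2) {
    stop("at most two halogens can be installed", call. = FALSE)
  }
  unknown <- setdiff(halogens, HALIDES)
  if (length(unknown)) {
    stop("unknown halide symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- substrate$formula
  if (counts[["H"]] < length(halogens)) {
    stop("substrate has too few H atoms to halogenate", call. = FALSE)
  }
  counts[["H"]] <- counts[["H"]] - length(halogens)
  for (h in halogens) {
    counts[h] <- if (h %in% names(counts)) counts[[h]] + 1L else 1L
  }
  tab <- table(factor(halogens, levels = HALIDES))
  lab <- paste0(ifelse(tab > 1, tab, ""), names(tab))[tab > 0]
  structure(list(
    parent = substrate,
    halogens = sort(halogens),
    n_halogens = length(halogens),
    positions = positions,
    formula = counts,
    label = paste0(paste(lab, collapse = ""), "-", substrate$name)
  ), class = "halogenation_product")
}

#' @export
print.halogenation_product <- function(x, ...) {
  cat(x$label, " (", format_formula(x$formula), "), [M-H]- = ",
      round(adduct_mz(x$formula, "negative"), 4), " Da\n", sep = "")
  invisible(x)
}

#' Halogen isotope pattern of a product
#'
#' Convolves the two-isotope binomial distributions of 35Cl/37Cl
#' (75.76/24.24) and 79Br/81Br (50.69/49.31); iodine is monoisotopic.
#' `mode = "full"` additionally convolves 13C at natural abundance.
#' Peaks are reported as mass shifts relative to the monoisotopic peak
#' with abundances normalized so the base peak is 100.
#'
#' @param product A `halogenation_product`, or a formula (string/counts).
#' @param mode `"halogens_only"` (default) or `"full"`.
#' @return data.frame with columns `shift` (Da) and `abundance`,
#'   class `isotope_pattern`.
#' @examples
#' phl <- ring_substrate("phloroglucinol", "C6H6O3",
#'                       c("1" = "OH", "3" = "OH", "5" = "OH"))
#' isotope_pattern(halogenation_product(phl, "Cl"))
#' @export
isotope_pattern <- function(product, mode = c("halogens_only", "full")) {
  mode <- match.arg(mode)
  counts <- if (inherits(product, "halogenation_product")) {
    product$formula
  } else {
    parse_formula(product)
  }
  peaks <- data.frame(shift = 0, ab = 1)
  convolve_el <- function(peaks, el, n) {
    if (n == 0) return(peaks)
    iso <- ISOTOPE2[[el]]
    k <- 0:n
    comp <- data.frame(shift = k * iso$shift,
                       ab = stats::dbinom(k, n, iso$ab[2]))
    out <- merge(peaks, comp, by = NULL)
    out$shift <- out$shift.x + out$shift.y
    out$ab <- out$ab.x * out$ab.y
    stats::aggregate(ab ~ shift, data = out, FUN = sum)
  }
  els <- if (mode == "full") c("Cl", "Br", "C") else c("Cl", "Br")
  for (el in els) {
    n <- if (el %in% names(counts)) counts[[el]] else 0L
    peaks <- convolve_el(peaks, el, n)
  }
  ## merge peaks closer than 0.01 Da, drop below 0.01% of base
  peaks <- peaks[order(peaks$shift), ]
  peaks$bin <- round(peaks$shift, 2)
  ab <- tapply(peaks$ab, peaks$bin, sum)
  sh <- tapply(peaks$shift * peaks$ab, peaks$bin, sum) / ab
  out <- data.frame(shift = as.numeric(sh), abundance = as.numeric(ab))
  out$abundance <- 100 * out$abundance / max(out$abundance)
  out <- out[out$abundance >= 0.01, ]
  rownames(out) <- NULL
  structure(out, class = c("isotope_pattern", "data.frame"))
}

#' Match observed m/z peaks against candidate products (XIC logic)
#'
#' Each observed m/z is assigned every candidate whose adduct m/z lies in
#' the closed window `[mz - tolerance, mz + tolerance]` (the window is
#' closed because instrument tolerances are quoted as plus/minus; a
#' 1e-9 Da guard, far below instrument precision, keeps the boundary
#' deterministic in floating point).
#' Candidates outside the 80-600 m/z instrument range are never assigned.
#' Ambiguous assignments are reported, not resolved.
#'
#' @param observed_mz Numeric vector of observed m/z values (Da).
#' @param candidates List of `halogenation_product` objects.
#' @param mode Ionization mode, `"negative"` or `"positive"`.
#' @param tolerance Window half-width in Da (e.g. 0.05 for the survey
#'   assays, 0.005 for high-accuracy runs). Must be positive.
#' @param mz_range Instrument m/z window (default `c(80, 600)`).
#' @return data.frame with one row per (observed peak, candidate) match:
#'   `observed_mz`, `label`, `formula`, `mz`, `delta`.
#' @export
xic_match <- function(observed_mz, candidates,
                      mode = c("negative", "positive"), tolerance,
                      mz_range = c(80, 600)) {
  mode <- match.arg(mode)
  if (tolerance <= 0) stop("'tolerance' must be positive", call. = FALSE)
  if (length(candidates) == 0) {
    warning("empty candidate set: no assignments possible", call. = FALSE)
    return(data.frame(observed_mz = numeric(), label = character(),
                      formula = character(), mz = numeric(),
                      delta = numeric(), stringsAsFactors = FALSE))
  }
  cand <- data.frame(
    label = vapply(candidates, function(p) p$label, character(1)),
    formula = vapply(candidates, function(p) format_formula(p$formula),
                     character(1)),
    mz = vapply(candidates, function(p) adduct_mz(p, mode), numeric(1)),
    stringsAsFactors = FALSE
  )
  in_range <- cand$mz >= mz_range[1] & cand$mz <= mz_range[2]
  out <- list()
  for (mz in observed_mz) {
    hit <- in_range & abs(cand$mz - mz) <= tolerance + 1e-9
    if (any(hit)) {
      h <- cand[hit, , drop = FALSE]
      h$observed_mz <- mz
      h$delta <- h$mz - mz
      out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) {
    return(data.frame(observed_mz = numeric(), label = character(),
                      formula = character(), mz = numeric(),
                      delta = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("observed_mz", "label", "formula", "mz", "delta")]
}
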