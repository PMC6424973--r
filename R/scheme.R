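#' Michaelis constant from microscopic rate constants
#'
#' For a catalytic cycle E + X <-> EX -> products with association rate
#' `ka`, dissociation rate `kd` and turnover `kcat`, the Michaelis constant
#' is defined microscopically as \eqn{K_m = (k_d + k_{cat})/k_a}.
#'
#' @param kd Dissociation rate constant (min^-1).
#' @param kcat Turnover number (min^-1).
#' @param ka Association rate constant (uM^-1 min^-1); must be positive.
#' @return Michaelis constant in uM.
#' @seealso [micro_from_macro()] for the inverse mapping.
#' @examples
#' km_of(kd = 5.3, kcat = 2.3, ka = 100) # 0.076 uM
#' @export
km_of <- function(kd, kcat, ka) {
  if (any(ka <= 0)) {
    stop("invalid parameterization: 'ka' must be positive (got ",
         paste(ka[ka <= 0], collapse = ", "), ")", call. = FALSE)
  }
  if (any(kd < 0)) stop("'kd' must be non-negative", call. = FALSE)
  if (any(kcat < 0)) stop("'kcat' must be non-negative", call. = FALSE)
  (kd + kcat) / ka
}

#' Microscopic rate constants from macroscopic ones
#'
#' Inverts [km_of()] under a fixed association rate: given `kcat` and `Km`,
#' returns `(ka, kd, kcat)` with `kd = ka * Km - kcat`. Progress-curve
#' fractions do not identify `ka` on their own, so it is supplied (default
#' 100 uM^-1 min^-1, a fast but not diffusion-limited association rate).
#'
#' @param kcat Turnover number (min^-1).
#' @param km Michaelis constant (uM).
#' @param ka Fixed association rate constant (uM^-1 min^-1). Must satisfy
#'   `ka >= kcat / km`, otherwise the implied `kd` would be negative.
#' @return Named numeric vector with elements `ka`, `kd`, `kcat`.
#' @examples
#' micro_from_macro(kcat = 2.3, km = 0.076, ka = 100)
#' @export
micro_from_macro <- function(kcat, km, ka = 100) {
  if (kcat < 0) stop("'kcat' must be non-negative", call. = FALSE)
  if (km <= 0) stop("'km' must be positive", call. = FALSE)
  if (ka <= 0) stop("'ka' must be positive", call. = FALSE)
  kd <- ka * km - kcat
  if (kd < 0) {
    stop("catalytic efficiency kcat/km = ", signif(kcat / km, 4),
         " uM^-1 min^-1 exceeds the assumed association rate ka = ", ka,
         "; supply a larger 'ka'", call. = FALSE)
  }
  c(ka = unname(ka), kd = unname(kd), kcat = unname(kcat))
}

## internal constructor: assemble and validate a scheme object
new_scheme <- function(topology, species, reactions, rates, macro) {
  scheme <- structure(
    list(topology = topology, species = species, reactions = reactions,
         rates = rates, macro = macro),
    class = "kinetic_scheme"
  )
  validate_scheme(scheme)
  scheme
}

check_rate <- function(rates) {
  for (nm in names(rates)) {
    v <- rates[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop("rate constant '", nm, "' is missing", call. = FALSE)
    }
    if (v < 0) {
      stop("rate constant '", nm, "' is negative (", v, ")", call. = FALSE)
    }
  }
  invisible(rates)
}

#' Validate a kinetic scheme
#'
#' Checks the structural invariants of a [kinetic_scheme]: unique species
#' names, association reactions bimolecular and dissociation/catalytic
#' reactions unimolecular, every rate label resolvable, and conservation of
#' enzyme-containing species and substrate-derived aromatic cores
#' (moieties) across every reaction.
#'
#' @param scheme A `kinetic_scheme` object.
#' @return The scheme, invisibly; errors describe the violated invariant.
#' @export
validate_scheme <- function(scheme) {
  sp <- scheme$species
  rx <- scheme$reactions
  if (anyDuplicated(sp$name)) {
    stop("species names must be unique within a scheme", call. = FALSE)
  }
  bad_moiety <- (sp$role == "enzyme" & sp$moiety != 0) |
    (sp$role == "complex" & sp$moiety != 1)
  if (any(bad_moiety)) {
    stop("moiety counts: free enzyme carries 0, complexes exactly 1",
         call. = FALSE)
  }
  enz <- sp$role %in% c("enzyme", "complex")
  names(enz) <- sp$name
  moi <- sp$moiety
  names(moi) <- sp$name
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    reac <- stats::na.omit(c(r$r1, r$r2))
    prod <- stats::na.omit(c(r$p1, r$p2))
    if (!all(c(reac, prod) %in% sp$name)) {
      stop("reaction ", i, " references unknown species", call. = FALSE)
    }
    if (r$kind == "association" && (length(reac) != 2L || length(prod) != 1L)) {
      stop("association reactions must be bimolecular with one product",
           call. = FALSE)
    }
    if (r$kind != "association" && length(reac) != 1L) {
      stop("dissociation/catalytic reactions must be unimolecular",
           call. = FALSE)
    }
    if (sum(enz[reac]) != sum(enz[prod])) {
      stop("reaction ", i, " does not balance enzyme-containing species",
           call. = FALSE)
    }
    if (sum(moi[reac]) != sum(moi[prod])) {
      stop("reaction ", i, " does not balance substrate moieties",
           call. = FALSE)
    }
    if (!r$rate %in% names(scheme$rates)) {
      stop("rate label '", r$rate, "' does not resolve to a parameter",
           call. = FALSE)
    }
  }
  invisible(scheme)
}

#' Sequential two-cycle halogenation scheme
#'
#' Builds the mass-action scheme for halogenation through a single
#' mono-halogenated intermediate that is released and rebound:
#' \deqn{E + S \rightleftharpoons ES \rightarrow E + P_1;\quad
#'       E + P_1 \rightleftharpoons EP_1 \rightarrow E + P_2}
#' where E, S, P1 and P2 are enzyme, substrate, mono- and dihalogenated
#' product. The scheme is parameterized macroscopically: per cycle a
#' turnover number `kcat` and Michaelis constant `km`
#' (\eqn{K_m = (k_d + k_{cat})/k_a}), with the association rate `ka` fixed.
#'
#' @param kcat Numeric length 2: turnover numbers (min^-1) for the
#'   mono- and di-halogenation cycles.
#' @param km Numeric length 2: Michaelis constants (uM) per cycle.
#' @param ka Fixed association rate constant(s) (uM^-1 min^-1); recycled
#'   to both cycles.
#' @return A `kinetic_scheme` with 6 species (E, S, ES, P1, EP1, P2) and
#'   6 reactions. Observable classes: S (free substrate plus ES cargo),
#'   P1 (free mono product plus EP1 cargo), P2.
#' @examples
#' sch <- sequential_scheme(kcat = c(2.3, 0.40), km = c(0.076, 0.11))
#' sch
#' @export
sequential_scheme <- function(kcat, km, ka = 100) {
  if (length(kcat) != 2L || length(km) != 2L) {
    stop("'kcat' and 'km' must each supply both cycles (length 2)",
         call. = FALSE)
  }
  ka <- rep_len(ka, 2L)
  m1 <- micro_from_macro(kcat[1], km[1], ka[1])
  m2 <- micro_from_macro(kcat[2], km[2], ka[2])
  rates <- c(ka1 = m1[["ka"]], kd1 = m1[["kd"]], kcat1 = m1[["kcat"]],
             ka2 = m2[["ka"]], kd2 = m2[["kd"]], kcat2 = m2[["kcat"]])
  check_rate(as.list(rates))
  species <- data.frame(
    name  = c("E", "S", "ES", "P1", "EP1", "P2"),
    role  = c("enzyme", "substrate", "complex", "mono_product", "complex",
              "di_product"),
    moiety = c(0L, 1L, 1L, 1L, 1L, 1L),
    class = c(NA, "S", "S", "P1", "P1", "P2"),
    stringsAsFactors = FALSE
  )
  reactions <- data.frame(
    kind = c("association", "dissociation", "catalytic",
             "association", "dissociation", "catalytic"),
    rate = c("ka1", "kd1", "kcat1", "ka2", "kd2", "kcat2"),
    r1 = c("E", "ES", "ES", "E", "EP1", "EP1"),
    r2 = c("S", NA, NA, "P1", NA, NA),
    p1 = c("ES", "E", "E", "EP1", "E", "E"),
    p2 = c(NA, "S", "P1", NA, "P1", "P2"),
    stringsAsFactors = FALSE
  )
  macro <- data.frame(step = c("1", "2"), kcat = kcat, km = km, ka = ka,
                      kd = c(m1[["kd"]], m2[["kd"]]),
                      stringsAsFactors = FALSE)
  new_scheme("sequential", species, reactions, rates, macro)
}

#' Branched two-cycle halogenation scheme
#'
#' For an asymmetric substrate the first cycle yields two distinguishable
#' mono-halogenated regioisomers (branches a and b). A single shared ES
#' complex partitions between the branches:
#' \deqn{E + S \rightleftharpoons ES;\quad ES \rightarrow E + P_{1a};\quad
#'       ES \rightarrow E + P_{1b}}
#' and each mono product is rebound and converted to the common
#' dihalogenated product P2. Because the first cycle has one binding step,
#' its Michaelis constant \eqn{K_{m,1} = (k_{d,1}+k_{cat,1a}+k_{cat,1b})/k_{a,1}}
#' is shared between branches; each branch's efficiency is
#' \eqn{k_{cat,1x}/K_{m,1}}.
#'
#' @param kcat1 Numeric length 2 (order a, b): first-cycle turnover numbers
#'   (min^-1) for the two branches.
#' @param km1 Shared first-cycle Michaelis constant (uM).
#' @param kcat2 Numeric length 2 (order a, b): second-cycle turnover
#'   numbers per branch (min^-1).
#' @param km2 Numeric length 2 (order a, b): second-cycle Michaelis
#'   constants per branch (uM).
#' @param ka Fixed association rate constant(s) (uM^-1 min^-1); recycled
#'   over the three binding steps (ES, EP1a, EP1b).
#' @return A `kinetic_scheme` with 8 species
#'   (E, S, ES, P1a, P1b, EP1a, EP1b, P2) and 10 reactions; observable
#'   classes S, P1a, P1b, P2.
#' @examples
#' branched_scheme(kcat1 = c(0.35, 0.22), km1 = 1.1,
#'                 kcat2 = c(0.95, 1.0), km2 = c(18, 15))
#' @export
branched_scheme <- function(kcat1, km1, kcat2, km2, ka = 100) {
  if (length(kcat1) != 2L) {
    stop("both branches of 'kcat1' must be supplied (length 2: a, b)",
         call. = FALSE)
  }
  if (length(kcat2) != 2L || length(km2) != 2L) {
    stop("both branches of the second cycle must be supplied", call. = FALSE)
  }
  if (length(km1) != 1L) stop("'km1' is shared: supply one value", call. = FALSE)
  ka <- rep_len(ka, 3L)
  if (any(kcat1 < 0)) stop("rate constant 'kcat1' is negative", call. = FALSE)
  if (km1 <= 0) stop("'km1' must be positive", call. = FALSE)
  kd1 <- ka[1] * km1 - sum(kcat1)
  if (kd1 < 0) {
    stop("first-cycle efficiency (kcat1a + kcat1b)/km1 exceeds the assumed ",
         "association rate ka = ", ka[1], "; supply a larger 'ka'",
         call. = FALSE)
  }
  m2a <- micro_from_macro(kcat2[1], km2[1], ka[2])
  m2b <- micro_from_macro(kcat2[2], km2[2], ka[3])
  rates <- c(ka1 = ka[1], kd1 = kd1, kcat1a = kcat1[1], kcat1b = kcat1[2],
             ka2a = m2a[["ka"]], kd2a = m2a[["kd"]], kcat2a = m2a[["kcat"]],
             ka2b = m2b[["ka"]], kd2b = m2b[["kd"]], kcat2b = m2b[["kcat"]])
  check_rate(as.list(rates))
  species <- data.frame(
    name  = c("E", "S", "ES", "P1a", "P1b", "EP1a", "EP1b", "P2"),
    role  = c("enzyme", "substrate", "complex", "mono_product",
              "mono_product", "complex", "complex", "di_product"),
    moiety = c(0L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    class = c(NA, "S", "S", "P1a", "P1b", "P1a", "P1b", "P2"),
    stringsAsFactors = FALSE
  )
  reactions <- data.frame(
    kind = c("association", "dissociation", "catalytic", "catalytic",
             "association", "dissociation", "catalytic",
             "association", "dissociation", "catalytic"),
    rate = c("ka1", "kd1", "kcat1a", "kcat1b",
             "ka2a", "kd2a", "kcat2a",
             "ka2b", "kd2b", "kcat2b"),
    r1 = c("E", "ES", "ES", "ES", "E", "EP1a", "EP1a", "E", "EP1b", "EP1b"),
    r2 = c("S", NA, NA, NA, "P1a", NA, NA, "P1b", NA, NA),
    p1 = c("ES", "E", "E", "E", "EP1a", "E", "E", "EP1b", "E", "E"),
    p2 = c(NA, "S", "P1a", "P1b", NA, "P1a", "P2", NA, "P1b", "P2"),
    stringsAsFactors = FALSE
  )
  macro <- data.frame(
    step = c("1a", "1b", "2a", "2b"),
    kcat = c(kcat1, kcat2),
    km = c(km1, km1, km2),
    ka = ka[c(1, 1, 2, 3)],
    kd = c(kd1, kd1, m2a[["kd"]], m2b[["kd"]]),
    stringsAsFactors = FALSE
  )
  new_scheme("branched", species, reactions, rates, macro)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme:", x$topology, "two-cycle halogenation\n")
  cat(nrow(x$species), "species,", nrow(x$reactions), "reactions\n")
  cat("Macroscopic constants (time in min, concentration in uM):\n")
  print(x$macro, row.names = FALSE)
  invisible(x)
}

## observable classes of a scheme, in canonical order
scheme_classes <- function(scheme) {
  cls <- unique(stats::na.omit(scheme$species$class))
  ord <- c("S", "P1", "P1a", "P1b", "P2")
  cls[order(match(cls, ord))]
}
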