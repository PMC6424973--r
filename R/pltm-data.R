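#' Published kinetic constants for PltM halogenation
#'
#' Macroscopic constants (turnover number, Michaelis constant and
#' catalytic efficiency with reported uncertainties) for the chlorination
#' and bromination of the three substrates whose progress curves were
#' quantified for PltM: resorcinol (substrate 3), 3,5-dihydroxybenzyl
#' alcohol (substrate 11) and 3-aminophenol (substrate 16). Substrates 3
#' and 11 follow the sequential scheme (one mono intermediate); substrate
#' 16 is asymmetric and branches into two mono intermediates (steps 1a/1b
#' and 2a/2b). The branched rows share one first-cycle Km, as expected
#' for a single partitioning ES complex.
#'
#' @param substrate Optional filter: one of `"3"`, `"11"`, `"16"`.
#' @param halide Optional filter: `"Cl"` or `"Br"`.
#' @return data.frame with columns `substrate`, `halide`, `step`,
#'   `kcat`, `kcat_se` (min^-1), `km`, `km_se` (uM), `eff`, `eff_se`
#'   (min^-1 uM^-1) and `topology`.
#' @examples
#' pltm_kinetic_table("3", "Cl")
#' @export
pltm_kinetic_table <- function(substrate = NULL, halide = NULL) {
  tab <- data.frame(
    substrate = c(rep("3", 4), rep("11", 3), rep("16", 8)),
    halide = c("Cl", "Cl", "Br", "Br",
               "Cl", "Cl", "Br",
               rep("Cl", 4), rep("Br", 4)),
    step = c("1", "2", "1", "2",
             "1", "2", "1",
             "1a", "1b", "2a", "2b", "1a", "1b", "2a", "2b"),
    kcat = c(2.3, 0.40, 1.9, 0.38,
             1.6, 0.18, 0.24,
             0.35, 0.22, 0.95, 1.0, 0.47, 2.2, 0.21, 2.0),
    kcat_se = c(0.1, 0.01, 0.1, 0.01,
                0.1, 0.01, 0.02,
                0.01, 0.01, 0.01, 0.1, 0.04, 0.1, 0.02, 0.1),
    km = c(0.076, 0.11, 0.71, 0.78,
           8.4, 0.44, 1100,
           1.1, 1.1, 18, 15, 151, 151, 6.0, 1300),
    km_se = c(0.013, 0.02, 0.2, 0.17,
              0.4, 0.02, 200,
              0.3, 0.3, 5, 9, 20, 20, 1.2, 100),
    eff = c(30, 3.5, 2.7, 0.49,
            0.19, 0.41, 2.2e-4,
            0.31, 0.19, 5.2e-2, 7.0e-2, 3.1e-3, 1.5e-2, 3.5e-2, 1.5e-3),
    eff_se = c(5, 0.6, 0.6, 0.11,
               0.01, 0.02, 0.2e-4,
               0.09, 0.06, 1.4e-2, 4.4e-2, 0.5e-3, 0.2e-2, 0.8e-2, 0.2e-3),
    stringsAsFactors = FALSE
  )
  tab$topology <- ifelse(tab$substrate == "16", "branched", "sequential")
  if (!is.null(substrate)) tab <- tab[tab$substrate == substrate, ]
  if (!is.null(halide)) tab <- tab[tab$halide == halide, ]
  rownames(tab) <- NULL
  tab
}

#' Kinetic scheme from the published constants
#'
#' Instantiates the sequential or branched scheme for one
#' substrate/halide combination of [pltm_kinetic_table()], with the
#' association rate fixed (the published table reports only macroscopic
#' constants).
#'
#' @param substrate `"3"`, `"11"` or `"16"`.
#' @param halide `"Cl"` or `"Br"`.
#' @param ka Fixed association rate constant (uM^-1 min^-1).
#' @return A [kinetic_scheme]. Monobromination-only rows (substrate 11
#'   with Br) are not instantiable as a two-cycle scheme and raise an
#'   error.
#' @examples
#' pltm_scheme("3", "Cl")
#' @export
pltm_scheme <- function(substrate, halide = "Cl", ka = 100) {
  tab <- pltm_kinetic_table(substrate, halide)
  if (nrow(tab) == 0) {
    stop("no published constants for substrate ", substrate, " with ",
         halide, call. = FALSE)
  }
  if (tab$topology[1] == "sequential") {
    if (nrow(tab) < 2) {
      stop("substrate ", substrate, "/", halide, " has no second cycle ",
           "(mono-halogenation only)", call. = FALSE)
    }
    sequential_scheme(kcat = tab$kcat[match(c("1", "2"), tab$step)],
                      km = tab$km[match(c("1", "2"), tab$step)], ka = ka)
  } else {
    branched_scheme(
      kcat1 = tab$kcat[match(c("1a", "1b"), tab$step)],
      km1 = tab$km[match("1a", tab$step)],
      kcat2 = tab$kcat[match(c("2a", "2b"), tab$step)],
      km2 = tab$km[match(c("2a", "2b"), tab$step)],
      ka = ka)
  }
}

#' Substrate descriptors for the regiochemistry engine
#'
#' The abstract six-position ring maps and molecular formulas of the
#' single-ring phenolic/aniline substrates used in the halogenation
#' regiochemistry analysis, numbered as in their input naming. Fused or
#' second-ring substrates (e.g. catechin, fenoterol) are outside the ring
#' engine's scope; resveratrol is represented by its resorcinol-type ring
#' with the styrenyl substituent abstracted to one label.
#'
#' @return Named list of [ring_substrate()] objects.
#' @export
pltm_substrates <- function() {
  list(
    `1` = ring_substrate("phloroglucinol", "C6H6O3",
                         c("1" = "OH", "3" = "OH", "5" = "OH")),
    `3` = ring_substrate("resorcinol", "C6H6O2",
                         c("1" = "OH", "3" = "OH")),
    `8` = ring_substrate("2-chlororesorcinol", "C6H5ClO2",
                         c("1" = "OH", "2" = "Cl", "3" = "OH")),
    `9` = ring_substrate("orcinol", "C7H8O2",
                         c("1" = "OH", "3" = "OH", "5" = "CH3")),
    `11` = ring_substrate("3,5-dihydroxybenzyl alcohol", "C7H8O3",
                          c("1" = "CH2OH", "3" = "OH", "5" = "OH")),
    `15` = ring_substrate("2,4,6-trihydroxyacetophenone", "C8H8O4",
                          c("1" = "COCH3", "2" = "OH", "4" = "OH",
                            "6" = "OH")),
    `16` = ring_substrate("3-aminophenol", "C6H7NO",
                          c("1" = "OH", "3" = "NH2")),
    `18` = ring_substrate("m-phenylenediamine", "C6H8N2",
                          c("1" = "NH2", "3" = "NH2")),
    `19` = ring_substrate("3-nitrophenol", "C6H5NO3",
                          c("1" = "OH", "3" = "NO2")),
    `23` = ring_substrate("resveratrol", "C14H12O3",
                          c("1" = "styrenyl", "3" = "OH", "5" = "OH"))
  )
}
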