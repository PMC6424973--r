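#' Predict halogenation ring positions
#'
#' Rule engine for the regioselectivity of phenolic halogenation observed
#' for PltM: halogenation occurs ortho to the activating polar groups
#' (OH, NH2) but not between two of them, with one exception — when a
#' methyl or styrenyl substituent sits meta to two hydroxyls, the position
#' between the hydroxyls is halogenated with top priority. Nitro-bearing
#' substrates are not halogenated at all.
#'
#' Candidate positions (those carrying H) score +1 per ortho activating
#' group. A position flanked by two activating groups ("between") is
#' excluded whenever any non-between candidate exists; the meta
#' carbon-substituent exception re-includes it with top priority. The
#' `n_halogens` top-scoring positions are returned, with
#' symmetry-equivalent selections collapsed to their lowest-locant
#' representative.
#'
#' @param substrate A [ring_substrate()].
#' @param n_halogens 1 or 2 (the enzyme never installs a third halogen).
#' @return List of integer vectors (sorted ring positions), one per
#'   distinct maximal-scoring selection; empty list for nitro-bearing
#'   substrates.
#' @examples
#' resorcinol <- ring_substrate("resorcinol", "C6H6O2",
#'                              c("1" = "OH", "3" = "OH"))
#' predict_positions(resorcinol, 2) # positions 4 and 6
#' @export
predict_positions <- function(substrate, n_halogens) {
  if (n_halogens > 2) {
    stop("the enzyme cannot install more than two halogens ",
         "(trihalogenation is never observed)", call. = FALSE)
  }
  if (n_halogens < 1) stop("'n_halogens' must be 1 or 2", call. = FALSE)
  subst <- substrate$substituents
  if (any(subst == "NO2")) return(list())
  activating <- subst %in% c("OH", "NH2")
  if (!any(activating)) {
    stop("substrate has no activating group (OH or NH2)", call. = FALSE)
  }
  nbr <- function(p) c((p - 2) %% 6 + 1, p %% 6 + 1) # ring neighbours
  cand <- which(subst == "H")
  score <- vapply(cand, function(p) sum(activating[nbr(p)]), numeric(1))
  between <- score == 2
  cand <- cand[score >= 1]
  between <- between[score >= 1]
  score <- score[score >= 1]

  ## meta carbon-substituent exception: CH3/styrenyl meta to two hydroxyls
  ## promotes the position between those hydroxyls
  meta <- function(p) c((p + 1) %% 6 + 1, (p - 3) %% 6 + 1)
  for (p in which(subst %in% c("CH3", "styrenyl"))) {
    m <- meta(p)
    if (all(subst[m] == "OH")) {
      betw <- (p + 2) %% 6 + 1 # opposite position, flanked by the two OH
      i <- match(betw, cand)
      if (!is.na(i)) {
        score[i] <- score[i] + 10
        between[i] <- FALSE
      }
    }
  }
  if (any(!between)) {
    cand <- cand[!between]
    score <- score[!between]
  }
  if (length(cand) < n_halogens) {
    stop("fewer candidate positions (", length(cand), ") than requested ",
         "halogens", call. = FALSE)
  }
  sets <- utils::combn(seq_along(cand), n_halogens, simplify = FALSE)
  tot <- vapply(sets, function(i) sum(score[i]), numeric(1))
  best <- sets[tot == max(tot)]
  picks <- lapply(best, function(i) sort(cand[i]))
  picks <- unique(lapply(picks, canonical_positions, substrate = substrate))
  picks[order(vapply(picks, paste, character(1), collapse = ","))]
}

## ring automorphisms (dihedral group of the hexagon) preserving the
## substituent map
ring_automorphisms <- function(substrate) {
  subst <- substrate$substituents
  perms <- list()
  for (k in 0:5) {
    perms[[length(perms) + 1L]] <- ((0:5 + k) %% 6) + 1          # rotation
    perms[[length(perms) + 1L]] <- ((k - (0:5)) %% 6) + 1        # reflection
  }
  keep <- vapply(perms, function(pm) all(subst[pm] == subst), logical(1))
  perms[keep]
}

## lowest-locant representative of a position set under the substrate's
## ring symmetry
canonical_positions <- function(pos, substrate) {
  autos <- ring_automorphisms(substrate)
  images <- lapply(autos, function(pm) sort(pm[pos]))
  keys <- vapply(images, paste, character(1), collapse = ",")
  images[[order(vapply(images, function(v) sum(v * 10^rev(seq_along(v))),
                       numeric(1)), keys)[1]]]
}
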