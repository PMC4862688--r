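# Alchemical prediction of circular-permutant destabilization:
# ddG_tot = dG_J (cyclization) + dG_C (loop cut).

#' Per-residue unfolding entropy from the contact map
#'
#' `ds = sum(eps) / (T * N)`: the per-residue entropy change that makes the
#' total entropic cost of ordering all N residues cancel the total contact
#' energy at the folding temperature T.  With favourable (negative) contact
#' energies ds is negative; the join/cut free energies use its magnitude as
#' the entropy gained per unfolded residue.
#'
#' @param contact_map a `contact_map` tibble.
#' @param temperature folding temperature, K.
#' @param n_residues N; defaults to the map's `n_residues` attribute.
#' @return ds in kcal/mol/K.
#' @export
entropy_per_residue <- function(contact_map, temperature,
                                n_residues = NULL) {
  cm <- as_tibble(contact_map)
  if (nrow(cm) == 0) abort("empty contact map")
  n_residues <- n_residues %||% attr(contact_map, "n_residues")
  sum(cm$eps) / (temperature * n_residues)
}

#' Turn offset for joining the termini
#'
#' When the backbone directions at the N and C termini oppose each other
#' (dot product < 0) the joining loop must spend about six residues (three a
#' side) forming the turn, which do not contribute to its effective length:
#' M = 6.  Termini running the same way need no turn: M = 0.
#'
#' @param structure a [calpha_structure()].
#' @return 0 or 6.
#' @export
termini_offset <- function(structure) {
  tv <- structure$termini_vectors
  if (any(!is.finite(tv))) abort("chain too short to define termini vectors")
  if (sum(tv[1, ] * tv[2, ]) < 0) 6L else 0L
}

peel_cost <- function(peeled, contact_map, ds, temperature) {
  cm <- as_tibble(contact_map)
  if (length(peeled) == 0) {
    return(list(energy = 0, kappa = 0L, n = 0L, dG = 0))
  }
  busy <- unique(c(cm$i, cm$j))
  broken <- cm$i %in% peeled | cm$j %in% peeled
  kappa <- sum(!(peeled %in% busy))
  energy <- sum(abs(cm$eps[broken]))
  list(energy = energy, kappa = kappa, n = length(peeled),
       dG = energy - temperature * (length(peeled) - kappa) * abs(ds))
}

#' Cyclization free energy dG_J
#'
#' Searches the peel windows (up to nine residues off each terminus) for the
#' cheapest way to bring the chain ends close enough to join: peeling
#' residues 1..i and j+1..L breaks every native contact they carry (counted
#' once) and gains entropy `T |ds|` per peeled residue that had contacts
#' (residues without native contacts, counted by kappa, gain nothing).  A
#' candidate (i, j) is geometrically feasible when the native distance
#' between the anchor residues i+1 and j is below the effective loop length
#' `(n_peeled - M) * r0_peel`; termini already within one bond length can be
#' joined without peeling.  This step is independent of the cut position, so
#' it is shared by all circular permutants of a structure.
#'
#' @param structure the native [calpha_structure()].
#' @param contact_map its `contact_map`.
#' @param ds per-residue entropy from [entropy_per_residue()].
#' @param temperature K.
#' @param M turn offset (default [termini_offset()]).
#' @param r0_peel effective length per peeled residue, nm (3.5 Angstrom).
#' @param peel_max window size at each terminus.
#' @return One-row tibble: `dG_J`, `join_i`, `join_j`, `n_peeled`, `kappa`.
#' @export
join_free_energy <- function(structure, contact_map, ds, temperature,
                             M = NULL, r0_peel = 0.35, peel_max = 9) {
  L <- length(structure)
  M <- M %||% termini_offset(structure)
  best <- NULL
  for (i in 0:peel_max) {
    for (j in (L - peel_max):L) {
      if (i + 1 > j) next
      peeled <- c(seq_len(i), if (j < L) (j + 1):L)
      npeel <- length(peeled)
      d <- row_dist(structure$coords, i + 1, j)
      if (d >= max(npeel - M, 1) * r0_peel) next
      pc <- peel_cost(peeled, contact_map, ds, temperature)
      if (is.null(best) || pc$dG < best$dG_J - 1e-12 ||
          (abs(pc$dG - best$dG_J) <= 1e-12 && pc$n < best$n_peeled)) {
        best <- tibble(dG_J = pc$dG, join_i = i, join_j = j,
                       n_peeled = pc$n, kappa = pc$kappa)
      }
    }
  }
  if (is.null(best)) {
    abort("termini cannot be joined within the peel budget")
  }
  best
}

#' Loop-cut free energy dG_C
#'
#' Cutting between K and K+1 unfolds a small window of residues either side
#' of the cut; the window search (up to three residues left, three right)
#' finds the cheapest combination of broken contacts (counted once) against
#' entropy gained by the unfolded residues, with the same no-contact rule as
#' the join step: residues that carry no native contacts gain no entropy, so
#' a cut in a contact-free loop costs nothing.
#'
#' @param contact_map `contact_map` of the native domain.
#' @param K cut position.
#' @inheritParams join_free_energy
#' @return One-row tibble: `dG_C`, `cut_i`, `cut_j`, `n_unfolded`.
#' @export
cut_free_energy <- function(contact_map, K, ds, temperature) {
  L <- attr(contact_map, "n_residues")
  if (K <= 4 || K >= L - 4) {
    abort(sprintf("K = %d is within 4 residues of a chain end", K))
  }
  best <- NULL
  for (ip in (K - 3):K) {
    for (jp in (K + 1):(K + 4)) {
      unfolded <- c(if (ip < K) (ip + 1):K, if (jp > K + 1) (K + 1):(jp - 1))
      pc <- peel_cost(unfolded, contact_map, ds, temperature)
      if (is.null(best) || pc$dG < best$dG_C - 1e-12 ||
          (abs(pc$dG - best$dG_C) <= 1e-12 && pc$n < best$n_unfolded)) {
        best <- tibble(dG_C = pc$dG, cut_i = ip, cut_j = jp,
                       n_unfolded = pc$n)
      }
    }
  }
  best
}

#' Alchemical destabilization of circular permutants
#'
#' `ddG_tot = dG_J + dG_C`: the predicted stability loss of the circular
#' permutant cut at K relative to the wild type, assuming equal unfolded
#' free energies.  Larger ddG_tot means a less stable permutant and hence a
#' lower propensity for the corresponding domain-swapped misfold.
#'
#' @param structure native [calpha_structure()].
#' @param contact_map its `contact_map`.
#' @param K integer vector of cut positions to score.
#' @param temperature folding temperature, K.
#' @param ds per-residue entropy (default: [entropy_per_residue()] at
#'   `temperature`).
#' @param M turn offset (default: [termini_offset()]).
#' @inheritParams join_free_energy
#' @return A tibble of class `alchemical_result`: one row per K with
#'   `dG_J`, `dG_C`, `ddG_tot`, the argmin windows, `kappa`, plus
#'   attributes `ds`, `M`, `temperature`.
#' @export
ddg_total <- function(structure, contact_map, K, temperature, ds = NULL,
                      M = NULL, r0_peel = 0.35, peel_max = 9) {
  ds <- ds %||% entropy_per_residue(contact_map, temperature)
  M <- M %||% termini_offset(structure)
  join <- join_free_energy(structure, contact_map, ds, temperature, M,
                           r0_peel, peel_max)
  rows <- purrr::map_dfr(K, function(k) {
    cut <- cut_free_energy(contact_map, k, ds, temperature)
    bind_cols(tibble(K = k), join, cut)
  })
  out <- rows %>% mutate(ddG_tot = .data$dG_J + .data$dG_C)
  structure(out, class = c("alchemical_result", class(tibble())),
            ds = ds, M = M, temperature = temperature)
}

#' @export
glance.alchemical_result <- function(x, ...) {
  tibble(
    n_permutants = nrow(x),
    dG_J = x$dG_J[1],
    ddG_range = diff(range(x$ddG_tot)),
    M = attr(x, "M"),
    ds = attr(x, "ds"),
    temperature = attr(x, "temperature")
  )
}
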