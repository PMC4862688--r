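# Structure-based (Go-type) energy model for a single domain.

# Per-residue contact energies of Miyazawa & Jernigan (Macromolecules 18:534),
# in RT units.  The pair table below is the dominant rank-one (hydrophobicity)
# component of their 20x20 statistical contact potential: e_ij is proportional
# to -(m_i * m_j).  Relative well depths only; build_contact_map() rescales.
MJ_SCALE <- c(
  A = 5.33, R = 4.18, N = 3.71, D = 3.59, C = 7.93,
  Q = 3.87, E = 3.65, G = 4.48, H = 5.10, I = 8.83,
  L = 8.47, K = 2.95, M = 8.95, F = 9.03, P = 3.87,
  S = 4.09, T = 4.49, W = 7.66, Y = 5.89, V = 7.63
)

#' Pairwise Miyazawa-Jernigan-style contact energy table
#'
#' Rank-one reconstruction of the Miyazawa-Jernigan statistical contact
#' potential from their published per-residue contact-energy scale:
#' `e[a, b] = -m_a * m_b / mean(m)^2`, so a typical pair has energy about -1
#' (arbitrary units; the contact map builder rescales to kcal/mol).
#'
#' @return A 20 x 20 named numeric matrix (one-letter codes), all entries
#'   negative (favourable).
#' @export
mj_pair_energies <- function() {
  -outer(MJ_SCALE, MJ_SCALE) / mean(MJ_SCALE)^2
}

#' Native contact map of a C-alpha structure
#'
#' A residue pair (i, j) is a native contact when its C-alpha distance is
#' below `cutoff` and the pair is separated by at least `min_seq_sep`
#' residues in sequence.  Well depths follow the Miyazawa-Jernigan-style pair
#' table for the two residue types and are rescaled so the mean |epsilon|
#' equals `energy_unit` kcal/mol (or so the summed |epsilon| equals
#' `total_energy` when given).
#'
#' @param structure a [calpha_structure()].
#' @param cutoff contact distance cutoff in nm.
#' @param min_seq_sep minimum sequence separation `j - i` (>= 3; contacts
#'   always satisfy `j > i + 2`).
#' @param energy_unit mean |epsilon| per contact, kcal/mol.
#' @param total_energy optional total |epsilon| over the map, kcal/mol
#'   (overrides `energy_unit`).
#' @return A tibble of class `contact_map` with columns `i`, `j`, `r0` (nm)
#'   and `eps` (kcal/mol, negative), plus attributes `n_residues` and
#'   `cutoff`.
#' @export
build_contact_map <- function(structure, cutoff = 0.8, min_seq_sep = 3,
                              energy_unit = 1.0, total_energy = NULL) {
  stopifnot(cutoff > 0, min_seq_sep >= 3)
  n <- length(structure)
  if (n < min_seq_sep + 1) {
    warn("structure shorter than min_seq_sep + 1; empty contact map")
    return(new_contact_map(tibble(i = integer(), j = integer(),
                                  r0 = double(), eps = double()),
                           n, cutoff))
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- pairs[, 2] - pairs[, 1] >= min_seq_sep
  pairs <- pairs[keep, , drop = FALSE]
  d <- pair_distances(structure$coords, pairs[, 1], pairs[, 2])
  hit <- d < cutoff
  pairs <- pairs[hit, , drop = FALSE]
  d <- d[hit]
  aa <- seq_chars(structure$sequence)
  etab <- mj_pair_energies()
  aa[!aa %in% rownames(etab)] <- "A"
  eps_raw <- etab[cbind(aa[pairs[, 1]], aa[pairs[, 2]])]
  scale <- if (nrow(pairs) == 0) {
    1
  } else if (!is.null(total_energy)) {
    total_energy / sum(abs(eps_raw))
  } else {
    energy_unit / mean(abs(eps_raw))
  }
  map <- tibble(
    i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]),
    r0 = d, eps = eps_raw * scale
  ) %>% arrange(.data$i, .data$j)
  new_contact_map(map, n, cutoff)
}

new_contact_map <- function(tbl, n_residues, cutoff = NA_real_) {
  structure(tbl, class = c("contact_map", class(tibble())),
            n_residues = as.integer(n_residues), cutoff = cutoff)
}

#' @export
tidy.contact_map <- function(x, ...) as_tibble(x)

# default bonded force-field constants (kcal/mol based)
FF_DEFAULTS <- list(
  bond_k = 500,      # kcal/mol/nm^2; soft CG bonds keep junction strain mild
  angle_k = 12,      # kcal/mol/rad^2
  generic_angle_k = 1,  # soft prior on linker/junction angles: turns stay cheap
  generic_theta0 = 1.6,  # turn-capable prior: linkers bend as readily as loops
  dih_k1 = 0.15,     # kcal/mol
  dih_k3 = 0.075,
  rep_eps = 0.1,     # kcal/mol at r = sigma
  sigma = 0.40,      # nm; Gly/Ser get 0.35
  sigma_small = 0.35,
  mass = 110         # amu per bead
)

residue_sigmas <- function(sequence) {
  aa <- seq_chars(sequence)
  ifelse(aa %in% c("G", "S"), FF_DEFAULTS$sigma_small, FF_DEFAULTS$sigma)
}

# Bonded terms read off the native geometry of a contiguous chain segment.
# `native` flags residues whose local geometry should be biased to the input
# coordinates; runs of non-native (linker) residues get generic soft angles
# and no dihedral bias.
native_bonded_terms <- function(coords, native = rep(TRUE, nrow(coords)),
                                offset = 0L, segment = rep(1L, nrow(coords))) {
  n <- nrow(coords)
  idx <- seq_len(n)
  bonds <- tibble(
    i = idx[-n] + offset, j = idx[-1] + offset,
    r0 = pair_distances(coords, idx[-n], idx[-1]),
    k = FF_DEFAULTS$bond_k
  )
  # a triple/quadruple is biased to the input geometry only when all its
  # beads are native AND belong to the same chain segment (terms spanning an
  # inter-repeat junction are soft: the hinge between domains is floppy)
  nb <- native
  same_seg <- function(a, b) segment[a] == segment[b]
  angles <- NULL
  if (n >= 3) {
    ai <- idx[1:(n - 2)]
    nat3 <- nb[ai] & nb[ai + 1] & nb[ai + 2] & same_seg(ai, ai + 2)
    th <- vapply(ai, function(i) bead_angle(coords, i, i + 1, i + 2), 0)
    angles <- tibble(
      i = ai + offset, j = ai + 1 + offset, k = ai + 2 + offset,
      theta0 = ifelse(nat3, th, FF_DEFAULTS$generic_theta0),
      angle_k = ifelse(nat3, FF_DEFAULTS$angle_k, FF_DEFAULTS$generic_angle_k)
    )
  }
  dihedrals <- NULL
  if (n >= 4) {
    di <- idx[1:(n - 3)]
    nat4 <- nb[di] & nb[di + 1] & nb[di + 2] & nb[di + 3] &
      same_seg(di, di + 3)
    di <- di[nat4]
    if (length(di)) {
      ph <- vapply(di, function(i) bead_dihedral(coords, i, i + 1, i + 2, i + 3), 0)
      dihedrals <- tibble(
        i = di + offset, j = di + 1 + offset, k = di + 2 + offset,
        l = di + 3 + offset,
        phi0 = ph, k1 = FF_DEFAULTS$dih_k1, k3 = FF_DEFAULTS$dih_k3
      )
    }
  }
  list(
    bonds = bonds,
    angles = angles %||% tibble(i = integer(), j = integer(), k = integer(),
                                theta0 = double(), angle_k = double()),
    dihedrals = dihedrals %||% tibble(i = integer(), j = integer(),
                                      k = integer(), l = integer(),
                                      phi0 = double(), k1 = double(),
                                      k3 = double())
  )
}

bead_angle <- function(coords, i, j, k) {
  u <- coords[i, ] - coords[j, ]
  v <- coords[k, ] - coords[j, ]
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

bead_dihedral <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

#' Build a single-domain Go model
#'
#' Assembles the one-bead structure-based energy model: harmonic bonds and
#' angles at native values, a two-term cosine dihedral biased to the native
#' backbone torsions, 12-10 wells on native contacts with
#' Miyazawa-Jernigan-style relative depths, and a purely repulsive r^-12
#' excluded volume on all other pairs.
#'
#' @inheritParams build_contact_map
#' @param contact_map optionally, a precomputed [build_contact_map()] result.
#' @return An object of class `go_model`.
#' @export
build_go_model <- function(structure, cutoff = 0.8, min_seq_sep = 3,
                           energy_unit = 1.0, total_energy = NULL,
                           contact_map = NULL) {
  cm <- contact_map %||% build_contact_map(structure, cutoff, min_seq_sep,
                                           energy_unit, total_energy)
  bonded <- native_bonded_terms(structure$coords)
  structure(
    list(
      structure = structure,
      contacts = cm,
      bonded = bonded,
      sigma = residue_sigmas(structure$sequence),
      rep_eps = FF_DEFAULTS$rep_eps,
      mass = FF_DEFAULTS$mass,
      total_contact_energy = sum(cm$eps)
    ),
    class = "go_model"
  )
}

#' @export
print.go_model <- function(x, ...) {
  cat(sprintf("<go_model> %d residues, %d native contacts, sum(eps) = %.2f kcal/mol\n",
              length(x$structure), nrow(x$contacts), x$total_contact_energy))
  invisible(x)
}

#' @export
glance.go_model <- function(x, ...) {
  tibble(
    n_residues = length(x$structure),
    n_contacts = nrow(x$contacts),
    total_contact_energy = x$total_contact_energy,
    mean_abs_eps = mean(abs(x$contacts$eps))
  )
}

# ---- compiled-core assembly -------------------------------------------------

# Pack any model (go_model / tandem_model / permutant model) into the list
# consumed by the C++ kernel.  Native pairs get 12-10 wells; pairs joined by a
# bond or an angle are excluded from the nonbonded loop; everything else is
# repulsive.
model_core <- function(model) {
  n <- model_size(model)
  bonded <- model$bonded
  contacts <- model_contact_table(model)
  pair_code <- matrix(0L, n, n)
  pair_eps <- matrix(0, n, n)
  pair_r0 <- matrix(0, n, n)
  mark <- function(i, j, code) {
    pair_code[cbind(pmin(i, j), pmax(i, j))] <<- code
    pair_code[cbind(pmax(i, j), pmin(i, j))] <<- code
  }
  if (nrow(bonded$bonds)) mark(bonded$bonds$i, bonded$bonds$j, -1L)
  if (nrow(bonded$angles)) mark(bonded$angles$i, bonded$angles$k, -1L)
  if (nrow(contacts)) {
    ii <- pmin(contacts$i, contacts$j)
    jj <- pmax(contacts$i, contacts$j)
    pair_code[cbind(ii, jj)] <- 1L
    pair_code[cbind(jj, ii)] <- 1L
    pair_eps[cbind(ii, jj)] <- abs(contacts$eps)
    pair_eps[cbind(jj, ii)] <- abs(contacts$eps)
    pair_r0[cbind(ii, jj)] <- contacts$r0
    pair_r0[cbind(jj, ii)] <- contacts$r0
  }
  list(
    n = n,
    bonds = as.matrix(bonded$bonds[, c("i", "j")]),
    bond_r0 = bonded$bonds$r0, bond_k = bonded$bonds$k,
    angles = as.matrix(bonded$angles[, c("i", "j", "k")]),
    theta0 = bonded$angles$theta0, angle_k = bonded$angles$angle_k,
    dihedrals = as.matrix(bonded$dihedrals[, c("i", "j", "k", "l")]),
    phi0 = bonded$dihedrals$phi0, dih_k1 = bonded$dihedrals$k1,
    dih_k3 = bonded$dihedrals$k3,
    pair_code = pair_code, pair_eps = pair_eps, pair_r0 = pair_r0,
    sigma = model$sigma, rep_eps = model$rep_eps
  )
}

model_size <- function(model) UseMethod("model_size")
#' @export
model_size.go_model <- function(model) length(model$structure)
#' @export
model_size.tandem_model <- function(model) length(model$structure)

model_contact_table <- function(model) UseMethod("model_contact_table")
#' @export
model_contact_table.go_model <- function(model) model$contacts
#' @export
model_contact_table.tandem_model <- function(model) model$duplicated_contacts

#' Potential energy of a configuration
#'
#' Evaluates the full coarse-grained potential (bonds, angles, dihedrals,
#' native 12-10 wells, excluded volume) for a configuration of a
#' [build_go_model()] or [build_tandem_model()] model.
#'
#' @param model a `go_model` or `tandem_model`.
#' @param coords numeric matrix (n x 3), nm.
#' @return A list with `total` (kcal/mol) and `terms`, a tibble with one row
#'   per energy term.
#' @export
potential_energy <- function(model, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != model_size(model)) {
    abort("coordinate count does not match the model")
  }
  if (any(!is.finite(coords))) abort("non-finite coordinates")
  e <- cg_energy_cpp(coords, model_core(model))
  list(
    total = e$total,
    terms = tibble(
      term = c("bond", "angle", "dihedral", "native", "repulsive"),
      energy = c(e$bond, e$angle, e$dihedral, e$native, e$repulsive)
    )
  )
}

#' Serialize a Go model to JSON
#'
#' Writes the model's substrate -- sequence, coordinates (nm), contact map
#' and energy bookkeeping -- as a JSON document.  Bonded terms are not
#' stored: they are a deterministic function of the native geometry and are
#' rebuilt on read.
#'
#' @param model a `go_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    format = "swapfold-go-model",
    sequence = model$structure$sequence,
    coords = unname(model$structure$coords),
    contacts = as.data.frame(as_tibble(model$contacts)),
    total_contact_energy = model$total_contact_energy
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "swapfold-go-model")) {
    abort("not a swapfold model document")
  }
  st <- calpha_structure(doc$coords, doc$sequence)
  cm <- new_contact_map(as_tibble(doc$contacts), length(st))
  build_go_model(st, contact_map = cm)
}
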