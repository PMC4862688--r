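# Tandem-dimer model with swap-compatible duplicated contacts, and
# circular-permutant single-domain models.

# Gly-Ser repeat filler: whole repeats plus a tail taken from the end of the
# pattern, so ll = 5 gives (GS)2-S = "GSGSS".
gs_fill <- function(ll, pattern = "GS") {
  if (ll == 0) return("")
  len <- nchar(pattern)
  rem <- ll %% len
  paste0(strrep(pattern, ll %/% len),
         if (rem > 0) substr(pattern, len - rem + 1, len) else "")
}

#' Build the tandem two-domain model
#'
#' The chain holds two identical repeats of the domain, each followed by the
#' interdomain linker, for a total length of `2L` with
#' `L = domain length + linker length`.  Every native contact (i, j) of the
#' single domain appears four times -- (i, j), (i+L, j+L) and the two
#' interdomain swap copies (i, j+L) and (j, i+L) -- with equal well depth and
#' native distance, which is what makes domain-swapped misfolds energetically
#' native-like.  Linker beads are structureless: bonded and excluded-volume
#' terms only, no native contacts, no dihedral bias.
#'
#' @param domain a [build_go_model()] single-domain model.
#' @param linker_sequence one-letter linker string (may be empty).
#' @return An object of class `tandem_model`.
#' @export
build_tandem_model <- function(domain, linker_sequence = "") {
  nd <- length(domain$structure)
  ll <- nchar(linker_sequence)
  L <- nd + ll
  dcoords <- domain$structure$coords

  # native tandem reference coordinates: domain 2 is a translated copy,
  # linkers extended along the exit direction of each domain
  centroid <- colMeans(dcoords)
  u <- unit_vec(dcoords[nd, ] - centroid)
  place_linker <- function(from) {
    if (ll == 0) return(NULL)
    from[rep(1, ll), , drop = FALSE] + (seq_len(ll) * 0.38) %o% u
  }
  link1 <- place_linker(dcoords[nd, , drop = FALSE])
  anchor <- if (ll > 0) link1[ll, ] else dcoords[nd, ]
  shift <- anchor + 0.38 * u - dcoords[1, ]
  d2 <- sweep(dcoords, 2, shift, "+")
  # push domain 2 out along u until the domains are clash-free
  while (min_cross_distance(dcoords, d2) < 0.45) {
    d2 <- sweep(d2, 2, 0.2 * u, "+")
  }
  link2 <- place_linker(d2[nd, , drop = FALSE])
  coords <- rbind(dcoords, link1, d2, link2)

  dom_seq <- seq_chars(domain$structure$sequence)
  seq1 <- paste(c(dom_seq, seq_chars(linker_sequence),
                  dom_seq, seq_chars(linker_sequence)), collapse = "")
  tandem_structure <- calpha_structure(coords, seq1)

  native <- as_tibble(domain$contacts)
  copy_of <- function(ii, jj, tag) {
    tibble(i = as.integer(ii), j = as.integer(jj),
           r0 = native$r0, eps = native$eps, copy = tag)
  }
  dup <- bind_rows(
    copy_of(native$i, native$j, "d11"),
    copy_of(native$i + L, native$j + L, "d22"),
    copy_of(native$i, native$j + L, "swap_i1j2"),
    copy_of(native$j, native$i + L, "swap_j1i2")
  ) %>% arrange(.data$i, .data$j)
  dup <- new_contact_map(dup, 2L * L, attr(domain$contacts, "cutoff"))

  native_flags <- rep(c(rep(TRUE, nd), rep(FALSE, ll)), 2)
  bonded <- tandem_bonded_terms(domain, coords, L, nd, ll)
  structure(
    list(
      domain_model = domain,
      linker_sequence = linker_sequence,
      L = L,
      midpoint = L,
      structure = tandem_structure,
      duplicated_contacts = dup,
      bonded = bonded,
      sigma = residue_sigmas(seq1),
      rep_eps = domain$rep_eps,
      mass = domain$mass,
      is_linker = !native_flags
    ),
    class = "tandem_model"
  )
}

min_cross_distance <- function(a, b) {
  min(vapply(seq_len(nrow(a)), function(i) {
    min(sqrt(rowSums(sweep(b, 2, a[i, ])^2)))
  }, 0))
}

# bonded terms for the full tandem chain: native geometry inside each domain
# repeat, generic soft terms wherever a linker bead is involved
tandem_bonded_terms <- function(domain, coords, L, nd, ll) {
  native <- rep(c(rep(TRUE, nd), rep(FALSE, ll)), 2)
  segment <- rep(1:2, each = L)
  # domain-internal terms take the native geometry; anything involving a
  # linker bead or spanning the inter-repeat junction stays generic/soft
  native_bonded_terms(coords, native = native, segment = segment)
}

#' @export
print.tandem_model <- function(x, ...) {
  cat(sprintf(
    "<tandem_model> 2 x %d residues (L = %d, linker '%s'), %d duplicated contacts\n",
    x$L, x$L, x$linker_sequence, nrow(x$duplicated_contacts)))
  invisible(x)
}

#' @export
glance.tandem_model <- function(x, ...) {
  tibble(
    L = x$L, n_beads = 2L * x$L,
    linker = x$linker_sequence,
    n_native = nrow(x$domain_model$contacts),
    n_duplicated = nrow(x$duplicated_contacts),
    sum_eps_duplicated = sum(x$duplicated_contacts$eps)
  )
}

#' Extend the interdomain linker with a Gly-Ser repeat
#'
#' Appends a structureless Gly-Ser linker extension of length `ll` (pattern
#' repeated and truncated, e.g. `ll = 5` gives "GSGSS") to the existing
#' linker and rebuilds the tandem model, so the repeat length `L` grows by
#' `ll` and the four-copy contact duplication is re-established.  The added
#' residues form no native contacts.
#'
#' @param model a `tandem_model`.
#' @param ll number of residues to add (>= 0).
#' @param pattern composition pattern cycled to build the extension.
#' @return A new `tandem_model`.
#' @export
apply_linker_extension <- function(model, ll, pattern = "GS") {
  stopifnot(ll >= 0)
  if (ll == 0) return(model)
  build_tandem_model(model$domain_model,
                     paste0(model$linker_sequence, gs_fill(ll, pattern)))
}

#' Circular-permutant single-domain model
#'
#' Builds the Go model of the circular permutant cut after position `K`: the
#' chain is reordered to K+1, ..., L, 1, ..., K, the old termini are joined by
#' a fresh bond at the standard CA-CA spacing (0.38 nm), and the chain is cut
#' between K and K+1.  Native contacts, with their original well depths and
#' distances, are carried over under the new numbering.  When the parent's
#' termini are far apart the joined bond is strained in the permutant's
#' native-like geometry, which is the physical origin of circular-permutant
#' destabilization.
#'
#' @param domain a [build_go_model()] model of the parent domain.
#' @param K cut position, `1 <= K < L`.
#' @return A `go_model` for the permutant (attribute `K` records the cut).
#' @export
build_permutant_model <- function(domain, K) {
  L <- length(domain$structure)
  if (K < 1 || K >= L) abort("K must be in [1, L-1]")
  ord <- c((K + 1):L, 1:K)
  inv <- match(seq_len(L), ord)
  coords <- domain$structure$coords[ord, , drop = FALSE]
  seq1 <- paste(seq_chars(domain$structure$sequence)[ord], collapse = "")
  st <- calpha_structure(coords, seq1)

  # bonded terms: native where the new chain follows the old one, joined bond
  # at the old-termini junction
  old_adjacent <- abs(diff(ord)) == 1
  bonded <- native_bonded_terms(coords)
  bonded$bonds$r0[!old_adjacent] <- 0.38
  if (nrow(bonded$angles)) {
    nat3 <- old_adjacent[-length(old_adjacent)] & old_adjacent[-1] &
      (diff(ord, lag = 2) %in% c(-2L, 2L))
    bonded$angles$theta0[!nat3] <- FF_DEFAULTS$generic_theta0
    bonded$angles$angle_k[!nat3] <- FF_DEFAULTS$generic_angle_k
  }
  if (nrow(bonded$dihedrals)) {
    d <- bonded$dihedrals
    nat4 <- vapply(seq_len(nrow(d)), function(r) {
      o <- ord[c(d$i[r], d$j[r], d$k[r], d$l[r])]
      all(diff(o) == 1L) || all(diff(o) == -1L)
    }, TRUE)
    bonded$dihedrals <- d[nat4, , drop = FALSE]
  }

  cm <- as_tibble(domain$contacts) %>%
    mutate(
      ni = pmin(inv[.data$i], inv[.data$j]),
      nj = pmax(inv[.data$i], inv[.data$j]),
      i = .data$ni, j = .data$nj
    ) %>%
    select("i", "j", "r0", "eps") %>%
    arrange(.data$i, .data$j)
  cm <- new_contact_map(cm, L, attr(domain$contacts, "cutoff"))

  out <- structure(
    list(
      structure = st,
      contacts = cm,
      bonded = bonded,
      sigma = residue_sigmas(seq1),
      rep_eps = domain$rep_eps,
      mass = domain$mass,
      total_contact_energy = sum(cm$eps)
    ),
    class = "go_model"
  )
  attr(out, "K") <- K
  out
}
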