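#' Specification for a synthetic beta-meander test fold
#'
#' The toy generator produces a compact antiparallel beta-meander C-alpha
#' trace on a regular (optionally curled) lattice.  It gives every downstream
#' module a structure with a well-defined native contact map, contact-free
#' loops where circular-permutant cuts can be placed, a controllable N-to-C
#' termini separation, and deterministic coordinates for a fixed seed.
#'
#' @param n_strands number of beta strands (>= 2).
#' @param strand_length residues per strand (>= 2).
#' @param loop_length residues per connecting loop (>= 2).
#' @param termini_gap target N-to-C bead distance in nm.  The generator curls
#'   the sheet around an axis until the built distance matches within 10%;
#'   gaps outside the feasible range for the strand geometry are an error.
#' @param seed integer; fixes the small coordinate jitter.
#' @return A list of class `toy_spec`.
#' @export
toy_spec <- function(n_strands = 4, strand_length = 6, loop_length = 3,
                     termini_gap = 0.5, seed = 1) {
  stopifnot(n_strands >= 2, strand_length >= 2, loop_length >= 2,
            termini_gap > 0)
  structure(
    list(n_strands = n_strands, strand_length = strand_length,
         loop_length = loop_length, termini_gap = termini_gap, seed = seed),
    class = "toy_spec"
  )
}

# lattice constants (nm): CA-CA spacing along a strand, inter-strand spacing
TOY_DX <- 0.38
TOY_DY <- 0.42
TOY_SEG <- 0.36   # target loop segment length
TOY_JITTER <- 0.008

# strand/loop bead layout for a given curl angle between adjacent strands
toy_coords <- function(spec, curl) {
  ns <- spec$n_strands
  sl <- spec$strand_length
  ll <- spec$loop_length
  slot_pos <- function(s) {   # in-plane anchor of strand slot s (0-based)
    if (curl < 1e-8) {
      cbind(0, s * TOY_DY, 0)
    } else {
      R <- TOY_DY / curl
      cbind(0, R * sin(s * curl), R - R * cos(s * curl))
    }
  }
  slot_normal <- function(s) {  # outward (convex-side) unit normal
    if (curl < 1e-8) c(0, 0, -1) else c(0, sin(s * curl), -cos(s * curl))
  }
  xmax <- (sl - 1) * TOY_DX
  coords <- NULL
  for (s in seq_len(ns) - 1) {
    xs <- if (s %% 2 == 0) seq(0, xmax, by = TOY_DX) else seq(xmax, 0, by = -TOY_DX)
    strand <- cbind(xs, 0, 0) + slot_pos(s)[rep(1, sl), ]
    coords <- rbind(coords, strand)
    if (s < ns - 1) {
      a <- strand[sl, ]
      nxt <- if ((s + 1) %% 2 == 0) 0 else xmax
      b <- c(nxt, 0, 0) + slot_pos(s + 1)[1, ]
      w <- unit_vec(slot_normal(s) + slot_normal(s + 1))
      # beads at equal arc length along a bulged curve from a to b
      tfine <- seq(0, 1, length.out = 201)
      curve_pts <- function(h) {
        matrix(a, length(tfine), 3, byrow = TRUE) + tfine %o% (b - a) +
          (h * sin(pi * tfine)) %o% w
      }
      arc_len <- function(h) sum(sqrt(rowSums(diff(curve_pts(h))^2)))
      target <- (ll + 1) * TOY_SEG
      h <- if (arc_len(0) >= target) 0 else {
        uniroot(function(h) arc_len(h) - target, c(0, 5))$root
      }
      cp <- curve_pts(h)
      s_cum <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
      s_at <- seq_len(ll) / (ll + 1) * s_cum[length(s_cum)]
      pts <- apply(cp, 2, function(col) approx(s_cum, col, xout = s_at)$y)
      if (ll == 1) pts <- matrix(pts, 1, 3)
      coords <- rbind(coords, pts)
    }
  }
  unname(coords)
}

toy_gap <- function(spec, curl) {
  co <- toy_coords(spec, curl)
  sqrt(sum((co[1, ] - co[nrow(co), ])^2))
}

#' Build a synthetic beta-meander structure
#'
#' @param spec a [toy_spec()], or `NULL` to build one from the remaining
#'   arguments.
#' @inheritParams toy_spec
#' @return A [calpha_structure()] whose sequence uses hydrophobic-cycle
#'   residues on strands and Gly/Ser/Asn on loops.
#' @examples
#' toy <- make_toy_structure(toy_spec(n_strands = 4, termini_gap = 0.6))
#' termini_distance(toy)
#' @export
make_toy_structure <- function(spec = NULL, n_strands = 4, strand_length = 6,
                               loop_length = 3, termini_gap = 0.5, seed = 1) {
  if (is.null(spec)) {
    spec <- toy_spec(n_strands, strand_length, loop_length, termini_gap, seed)
  }
  # two-strand hairpins are flat; wider sheets can curl up to barrel closure
  curl_max <- if (spec$n_strands == 2) 1e-7 else 2 * pi / spec$n_strands
  g0 <- toy_gap(spec, 0)
  g1 <- toy_gap(spec, curl_max)
  curl <- if (spec$termini_gap >= g0) {
    if (spec$termini_gap > 1.1 * g0) {
      abort(sprintf(
        "termini_gap %.2f nm infeasible: flat sheet tops out at %.2f nm",
        spec$termini_gap, g0))
    }
    0
  } else if (spec$termini_gap <= g1) {
    if (spec$termini_gap < 0.9 * g1) {
      abort(sprintf(
        "termini_gap %.2f nm infeasible: closed barrel bottoms out at %.2f nm",
        spec$termini_gap, g1))
    }
    curl_max
  } else {
    uniroot(function(cu) toy_gap(spec, cu) - spec$termini_gap,
            c(1e-6, curl_max))$root
  }
  coords <- toy_coords(spec, curl)
  # the seed perturbs the frame rigidly: coordinates differ between seeds
  # while the internal geometry (and hence the contact topology) is identical
  coords <- with_seed(spec$seed, {
    ang <- runif(3, 0, 2 * pi)
    shift <- runif(3, -0.5, 0.5)
    Rz <- rbind(c(cos(ang[1]), -sin(ang[1]), 0),
                c(sin(ang[1]), cos(ang[1]), 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[2]), -sin(ang[2])),
                c(0, sin(ang[2]), cos(ang[2])))
    sweep(coords %*% (Rz %*% Rx), 2, shift, "+")
  })

  strand_aa <- c("V", "I", "T", "L", "E", "A")
  loop_aa <- c("G", "S", "N")
  seq1 <- character(0)
  for (s in seq_len(spec$n_strands)) {
    seq1 <- c(seq1, rep_len(strand_aa, spec$strand_length))
    if (s < spec$n_strands) seq1 <- c(seq1, rep_len(loop_aa, spec$loop_length))
  }
  out <- calpha_structure(coords, paste(seq1, collapse = ""))
  attr(out, "toy_spec") <- spec
  attr(out, "curl") <- curl
  out
}

#' Residue spans of the loops of a toy structure
#'
#' @param spec the `toy_spec` used to build the structure.
#' @return tibble with one row per loop: `loop`, `start`, `end`.
#' @export
toy_loop_spans <- function(spec) {
  sl <- spec$strand_length
  ll <- spec$loop_length
  starts <- sl + (seq_len(spec$n_strands - 1) - 1) * (sl + ll) + 1
  tibble(loop = seq_along(starts), start = starts, end = starts + ll - 1)
}
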