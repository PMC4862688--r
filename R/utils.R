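# Internal helpers shared across modules.

# Run code with a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Pairwise Euclidean distance between two rows of a coordinate matrix.
row_dist <- function(coords, i, j) {
  sqrt(sum((coords[i, ] - coords[j, ])^2))
}

# Distances for index pairs (vectorised).
pair_distances <- function(coords, i, j) {
  d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  sqrt(rowSums(d * d))
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate direction vector")
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-letter <-> three-letter amino-acid codes (alphabetical in one-letter).
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

aa_three <- function(one) {
  idx <- match(one, AA1)
  idx[is.na(idx)] <- match("A", AA1)
  AA3[idx]
}

seq_chars <- function(sequence) strsplit(sequence, "")[[1]]
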