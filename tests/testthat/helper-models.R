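# Shared fixtures, built once per test run.

# small standard toy: 4-strand meander, close termini
toy_small <- function() {
  make_toy_structure(toy_spec(n_strands = 4, strand_length = 5,
                              loop_length = 5, termini_gap = 0.5, seed = 1))
}

toy_small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_go_model(toy_small())
    cache
  }
})

toy_small_tandem <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_tandem_model(toy_small_model(), "")
    cache
  }
})

# a hand-specified contact map wrapped with the right attributes
hand_map <- function(i, j, eps, r0 = 0.6, n_residues = max(j)) {
  swapfold:::new_contact_map(
    tibble::tibble(i = as.integer(i), j = as.integer(j),
                   r0 = rep_len(r0, length(i)), eps = rep_len(eps, length(i))),
    n_residues
  )
}

# PDB text for an n-residue C-alpha chain with given coordinates (Angstrom)
pdb_text <- function(coords_ang, resid = "ALA", chain = "A",
                     altloc = rep("", nrow(coords_ang))) {
  n <- nrow(coords_ang)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d  CA %1s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, altloc[i], rep_len(resid, n)[i], chain, i,
            coords_ang[i, 1], coords_ang[i, 2], coords_ang[i, 3])
  }, character(1))
  paste(c(lines, "END"), collapse = "\n")
}

total_variation <- function(p_tbl, q_tbl) {
  m <- dplyr::full_join(p_tbl, q_tbl, by = c("start", "length"),
                        suffix = c("_p", "_q"))
  m[is.na(m)] <- 0
  sum(abs(m$prob_p - m$prob_q)) / 2
}

# internal shorthands used across tests
with_seed <- swapfold:::with_seed
unit_vec <- swapfold:::unit_vec
`%||%` <- function(a, b) if (is.null(a)) b else a
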