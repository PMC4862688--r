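#' One-bead-per-residue protein structures
#'
#' A `calpha_structure` reduces a protein chain to its C-alpha trace: one bead
#' per residue, coordinates in nanometres, a one-letter sequence, contiguous
#' 1-based residue ids, and unit vectors giving the backbone direction at the
#' two termini (used by the alchemical predictor to decide whether a turn
#' offset is needed when joining the termini).
#'
#' @param coords numeric matrix (n x 3) of bead positions in nm.
#' @param sequence one-letter amino-acid string of length n.
#' @param warnings character vector of non-fatal issues recorded while the
#'   structure was built (e.g. chain breaks).
#' @return An object of class `calpha_structure`.
#' @export
calpha_structure <- function(coords, sequence, warnings = character()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) == 3)
  n <- nrow(coords)
  if (nchar(sequence) != n) {
    abort("`sequence` length must equal the number of beads")
  }
  structure(
    list(
      sequence = sequence,
      coords = coords,
      residue_ids = seq_len(n),
      termini_vectors = termini_vectors(coords),
      warnings = warnings
    ),
    class = "calpha_structure"
  )
}

# Chain direction at the N and C termini, from the first/last three beads.
termini_vectors <- function(coords) {
  n <- nrow(coords)
  if (n < 3) return(matrix(NA_real_, 2, 3))
  rbind(
    n_term = unit_vec(coords[3, ] - coords[1, ]),
    c_term = unit_vec(coords[n, ] - coords[n - 2, ])
  )
}

#' @export
print.calpha_structure <- function(x, ...) {
  cat(sprintf(
    "<calpha_structure> %d residues, N-to-C distance %.3f nm\n",
    length(x), termini_distance(x)
  ))
  if (length(x$warnings)) cat(" warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
length.calpha_structure <- function(x) nrow(x$coords)

#' Distance between the N- and C-terminal beads (nm)
#' @param x a `calpha_structure`.
#' @export
termini_distance <- function(x) row_dist(x$coords, 1, nrow(x$coords))

#' @describeIn calpha_structure coordinates and sequence as a tibble
#'   (one row per residue).
#' @param x a `calpha_structure`.
#' @param ... unused.
#' @export
tidy.calpha_structure <- function(x, ...) {
  co <- x$coords
  tibble(
    residue = x$residue_ids,
    aa = seq_chars(x$sequence),
    x = co[, 1], y = co[, 2], z = co[, 3]
  )
}

#' Read a C-alpha structure from a PDB file or PDB text
#'
#' Keeps one bead per residue (first alternate location wins), drops
#' heteroatoms and waters, converts coordinates from Angstrom to nm, and
#' renumbers residues contiguously from 1.  Consecutive beads further apart
#' than 0.45 nm are recorded as chain-break warnings in the returned object
#' rather than raising an error.
#'
#' @param pdb path to a PDB file, or a character string of PDB-format text.
#' @param chain chain identifier to extract.  Mandatory when the file holds
#'   more than one chain.
#' @return A [calpha_structure()].
#' @export
read_structure <- function(pdb, chain = NULL) {
  path <- pdb
  if (length(pdb) > 1 || grepl("\n", pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(paste(pdb, collapse = "\n"), path)
    on.exit(unlink(path))
  }
  p <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- p$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  chains <- unique(atoms$chain)
  if (is.null(chain)) {
    if (length(chains) > 1) {
      abort(sprintf(
        "PDB holds chains %s; pass `chain` explicitly",
        paste(chains, collapse = ", ")
      ))
    }
    chain <- chains[1]
  }
  if (!chain %in% chains) {
    abort(sprintf("chain '%s' not found (available: %s)",
                  chain, paste(chains, collapse = ", ")))
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  atoms <- atoms[!duplicated(atoms$resno), , drop = FALSE]  # first altloc wins
  if (nrow(atoms) == 0) abort("no C-alpha records in selected chain")
  coords <- as.matrix(atoms[, c("x", "y", "z")]) / 10  # Angstrom -> nm
  seq1 <- paste(vapply(atoms$resid, function(r) {
    i <- match(toupper(r), AA3)
    if (is.na(i)) "X" else AA1[i]
  }, character(1)), collapse = "")
  warnings <- character()
  if (nrow(coords) > 1) {
    d <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                         coords[-nrow(coords), , drop = FALSE])^2))
    breaks <- which(d > 0.45)
    if (length(breaks)) {
      warnings <- sprintf("chain break after residue %d (%.2f nm)",
                          breaks, d[breaks])
    }
  }
  calpha_structure(coords, seq1, warnings = warnings)
}

#' Write a C-alpha structure as a PDB file
#'
#' Coordinates are converted back from nm to Angstrom; one CA atom per
#' residue.
#'
#' @param x a `calpha_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  n <- length(x)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(x$coords * 10)),
    resno = x$residue_ids,
    resid = aa_three(seq_chars(x$sequence)),
    elety = rep("CA", n),
    chain = rep("A", n)
  )
  invisible(path)
}

#' Plain-text XYZ trajectory I/O
#'
#' A minimal trajectory dialect used for all saved dynamics output: a header
#' line `frames <nframe> beads <n>` followed, for each frame, by one line per
#' bead holding three nm coordinates.
#'
#' @param frames numeric array (n x 3 x nframe) of coordinates in nm.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz_frames <- function(frames, path) {
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  n <- dim(frames)[1]
  nf <- dim(frames)[3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("frames %d beads %d", nf, n), con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("%.6f %.6f %.6f",
                       frames[, 1, f], frames[, 2, f], frames[, 3, f]), con)
  }
  invisible(path)
}

#' @rdname write_xyz_frames
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  nf <- as.integer(hdr[2])
  n <- as.integer(hdr[4])
  vals <- do.call(rbind, lapply(strsplit(lines[-1], " "), as.numeric))
  array(aperm(array(t(vals), c(3, n, nf)), c(2, 1, 3)), c(n, 3, nf))
}
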