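#' Read a protein structure from a PDB file
#'
#' Parses a PDB file into a `protein_structure`: an ordered list of residues,
#' each holding its heavy atoms. Hydrogens, waters, and heteroatoms are
#' removed; alternate locations are resolved to the highest-occupancy
#' conformer; residues are re-indexed 0-based internally while the author
#' numbering from the file is preserved for reporting.
#'
#' @param path Path to a PDB file.
#' @param model_index Which MODEL to read (1-based). Default 1.
#' @param chain_filter Optional character vector of chain identifiers to keep.
#' @return An object of class `protein_structure` with elements:
#'   \describe{
#'     \item{atoms}{data.frame with columns `serial`, `name`, `element`,
#'       `residue_pos` (0-based), `author_resnum`, `chain`, `x`, `y`, `z`.}
#'     \item{residues}{data.frame with one row per residue: `residue_pos`,
#'       `author_resnum`, `chain`, `aa` (one-letter code).}
#'     \item{length}{chain length L (number of residues).}
#'     \item{source_id}{free-text identifier (the file path).}
#'   }
#' @export
read_structure <- function(path, model_index = 1L, chain_filter = NULL) {
  if (!file.exists(path)) {
    stop("structure file not found: ", path)
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e))
  )
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1L || model_index > n_models) {
    stop("requested model ", model_index, " but file has ", n_models,
         " model(s)")
  }
  at <- pdb$atom
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model_index, ] else as.numeric(pdb$xyz)
  at$x <- xyz[seq(1L, length(xyz), by = 3L)]
  at$y <- xyz[seq(2L, length(xyz), by = 3L)]
  at$z <- xyz[seq(3L, length(xyz), by = 3L)]

  keep <- at$type == "ATOM"
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1L, 1L), at$elesy)))
  keep <- keep & elem != "H" & elem != "D"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (!is.null(chain_filter)) {
    sel <- at$chain %in% chain_filter
    at <- at[sel, , drop = FALSE]
    elem <- elem[sel]
  }
  if (nrow(at) == 0L) {
    stop("no heavy ATOM records left after filtering")
  }

  # resolve altlocs: keep highest occupancy per (chain, resnum, insert, name)
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  if (any(alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
                 trimws(at$elety), sep = "\r")
    ord <- order(key, -occ, alt)
    at <- at[ord, , drop = FALSE]
    elem <- elem[ord]
    dup <- duplicated(paste(at$chain, at$resno,
                            ifelse(is.na(at$insert), "", at$insert),
                            trimws(at$elety), sep = "\r"))
    at <- at[!dup, , drop = FALSE]
    elem <- elem[!dup]
    ord2 <- order(at$eleno)
    at <- at[ord2, , drop = FALSE]
    elem <- elem[ord2]
  }

  res_key <- paste(at$chain, at$resno,
                   ifelse(is.na(at$insert), "", at$insert), sep = "\r")
  res_levels <- unique(res_key)                 # file order
  residue_pos <- match(res_key, res_levels) - 1L

  first <- !duplicated(res_key)
  residues <- data.frame(
    residue_pos   = residue_pos[first],
    author_resnum = at$resno[first],
    chain         = at$chain[first],
    aa            = bio3d::aa321(at$resid[first]),
    stringsAsFactors = FALSE
  )
  atoms <- data.frame(
    serial        = at$eleno,
    name          = trimws(at$elety),
    element       = elem,
    residue_pos   = residue_pos,
    author_resnum = at$resno,
    chain         = at$chain,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates in '", path, "'")
  }
  new_structure(atoms, residues, source_id = path)
}

#' Construct a protein_structure from atom and residue tables
#'
#' Low-level constructor used by [read_structure()] and the fixture
#' generators. Validates the internal indexing invariants.
#'
#' @param atoms data.frame of heavy atoms (see [read_structure()]).
#' @param residues data.frame of residues.
#' @param source_id free-text identifier.
#' @return A `protein_structure`.
#' @export
new_structure <- function(atoms, residues, source_id = "") {
  stopifnot(nrow(residues) >= 1L)
  L <- nrow(residues)
  if (!identical(sort(unique(atoms$residue_pos)), 0:(L - 1L))) {
    stop("every residue must have at least one heavy atom and internal ",
         "indices must be consecutive 0..L-1")
  }
  structure(
    list(atoms = atoms, residues = residues, length = L,
         source_id = source_id),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", x$source_id, "\n")
  cat("  residues:", x$length, "  heavy atoms:", nrow(x$atoms), "\n")
  invisible(x)
}

#' Write a bead/atom structure to a PDB file
#'
#' Round-trip companion to [read_structure()]; used mainly to export
#' generated toy structures so they can flow through any PDB-consuming tool.
#'
#' @param s A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  stopifnot(inherits(s, "protein_structure"))
  a <- s$atoms
  res3 <- bio3d::aa123(s$residues$aa[a$residue_pos + 1L])
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    eleno = a$serial,
    elety = a$name,
    resid = res3,
    chain = a$chain,
    resno = a$author_resnum,
    elesy = a$element
  )
  invisible(path)
}

#' Extract C-alpha coordinates from a structure
#'
#' @param s A `protein_structure`.
#' @return L x 3 matrix of CA coordinates (Angstrom), one row per residue.
#' @export
ca_coords <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  ca <- s$atoms[s$atoms$name == "CA", , drop = FALSE]
  if (nrow(ca) != s$length || !identical(sort(ca$residue_pos),
                                         0:(s$length - 1L))) {
    stop("structure must have exactly one CA atom per residue")
  }
  ca <- ca[order(ca$residue_pos), , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' Sequence of a structure as a one-letter string
#'
#' @param s A `protein_structure`.
#' @return Character scalar of one-letter residue codes.
#' @export
structure_sequence <- function(s) {
  paste(s$residues$aa, collapse = "")
}
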