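#' Structures and structural ensembles
#'
#' A `Structure` couples an atom table (one row per atom: identity, residue
#' membership, backbone/heavy flags) with an n x 3 coordinate matrix in
#' Angstrom.  A `StructuralEnsemble` shares one atom table (the topology)
#' across an ordered set of frames, stored bio3d-style as an
#' n_frames x 3*n_atoms matrix with columns x1,y1,z1,x2,...
#'
#' The atom table is the single indexing authority: every per-residue profile
#' produced by this package uses the residue order defined here (order of
#' first appearance, which for well-formed PDB files is (chain, resno,
#' insertion code) order).
#'
#' @name structure-objects
NULL

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

# Canonical atom-table constructor; fills derived columns.
make_atom_table <- function(elety, element, chain, resno, insert, resid) {
  insert[is.na(insert) | insert == ""] <- ""
  chain[is.na(chain) | chain == ""] <- "A"
  element <- toupper(element)
  if (any(!nzchar(element))) stop_allonet("every atom needs an element", "allonet_format_error")
  key <- paste(chain, resno, insert, sep = ":")
  atoms <- data.frame(
    atom_index = seq_along(elety) - 1L,
    elety = as.character(elety),
    element = element,
    chain = as.character(chain),
    resno = as.integer(resno),
    insert = as.character(insert),
    resid = as.character(resid),
    stringsAsFactors = FALSE
  )
  atoms$residue_key <- key
  atoms$res_index <- match(key, unique(key))
  atoms$is_backbone <- atoms$elety %in% BACKBONE_NAMES
  atoms$is_heavy <- atoms$element != "H"
  atoms
}

#' Create a Structure object
#'
#' @param atoms atom table as built by the readers/generators
#' @param xyz numeric n_atoms x 3 coordinate matrix (Angstrom)
#' @return object of class `Structure`
#' @export
new_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3L)
    stop_allonet("coordinate count must equal atom count", "allonet_consistency_error")
  if (!all(is.finite(xyz)))
    stop_allonet("coordinates must be finite", "allonet_format_error")
  structure(list(atoms = atoms, xyz = xyz), class = "Structure")
}

#' Create a StructuralEnsemble
#'
#' @param atoms shared atom table (the topology)
#' @param xyz n_frames x 3*n_atoms matrix, columns x1,y1,z1,x2,...
#' @param labels optional per-frame labels
#' @return object of class `StructuralEnsemble`
#' @export
new_ensemble <- function(atoms, xyz, labels = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop_allonet("every frame must have the same atom count as the topology",
                 "allonet_consistency_error")
  if (nrow(xyz) < 1L)
    stop_allonet("an ensemble needs at least one frame", "allonet_consistency_error")
  if (!is.null(labels) && length(labels) != nrow(xyz))
    stop_allonet("one label per frame required", "allonet_consistency_error")
  structure(list(atoms = atoms, xyz = xyz, labels = labels),
            class = "StructuralEnsemble")
}

#' Number of frames in an ensemble
#' @param ensemble a `StructuralEnsemble`
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Extract one frame as an n x 3 coordinate matrix
#' @param ensemble a `StructuralEnsemble`
#' @param i frame index
#' @export
frame_coords <- function(ensemble, i) {
  matrix(ensemble$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Extract one frame as a Structure
#' @inheritParams frame_coords
#' @export
frame_structure <- function(ensemble, i) {
  new_structure(ensemble$atoms, frame_coords(ensemble, i))
}

#' Promote a Structure to a one-frame ensemble
#' @param x a `Structure`
#' @param labels optional frame label
#' @export
as_ensemble <- function(x, labels = NULL) {
  if (inherits(x, "StructuralEnsemble")) return(x)
  new_ensemble(x$atoms, matrix(t(x$xyz), nrow = 1L), labels = labels)
}

flat_xyz <- function(xyz) as.numeric(t(xyz))

#' Residue table of a structure or ensemble
#'
#' One row per residue in canonical order with columns chain, resno, insert,
#' resid, residue_key, res_index.
#' @param x `Structure`, `StructuralEnsemble`, or an atom table
#' @export
residue_table <- function(x) {
  atoms <- if (is.data.frame(x)) x else x$atoms
  r <- atoms[!duplicated(atoms$res_index),
             c("chain", "resno", "insert", "resid", "residue_key", "res_index")]
  rownames(r) <- NULL
  r
}

n_residues <- function(x) {
  atoms <- if (is.data.frame(x)) x else x$atoms
  max(atoms$res_index)
}

# Resolve a residue selection to dense residue indices.  Accepts residue keys
# ("A:10:"), integer residue indices, or a logical mask over residues.
resolve_residues <- function(x, selection) {
  rt <- residue_table(x)
  if (is.null(selection)) return(rt$res_index)
  if (is.logical(selection)) {
    stopifnot(length(selection) == nrow(rt))
    return(rt$res_index[selection])
  }
  if (is.numeric(selection)) {
    if (!all(selection %in% rt$res_index))
      stop_allonet("residue index out of range", "allonet_validation_error")
    return(as.integer(selection))
  }
  idx <- match(selection, rt$residue_key)
  if (anyNA(idx)) {
    # tolerate bare "chain:resno" keys without insertion code
    idx2 <- match(selection, paste(rt$chain, rt$resno, sep = ":"))
    idx[is.na(idx)] <- idx2[is.na(idx)]
  }
  if (anyNA(idx))
    stop_allonet(paste("unknown residues:",
                       paste(selection[is.na(idx)], collapse = ", ")),
                 "allonet_validation_error")
  rt$res_index[idx]
}

# Atom indices for a residue selection under an atom mode.
select_atoms <- function(x, residues = NULL, mode = c("CA", "heavy", "backbone", "all")) {
  mode <- match.arg(mode)
  atoms <- if (is.data.frame(x)) x else x$atoms
  ridx <- resolve_residues(x, residues)
  keep <- atoms$res_index %in% ridx
  keep <- keep & switch(mode,
    CA = atoms$elety == "CA",
    heavy = atoms$is_heavy,
    backbone = atoms$is_backbone & atoms$is_heavy,
    all = TRUE)
  which(keep)
}

# Side-chain heavy atoms per residue; glycine (no side chain beyond CA)
# contributes its CA so it can still form network edges.
sidechain_atom_indices <- function(atoms) {
  sc <- atoms$is_heavy & !atoms$is_backbone
  out <- which(sc)
  have <- unique(atoms$res_index[sc])
  gly <- setdiff(unique(atoms$res_index), have)
  if (length(gly))
    out <- sort(c(out, which(atoms$elety == "CA" & atoms$res_index %in% gly)))
  out
}

#' Subset a structure or ensemble to a set of atom indices
#'
#' Residue indices are re-derived after subsetting; residue keys are stable.
#' @param x `Structure` or `StructuralEnsemble`
#' @param atom_idx integer atom indices to keep
#' @export
subset_atoms <- function(x, atom_idx) {
  atom_idx <- sort(atom_idx)
  atoms <- x$atoms[atom_idx, , drop = FALSE]
  atoms$atom_index <- seq_len(nrow(atoms)) - 1L
  atoms$res_index <- match(atoms$residue_key, unique(atoms$residue_key))
  rownames(atoms) <- NULL
  cols <- as.numeric(t(outer(atom_idx, 0:2, function(i, k) 3 * (i - 1) + 1 + k)))
  if (inherits(x, "StructuralEnsemble"))
    new_ensemble(atoms, x$xyz[, cols, drop = FALSE], labels = x$labels)
  else new_structure(atoms, x$xyz[atom_idx, , drop = FALSE])
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), n_residues(x), length(unique(x$atoms$chain))))
  invisible(x)
}

#' @export
print.StructuralEnsemble <- function(x, ...) {
  cat(sprintf("StructuralEnsemble: %d frames, %d atoms, %d residues\n",
              n_frames(x), nrow(x$atoms), n_residues(x)))
  invisible(x)
}

# Empty per-residue profile data.frame for a topology.
profile_frame <- function(x, value, name = "value") {
  rt <- residue_table(x)
  out <- rt[, c("chain", "resno", "insert", "resid")]
  out[[name]] <- value
  out
}
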