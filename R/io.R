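#' Read a protein structure from a PDB file
#'
#' Parsing is delegated to \code{bio3d::read.pdb}; on top of it this reader
#' enforces the package's indexing contract: alternate locations are resolved
#' to the highest-occupancy copy (ties broken alphabetically, so "A" wins),
#' crystallographic waters are always removed, HETATM records are dropped
#' unless \code{keep_hetero = TRUE}, and hydrogens are retained but flagged
#' (\code{is_heavy = FALSE}) so that contact, depth and SASA computations can
#' exclude them.
#'
#' @param path PDB file
#' @param model model number for multi-model files (default: first)
#' @param keep_hetero keep non-water HETATM records (ligands)?
#' @return a [new_structure()] object
#' @export
read_structure <- function(path, model = NULL, keep_hetero = FALSE) {
  ens <- read_ensemble(path, keep_hetero = keep_hetero)
  m <- model %||% 1L
  if (m < 1L || m > n_frames(ens))
    stop_allonet(sprintf("model %d not found (%d models present)", m, n_frames(ens)),
                 "allonet_notfound_error")
  frame_structure(ens, m)
}

WATER_RESIDS <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "DOD")

#' Read a conformational ensemble
#'
#' Accepts a (possibly multi-model) PDB file, or a delimited long-format
#' coordinate table (columns \code{frame, x, y, z}, atoms in topology order
#' within each frame) together with a declared topology.
#'
#' @param path input file
#' @param topology a `Structure` (or atom table) declaring the atom order for
#'   delimited coordinate tables; ignored for PDB input
#' @param keep_hetero keep non-water HETATM records?
#' @return a [new_ensemble()] object, frames in file order
#' @export
read_ensemble <- function(path, topology = NULL, keep_hetero = FALSE) {
  if (!file.exists(path))
    stop_allonet(paste("file not found:", path), "allonet_notfound_error")
  if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE))
    read_ensemble_pdb(path, keep_hetero = keep_hetero)
  else read_ensemble_table(path, topology)
}

read_ensemble_pdb <- function(path, keep_hetero = FALSE) {
  txt <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", txt)
  if (!any(is_atom))
    stop_allonet("no ATOM/HETATM records found", "allonet_format_error")
  # ragged multi-model files confuse downstream matrix reshaping; diagnose here
  model_id <- cumsum(grepl("^MODEL", txt))
  counts <- table(model_id[is_atom])
  if (length(counts) > 1L && length(unique(as.integer(counts))) != 1L)
    stop_allonet("models differ in atom count", "allonet_consistency_error")
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop_allonet(paste("unparseable PDB:", conditionMessage(e)),
                                     "allonet_format_error"))
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  keep[at$resid %in% WATER_RESIDS] <- FALSE
  if (!keep_hetero) keep[at$type == "HETATM"] <- FALSE
  if (!any(keep))
    stop_allonet("no atoms left after water/hetero filtering", "allonet_format_error")
  # altloc: highest occupancy wins, ties broken by altloc letter
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  uid <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(-occ, alt)
  first <- ord[!duplicated(uid[ord])]
  keep_alt <- sort(first)
  keep <- keep & seq_len(nrow(at)) %in% keep_alt
  idx <- which(keep)
  at <- at[idx, , drop = FALSE]
  element <- at$elesy
  element[is.na(element) | element == ""] <- substr(gsub("[^A-Za-z].*", "", at$elety[is.na(element) | element == ""]), 1, 1)
  atoms <- make_atom_table(at$elety, element, at$chain, at$resno,
                           ifelse(is.na(at$insert), "", at$insert), at$resid)
  cols <- as.numeric(t(cbind(3 * (idx - 1) + 1, 3 * (idx - 1) + 2, 3 * idx)))
  xyz <- pdb$xyz[, cols, drop = FALSE]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  new_ensemble(atoms, xyz)
}

read_ensemble_table <- function(path, topology) {
  if (is.null(topology))
    stop_allonet("delimited coordinate tables need a declared topology",
                 "allonet_validation_error")
  atoms <- if (is.data.frame(topology)) topology else topology$atoms
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("frame", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop_allonet("coordinate table needs columns frame, x, y, z",
                 "allonet_format_error")
  fr <- unique(tab$frame)
  per <- table(tab$frame)
  if (length(unique(as.integer(per))) != 1L || per[[1]] != nrow(atoms))
    stop_allonet("frames differ in atom count or do not match the topology",
                 "allonet_consistency_error")
  xyz <- matrix(NA_real_, length(fr), 3L * nrow(atoms))
  for (k in seq_along(fr)) {
    sub <- tab[tab$frame == fr[k], c("x", "y", "z")]
    xyz[k, ] <- as.numeric(t(as.matrix(sub)))
  }
  new_ensemble(atoms, xyz, labels = as.character(fr))
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble a `StructuralEnsemble`
#' @param path output file
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  a <- ensemble$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    co <- frame_coords(ensemble, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       seq_len(nrow(a)) %% 100000,
                       ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
                       a$resid, a$chain, a$resno, ifelse(a$insert == "", " ", a$insert),
                       co[, 1], co[, 2], co[, 3], a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Parse a domain annotation config
#'
#' A YAML mapping from segment name to residue ranges, e.g.
#' \code{IA: "A:1-10"} or \code{SBD: "389-420, 430-440"} (chain defaults to
#' the topology's first chain).  Ranges are expanded to residue-key sets;
#' overlapping segments are rejected.
#'
#' @param path YAML file, or a named list of range strings
#' @param topology `Structure`/`StructuralEnsemble` the annotation refers to
#' @param strict unknown residues are an error (`TRUE`) or a warning
#' @param colors optional named vector of display colors
#' @return list of class `DomainAnnotation`: named list of residue-key sets
#' @export
parse_domain_annotation <- function(path, topology, strict = TRUE, colors = NULL) {
  spec <- if (is.list(path)) path else yaml::read_yaml(path)
  if (!length(spec)) stop_allonet("empty annotation", "allonet_validation_error")
  rt <- residue_table(topology)
  default_chain <- rt$chain[1]
  segments <- lapply(spec, function(ranges) {
    keys <- character()
    for (part in trimws(strsplit(as.character(ranges), ",")[[1]])) {
      chain <- default_chain
      if (grepl(":", part)) {
        chain <- sub(":.*", "", part)
        part <- sub("^[^:]*:", "", part)
      }
      nums <- as.integer(strsplit(part, "-")[[1]])
      if (anyNA(nums)) stop_allonet(paste("bad range:", part), "allonet_validation_error")
      lo <- nums[1]; hi <- if (length(nums) > 1) nums[2] else nums[1]
      hit <- rt$chain == chain & rt$resno >= lo & rt$resno <= hi
      want <- lo:hi
      missing <- setdiff(want, rt$resno[hit])
      if (length(missing)) {
        msg <- sprintf("annotation references unknown residues %s of chain %s",
                       paste(missing, collapse = ","), chain)
        if (strict) stop_allonet(msg, "allonet_validation_error") else warning(msg)
      }
      keys <- c(keys, rt$residue_key[hit])
    }
    unique(keys)
  })
  all_keys <- unlist(segments)
  if (anyDuplicated(all_keys))
    stop_allonet("domain segments overlap", "allonet_validation_error")
  structure(list(segments = segments, colors = colors), class = "DomainAnnotation")
}

#' Write a per-residue profile as TSV
#'
#' Columns: chain, resnum, icode, restype, value.  Values are written with
#' full precision; non-finite values use the sentinel tokens
#' \code{inf}/\code{-inf}/\code{nan} and round-trip through [read_profile()].
#'
#' @param profile data.frame with columns chain, resno, insert, resid and one
#'   numeric value column (the last column)
#' @param path output file
#' @export
write_profile <- function(profile, path) {
  vcol <- names(profile)[ncol(profile)]
  out <- data.frame(chain = profile$chain, resnum = profile$resno,
                    icode = ifelse(profile$insert == "", ".", profile$insert),
                    restype = profile$resid,
                    value = format_value(profile[[vcol]]),
                    stringsAsFactors = FALSE)
  names(out)[5] <- vcol
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(out, sep = "\t")), con)
  invisible(path)
}

#' Read back a profile written by [write_profile()]
#' @param path TSV file
#' @return data.frame with columns chain, resno, insert, resid, value
#' @export
read_profile <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  data.frame(chain = tab[[1]], resno = as.integer(tab[[2]]),
             insert = ifelse(tab[[3]] == ".", "", tab[[3]]),
             resid = tab[[4]], value = parse_value(tab[[5]]),
             stringsAsFactors = FALSE)
}

#' Write a residue-graph edge list as TSV
#' @param im an `InteractionMatrix` from [interaction_strengths()]
#' @param path output file
#' @param I_min optional threshold: only edges with I >= I_min are written
#' @export
write_edge_list <- function(im, path, I_min = 0) {
  keys <- rownames(im$I)
  idx <- which(upper.tri(im$I) & im$I >= I_min & im$I > 0, arr.ind = TRUE)
  out <- data.frame(resA = keys[idx[, 1]], resB = keys[idx[, 2]],
                    n_ij = im$n[idx], I_ij = format_value(im$I[idx]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
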