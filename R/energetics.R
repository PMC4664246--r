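#' Nonpolar solvation free energy from SASA
#'
#' \eqn{\Delta G_{np} = \sigma \cdot SASA} with \eqn{\sigma = 0.0072}
#' kcal/(mol A^2).
#'
#' @param sasa solvent-accessible surface area (A^2, >= 0)
#' @param sigma surface tension coefficient
#' @return kcal/mol
#' @export
nonpolar_solvation <- function(sasa, sigma = 0.0072) {
  if (any(sasa < 0)) stop_allonet("SASA must be >= 0", "allonet_parameter_error")
  sigma * sasa
}

# Generic per-element pair parameters: LJ sigma (A), epsilon (kcal/mol).
# Chosen for reproducibility, not force-field realism.
DEFAULT_PAIR_PARAMS <- data.frame(
  element = c("C", "N", "O", "S", "H", "P"),
  sigma = c(3.40, 3.25, 3.00, 3.60, 2.50, 3.70),
  epsilon = c(0.10, 0.17, 0.21, 0.25, 0.02, 0.20),
  stringsAsFactors = FALSE
)

#' Simple pairwise molecular-mechanics energy backend
#'
#' A deterministic surrogate energy function over heavy atoms:
#' Lennard-Jones 12-6 van der Waals
#' (\eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}, Lorentz-Berthelot
#' mixing) plus Coulomb electrostatics with a distance-dependent dielectric
#' \eqn{\epsilon(r) = 4r} (\eqn{E = 332.06\, q_i q_j / (4 r \cdot r)}).
#' Atom charges default to 0 and can be supplied through a `charge` column
#' of the atom table or the \code{charges} argument.  \eqn{E_{bond}} is 0
#' (rigid snapshots) and the polar solvation hook defaults to 0.
#'
#' @param params per-element parameter table (element, sigma, epsilon)
#' @param coulomb_k Coulomb constant, kcal A / (mol e^2)
#' @param charges optional named vector: atom name -> partial charge
#' @param gb_hook optional function(structure) returning a polar solvation
#'   free energy (kcal/mol); default contributes 0
#' @return a backend function(structure) -> named list of energy terms
#'   (E_bond, E_vdw, E_elec, G_elec_solv)
#' @export
simple_pair_backend <- function(params = DEFAULT_PAIR_PARAMS, coulomb_k = 332.06,
                                charges = NULL, gb_hook = NULL) {
  function(structure) {
    atoms <- structure$atoms
    heavy <- which(atoms$is_heavy)
    el <- atoms$element[heavy]
    pi_ <- match(el, params$element)
    if (anyNA(pi_))
      stop_allonet(paste("no pair parameters for element(s):",
                         paste(unique(el[is.na(pi_)]), collapse = ", ")),
                   "allonet_coverage_error")
    sig <- params$sigma[pi_]; eps <- params$epsilon[pi_]
    q <- if (!is.null(atoms$charge)) atoms$charge[heavy]
         else if (!is.null(charges)) unname(ifelse(is.na(charges[atoms$elety[heavy]]),
                                                   0, charges[atoms$elety[heavy]]))
         else rep(0, length(heavy))
    n <- length(heavy)
    if (n < 2)
      return(list(E_bond = 0, E_vdw = 0, E_elec = 0, G_elec_solv = 0))
    co <- structure$xyz[heavy, , drop = FALSE]
    D <- as.matrix(stats::dist(co))
    ut <- upper.tri(D)
    r <- D[ut]
    sij <- outer(sig, sig, `+`)[ut] / 2
    eij <- sqrt(outer(eps, eps))[ut]
    sr6 <- (sij / r)^6
    e_vdw <- sum(4 * eij * (sr6^2 - sr6))
    qq <- outer(q, q)[ut]
    e_elec <- sum(coulomb_k * qq / (4 * r * r))
    gsolv <- if (is.null(gb_hook)) 0 else gb_hook(structure)
    list(E_bond = 0, E_vdw = e_vdw, E_elec = e_elec, G_elec_solv = gsolv)
  }
}

#' Per-snapshot energy table for a complex (single-trajectory protocol)
#'
#' For every frame the backend is evaluated on the complex, the receptor
#' alone, and the ligand alone, all at the coordinates of that same frame
#' (no re-minimization), so the intramolecular terms cancel exactly and
#' only interaction and solvation differences remain:
#' \eqn{\Delta E_{vdw}}, \eqn{\Delta E_{elec}},
#' \eqn{\Delta G_{np} = \sigma (SASA_{complex} - SASA_{rec} - SASA_{lig})},
#' \eqn{\Delta G_{elec,solv}} from the backend's polar hook.
#'
#' @param ensemble complex `StructuralEnsemble` (or `Structure`)
#' @param receptor_sel,ligand_sel residue selections partitioning the atoms
#' @param backend energy backend (default [simple_pair_backend()])
#' @param sigma_np nonpolar surface coefficient (kcal/(mol A^2))
#' @param compute_sasa evaluate the SASA nonpolar term?
#' @param probe,points_per_atom surface parameters for the SASA term
#' @return a `snapshot_energy_table` data.frame, one row per frame
#' @export
snapshot_energy_table <- function(ensemble, receptor_sel, ligand_sel,
                                  backend = simple_pair_backend(),
                                  sigma_np = 0.0072, compute_sasa = TRUE,
                                  probe = 1.4, points_per_atom = 64L) {
  ensemble <- as_ensemble(ensemble)
  r_res <- resolve_residues(ensemble, receptor_sel)
  l_res <- resolve_residues(ensemble, ligand_sel)
  if (length(intersect(r_res, l_res)))
    stop_allonet("receptor and ligand selections overlap", "allonet_validation_error")
  if (length(union(r_res, l_res)) != n_residues(ensemble))
    stop_allonet("selections must partition the complex", "allonet_validation_error")
  ridx <- which(ensemble$atoms$res_index %in% r_res)
  lidx <- which(ensemble$atoms$res_index %in% l_res)
  F <- n_frames(ensemble)
  rows <- vector("list", F)
  for (f in seq_len(F)) {
    cplx <- frame_structure(ensemble, f)
    rec <- subset_atoms(cplx, ridx)
    lig <- subset_atoms(cplx, lidx)
    ec <- backend(cplx); er <- backend(rec); el <- backend(lig)
    d_np <- 0
    if (compute_sasa && sigma_np != 0) {
      sc <- shrake_sasa(cplx, probe, points_per_atom)$total
      sr <- shrake_sasa(rec, probe, points_per_atom)$total
      sl <- shrake_sasa(lig, probe, points_per_atom)$total
      d_np <- sigma_np * (sc - sr - sl)
    }
    rows[[f]] <- data.frame(
      frame = f,
      dE_intra = 0,   # exact cancellation under the single-trajectory protocol
      dE_vdw = ec$E_vdw - er$E_vdw - el$E_vdw,
      dE_elec = ec$E_elec - er$E_elec - el$E_elec,
      dG_np = d_np,
      dG_elec_solv = ec$G_elec_solv - er$G_elec_solv - el$G_elec_solv)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("snapshot_energy_table", "data.frame")
  out
}

#' MM-GBSA aggregation of a snapshot energy table
#'
#' \eqn{\Delta G_{bind} = \langle\Delta G_{MM}\rangle +
#' \langle\Delta G_{solv}\rangle - \langle T\Delta S\rangle} with
#' \eqn{\Delta G_{MM} = \Delta E_{intra} + \Delta E_{vdw} + \Delta E_{elec}}
#' and \eqn{\Delta G_{solv} = \Delta G_{np} + \Delta G_{elec,solv}};
#' the entropy term is a user-supplied scalar (default 0).
#'
#' @param table a `snapshot_energy_table`
#' @param TdS entropy contribution T Delta S (kcal/mol)
#' @return object of class `binding_free_energy` with the component means
#'   and `dG_bind`; the identity dG_bind = dG_MM + dG_solv - TdS is exact
#' @export
mmgbsa_aggregate <- function(table, TdS = 0) {
  if (!nrow(table)) stop_allonet("empty energy table", "allonet_validation_error")
  col <- function(nm) if (nm %in% names(table)) table[[nm]] else rep(0, nrow(table))
  dG_MM <- mean(col("dE_intra") + col("dE_vdw") + col("dE_elec"))
  dG_solv <- mean(col("dG_np") + col("dG_elec_solv"))
  structure(list(dG_MM = dG_MM, dG_solv = dG_solv, TdS = TdS,
                 dG_bind = dG_MM + dG_solv - TdS,
                 components = c(dE_intra = mean(col("dE_intra")),
                                dE_vdw = mean(col("dE_vdw")),
                                dE_elec = mean(col("dE_elec")),
                                dG_np = mean(col("dG_np")),
                                dG_elec_solv = mean(col("dG_elec_solv"))),
                 n_snapshots = nrow(table)),
            class = "binding_free_energy")
}

#' @export
print.binding_free_energy <- function(x, ...) {
  cat(sprintf("dG_bind = %.4f kcal/mol (dG_MM %.4f + dG_solv %.4f - TdS %.4f; %d snapshots)\n",
              x$dG_bind, x$dG_MM, x$dG_solv, x$TdS, x$n_snapshots))
  invisible(x)
}

# Atom indices removed by truncating a residue's side chain beyond C-beta.
truncation_atoms <- function(atoms, ridx) {
  which(atoms$res_index == ridx & atoms$is_heavy & !atoms$is_backbone &
          atoms$elety != "CB")
}

#' Computational alanine scanning by C-beta truncation
#'
#' For each listed residue, every snapshot is rebuilt with the side-chain
#' atoms beyond C-beta removed (C-beta keeps its coordinates; no
#' re-minimization, the wild-type-trajectory assumption) and the binding
#' free energy recomputed with the same backend:
#' \eqn{\Delta\Delta G = \Delta G_{mut} - \Delta G_{WT}}.  Glycine/alanine
#' residues have nothing to remove and report exactly 0.
#'
#' @param ensemble complex ensemble
#' @param residues residue keys/indices to scan
#' @param receptor_sel,ligand_sel the binding partition
#' @param backend energy backend
#' @param TdS entropy term passed to the aggregation
#' @param ... further arguments to [snapshot_energy_table()]
#' @return data.frame of class `ala_scan_result`: residue, ddG and component
#'   differences, note
#' @export
alanine_scan <- function(ensemble, residues, receptor_sel, ligand_sel,
                         backend = simple_pair_backend(), TdS = 0, ...) {
  ensemble <- as_ensemble(ensemble)
  wt_table <- snapshot_energy_table(ensemble, receptor_sel, ligand_sel,
                                    backend = backend, ...)
  wt <- mmgbsa_aggregate(wt_table, TdS)
  ridx <- resolve_residues(ensemble, residues)
  rt <- residue_table(ensemble)
  rec_keys <- rt$residue_key[resolve_residues(ensemble, receptor_sel)]
  lig_keys <- rt$residue_key[resolve_residues(ensemble, ligand_sel)]
  rows <- lapply(ridx, function(r) {
    if (!rt$residue_key[r] %in% c(rec_keys, lig_keys))
      stop_allonet("scanned residue outside receptor/ligand", "allonet_validation_error")
    base <- data.frame(node = rt$residue_key[r], resid = rt$resid[r],
                       ddG = 0, d_dE_vdw = 0, d_dE_elec = 0, d_dG_np = 0,
                       d_dG_elec_solv = 0, note = "",
                       stringsAsFactors = FALSE)
    drop_atoms <- truncation_atoms(ensemble$atoms, r)
    if (!length(drop_atoms)) {
      base$note <- "no side-chain atoms beyond C-beta"
      return(base)
    }
    mut <- subset_atoms(ensemble, setdiff(seq_len(nrow(ensemble$atoms)), drop_atoms))
    mut_table <- snapshot_energy_table(mut, rec_keys, lig_keys,
                                       backend = backend, ...)
    mu <- mmgbsa_aggregate(mut_table, TdS)
    base$ddG <- mu$dG_bind - wt$dG_bind
    base$d_dE_vdw <- mu$components[["dE_vdw"]] - wt$components[["dE_vdw"]]
    base$d_dE_elec <- mu$components[["dE_elec"]] - wt$components[["dE_elec"]]
    base$d_dG_np <- mu$components[["dG_np"]] - wt$components[["dG_np"]]
    base$d_dG_elec_solv <- mu$components[["dG_elec_solv"]] - wt$components[["dG_elec_solv"]]
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ala_scan_result", "data.frame")
  out
}
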