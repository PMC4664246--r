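#' Build a toy protein with pseudo side chains
#'
#' Constructs a small synthetic polypeptide whose backbone follows an ideal
#' alpha-helical or extended geometry and whose residues carry
#' \code{sidechain_atoms} pseudo side-chain heavy atoms (the first named CB,
#' the rest CG, CD, ...) fanned off the outward C-alpha direction, with a
#' small seeded jitter so atom-contact counting is nontrivial.  Residue types
#' cycle through a fixed set so normalization factors become type-dependent.
#'
#' Each residue therefore contributes 4 backbone heavy atoms (N, CA, C, O)
#' plus \code{sidechain_atoms} side-chain heavy atoms.
#'
#' @param n_residues number of residues (>= 2)
#' @param geometry "helix" (2.3 A radius, 1.5 A rise, 100 deg/residue) or
#'   "extended" (3.8 A C-alpha spacing along x)
#' @param sidechain_atoms pseudo side-chain heavy atoms per residue
#' @param seed RNG seed for the side-chain jitter
#' @return a [new_structure()] object
#' @export
build_toy_protein <- function(n_residues, geometry = c("helix", "extended"),
                              sidechain_atoms = 3L, seed = 1L) {
  geometry <- match.arg(geometry)
  if (n_residues < 2)
    stop_allonet("need at least 2 residues", "allonet_parameter_error")
  sidechain_atoms <- max(0L, as.integer(sidechain_atoms))
  types <- c("ALA", "VAL", "LEU", "PHE", "SER")

  i <- seq_len(n_residues)
  if (geometry == "helix") {
    theta <- (i - 1) * 100 * pi / 180
    ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
    out_dir <- cbind(cos(theta), sin(theta), 0)   # radially outward
  } else {
    dx <- sqrt(3.8^2 - 1.2^2)   # zigzag step preserving 3.8 A CA-CA distance
    ca <- cbind(dx * (i - 1), 0.6 * (-1)^i, 0)
    out_dir <- cbind(0, (-1)^i, 0)
  }

  with_op_seed(seed, "build_toy_protein", {
    elety <- character(); element <- character()
    resno <- integer(); resid <- character()
    xyz <- NULL
    axis <- cbind(0, 0, 1)
    for (r in i) {
      o <- out_dir[r, ]
      a <- c(0, 0, 1)
      side <- c(o[2] * a[3] - o[3] * a[2], o[3] * a[1] - o[1] * a[3],
                o[1] * a[2] - o[2] * a[1])   # o x a
      n_pos <- ca[r, ] - 1.46 * (0.5 * o + 0.7 * side + 0.4 * a)
      c_pos <- ca[r, ] + 1.52 * (-0.4 * o + 0.7 * side + 0.5 * a)
      o_pos <- c_pos + 1.23 * (-0.6 * o - 0.6 * side + 0.4 * a)
      res_xyz <- rbind(n_pos, ca[r, ], c_pos, o_pos)
      res_ety <- c("N", "CA", "C", "O")
      if (sidechain_atoms >= 1L) {
        cb <- ca[r, ] + 1.53 * o
        res_xyz <- rbind(res_xyz, cb)
        res_ety <- c(res_ety, "CB")
        if (sidechain_atoms >= 2L) {
          # fan of pseudo atoms off CB, tilted along the chain axis so that
          # side chains of neighbouring helix turns come into contact range
          for (s in seq_len(sidechain_atoms - 1L)) {
            ang <- 2 * pi * (s - 1) / max(1, sidechain_atoms - 1)
            dir <- 0.3 * o + 0.95 * (cos(ang) * a + sin(ang) * side)
            dir <- dir / sqrt(sum(dir^2))
            jit <- stats::runif(3, -0.15, 0.15)
            res_xyz <- rbind(res_xyz, cb + 1.5 * s * dir + jit)
            res_ety <- c(res_ety, paste0("C", LETTERS[6 + s]))  # CG, CH, ...
          }
        }
      }
      xyz <- rbind(xyz, res_xyz)
      elety <- c(elety, res_ety)
      element <- c(element, substr(res_ety, 1, 1))
      resno <- c(resno, rep(r, length(res_ety)))
      resid <- c(resid, rep(types[(r - 1) %% length(types) + 1], length(res_ety)))
    }
    atoms <- make_atom_table(elety, element, "A", resno, "", resid)
    new_structure(atoms, xyz)
  })
}

#' Toy structure whose residues are single C-alpha atoms
#'
#' Convenience generator for oracle tests that need a bare node set.
#' @inheritParams build_toy_protein
#' @export
build_toy_ca_trace <- function(n_residues, geometry = c("helix", "extended")) {
  s <- build_toy_protein(n_residues, geometry, sidechain_atoms = 0L)
  subset_atoms(s, which(s$atoms$elety == "CA"))
}
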