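# Standard torsion templates.
#
# Amino acids: phi (C-, N, CA, C), psi (N, CA, C, N+) and the side-chain
# chi ladder below; omega is excluded by default (near-constant, inflates
# dimensionality). Nucleotides: backbone alpha..zeta and glycosidic chi.
# Torsions reaching into a neighbouring residue belong to the residue
# owning the central bond.

.chi_atoms <- list(
  ALA = list(),
  GLY = list(),
  SER = list(chi1 = c("N", "CA", "CB", "OG")),
  CYS = list(chi1 = c("N", "CA", "CB", "SG")),
  THR = list(chi1 = c("N", "CA", "CB", "OG1")),
  VAL = list(chi1 = c("N", "CA", "CB", "CG1")),
  ILE = list(chi1 = c("N", "CA", "CB", "CG1"),
             chi2 = c("CA", "CB", "CG1", "CD1")),
  LEU = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "CD1")),
  PRO = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "CD")),
  MET = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "SD"),
             chi3 = c("CB", "CG", "SD", "CE")),
  PHE = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "CD1")),
  TYR = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "CD1")),
  TRP = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "CD1")),
  ASP = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "OD1")),
  ASN = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "OD1")),
  HIS = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "ND1")),
  GLU = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "OE1")),
  GLN = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "OE1")),
  LYS = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "CE"),
             chi4 = c("CG", "CD", "CE", "NZ")),
  ARG = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "NE"),
             chi4 = c("CG", "CD", "NE", "CZ"),
             chi5 = c("CD", "NE", "CZ", "NH1")))

.purines <- c("A", "G", "DA", "DG", "8OG", "OXG", "8OX")
.pyrimidines <- c("C", "T", "U", "DC", "DT", "DU")
.nucleic <- c(.purines, .pyrimidines)

#' Enumerate torsion-angle definitions for selected residues
#'
#' For amino acids: phi, psi and the standard side-chain chi1..chin
#' (omega excluded); for nucleotides: backbone alpha, beta, gamma,
#' delta, epsilon, zeta and the glycosidic chi. Inter-residue torsions
#' (phi, psi, alpha, epsilon, zeta) are included when the central bond
#' belongs to a selected residue, even if a boundary atom lies in a
#' non-selected neighbour. Torsions with missing atoms (chain termini,
#' truncated side chains) are silently dropped (one summary message).
#' Residues without a template are skipped with a warning.
#'
#' @param model `StructureModel` or `Trajectory`.
#' @param residues character vector of residue keys (see
#'   [residue_keys()]); `NULL` selects all residues with a template.
#' @return Data frame of torsion definitions: `label`
#'   (`"<chain>:<resno>:<name>"`), `chain`, `resno`, `torsion`, and atom
#'   indices `a1..a4` into the atom table.
#' @export
enumerate_torsions <- function(model, residues = NULL) {
  atoms <- model$atoms
  keys <- residue_keys(model)
  ures <- unique(keys)
  resname <- atoms$resid[match(ures, keys)]
  chain <- atoms$chain[match(ures, keys)]
  if (is.null(residues)) {
    residues <- ures[resname %in% c(names(.chi_atoms), .nucleic)]
  }
  # residue order within each chain follows file order
  defs <- list(); dropped <- 0L
  find <- function(key, name) {
    i <- which(keys == key & atoms$elety == name)
    if (length(i)) i[1L] else NA_integer_
  }
  for (key in residues) {
    pos <- match(key, ures)
    if (is.na(pos)) stop("residue ", key, " not present in the model")
    rn <- resname[pos]
    prev <- if (pos > 1L && chain[pos - 1L] == chain[pos]) ures[pos - 1L] else NA
    nxt <- if (pos < length(ures) && chain[pos + 1L] == chain[pos]) ures[pos + 1L] else NA
    tors <- list()
    if (rn %in% names(.chi_atoms)) {
      if (!is.na(prev))
        tors$phi <- c(find(prev, "C"), find(key, "N"), find(key, "CA"), find(key, "C"))
      if (!is.na(nxt))
        tors$psi <- c(find(key, "N"), find(key, "CA"), find(key, "C"), find(nxt, "N"))
      for (cn in names(.chi_atoms[[rn]]))
        tors[[cn]] <- vapply(.chi_atoms[[rn]][[cn]], find, integer(1L), key = key)
    } else if (rn %in% .nucleic) {
      if (!is.na(prev))
        tors$alpha <- c(find(prev, "O3'"), find(key, "P"), find(key, "O5'"), find(key, "C5'"))
      tors$beta <- c(find(key, "P"), find(key, "O5'"), find(key, "C5'"), find(key, "C4'"))
      tors$gamma <- c(find(key, "O5'"), find(key, "C5'"), find(key, "C4'"), find(key, "C3'"))
      tors$delta <- c(find(key, "C5'"), find(key, "C4'"), find(key, "C3'"), find(key, "O3'"))
      if (!is.na(nxt)) {
        tors$epsilon <- c(find(key, "C4'"), find(key, "C3'"), find(key, "O3'"), find(nxt, "P"))
        tors$zeta <- c(find(key, "C3'"), find(key, "O3'"), find(nxt, "P"), find(nxt, "O5'"))
      }
      gly <- if (rn %in% .purines) c("O4'", "C1'", "N9", "C4") else c("O4'", "C1'", "N1", "C2")
      tors$chi <- vapply(gly, find, integer(1L), key = key)
    } else {
      warning("no torsion template for residue ", key, " (", rn, "); skipped")
      next
    }
    for (tn in names(tors)) {
      a <- tors[[tn]]
      if (anyNA(a)) { dropped <- dropped + 1L; next }
      defs[[paste0(key, ":", tn)]] <- data.frame(
        label = paste0(key, ":", tn), chain = chain[pos],
        resno = atoms$resno[match(key, keys)], torsion = tn,
        a1 = a[1L], a2 = a[2L], a3 = a[3L], a4 = a[4L],
        stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0L)
    message(dropped, " torsion(s) dropped for missing atoms")
  out <- do.call(rbind, defs)
  if (is.null(out))
    out <- data.frame(label = character(), chain = character(), resno = integer(),
                      torsion = character(), a1 = integer(), a2 = integer(),
                      a3 = integer(), a4 = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Signed dihedral (degrees) for stacked frames: p1..p4 are n x 3
# matrices. IUPAC convention: angle between plane(1,2,3) and
# plane(2,3,4), sign by the right-hand rule about the 2-3 bond; range
# (-180, 180]. Collinear central triples give NA.
dihedral_deg <- function(p1, p2, p3, p4) {
  cr <- function(a, b) cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                             a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                             a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  b2l <- sqrt(rowSums(b2^2))
  m1 <- cr(b2 / b2l, n1)
  ang <- atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  bad <- sqrt(rowSums(n1^2)) < 1e-9 | sqrt(rowSums(n2^2)) < 1e-9 | b2l < 1e-9
  ang[bad] <- NA_real_
  wrap_angle(ang)
}

#' Wrap angles into (-180, 180] degrees
#' @param x angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[!is.na(y) & y == -180] <- 180
  y
}

#' Compute per-frame torsion-angle series
#'
#' Evaluates each torsion definition in every frame of the trajectory
#' (standard signed dihedral, degrees in (-180, 180]). Frames in which
#' the three central atoms are collinear yield `NA` (reported once).
#'
#' @param traj `Trajectory` (or `StructureModel` for a single frame).
#' @param defs torsion definitions from [enumerate_torsions()].
#' @return Numeric matrix, frames x torsions, with `defs$label` as
#'   column names.
#' @export
compute_dihedral_series <- function(traj, defs) {
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nrow = nf, ncol = nrow(defs),
                dimnames = list(NULL, defs$label))
  get3 <- function(i) matrix(traj$xyz[, xyz_cols(i)], ncol = 3L)
  for (j in seq_len(nrow(defs))) {
    out[, j] <- dihedral_deg(get3(defs$a1[j]), get3(defs$a2[j]),
                             get3(defs$a3[j]), get3(defs$a4[j]))
  }
  if (anyNA(out))
    message(sum(is.na(out)), " torsion value(s) undefined (collinear atoms)")
  out
}

# Internal-to-Cartesian placement (natural extension reference frame):
# position of atom D given A, B, C, the C-D bond length r, the B-C-D
# angle theta and the A-B-C-D dihedral phi (degrees). Used by the toy
# structure builder; exact by construction, so scripted torsions are
# recovered to machine precision.
place_atom <- function(a, b, c, r, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2L] * bc[3L] - ab[3L] * bc[2L],
         ab[3L] * bc[1L] - ab[1L] * bc[3L],
         ab[1L] * bc[2L] - ab[2L] * bc[1L])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2L] * bc[3L] - n[3L] * bc[2L],
         n[3L] * bc[1L] - n[1L] * bc[3L],
         n[1L] * bc[2L] - n[2L] * bc[1L])
  d_local <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + cbind(bc, m, n) %*% d_local
}
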