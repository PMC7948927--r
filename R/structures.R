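#' Structure models and trajectories
#'
#' A `StructureModel` is a single set of atomic coordinates over a fixed
#' atom table; a `Trajectory` is an ordered series of coordinate frames
#' sharing one atom table (e.g. snapshots written as a multi-model PDB).
#' Both are lightweight S3 objects with
#' * `atoms`: data frame with columns `type` (ATOM/HETATM), `eleno`,
#'   `elety` (atom name), `resid` (residue name), `chain`, `resno`,
#'   `insert` (insertion code or `NA`), `elesy` (element symbol);
#' * `xyz`: numeric matrix with one row per frame and `3 * n_atoms`
#'   columns in x1,y1,z1,x2,... order (angstroms).
#'
#' @param atoms atom table as described above.
#' @param xyz coordinate matrix (a single frame may be given as a vector).
#' @param timestep_ps time between frames in picoseconds (trajectories).
#' @return An object of class `StructureModel` or `Trajectory`.
#' @export
structure_model <- function(atoms, xyz) {
  obj <- new_structure(atoms, xyz, timestep_ps = NULL)
  if (nrow(obj$xyz) != 1L)
    stop("a StructureModel holds exactly one frame; use trajectory() for several")
  class(obj) <- "StructureModel"
  obj
}

#' @rdname structure_model
#' @export
trajectory <- function(atoms, xyz, timestep_ps = 8) {
  stopifnot(timestep_ps > 0)
  obj <- new_structure(atoms, xyz, timestep_ps = timestep_ps)
  class(obj) <- "Trajectory"
  obj
}

new_structure <- function(atoms, xyz, timestep_ps) {
  stopifnot(is.data.frame(atoms))
  need <- c("elety", "resid", "chain", "resno")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$insert)) atoms$insert <- NA_character_
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(atoms$elety)
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns but the atom table implies ", 3L * nrow(atoms))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicated (chain, residue, atom name) in atom table: ",
         key[which(duplicated(key))[1L]])
  rownames(atoms) <- NULL
  list(atoms = atoms, xyz = xyz, timestep_ps = timestep_ps)
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  ifelse(substr(e, 1L, 1L) == "H", "H", substr(e, 1L, 1L))
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("<StructureModel> ", nrow(x$atoms), " atoms, ",
      length(unique(residue_keys(x))), " residues\n", sep = "")
  invisible(x)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("<Trajectory> ", n_frames(x), " frames x ", nrow(x$atoms), " atoms",
      if (!is.null(x$timestep_ps)) paste0(", dt = ", x$timestep_ps, " ps"), "\n", sep = "")
  invisible(x)
}

#' Number of coordinate frames
#' @param x a `StructureModel` or `Trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) nrow(x$xyz)

#' Residue keys
#'
#' Residues are identified throughout by the key
#' `"<chain>:<resno>"` (with the insertion code appended as
#' `"<chain>:<resno><icode>"` when present); PDB numbering is kept as
#' authored.
#'
#' @param x a structure/trajectory, or an atom table.
#' @return Character vector, one key per atom.
#' @export
residue_keys <- function(x) {
  atoms <- if (is.data.frame(x)) x else x$atoms
  ins <- ifelse(is.na(atoms$insert) | atoms$insert == "", "", atoms$insert)
  paste0(atoms$chain, ":", atoms$resno, ins)
}

# xyz columns for atom indices
xyz_cols <- function(i) as.vector(rbind(3L * i - 2L, 3L * i - 1L, 3L * i))

# coordinates of atom indices in one frame, as an n x 3 matrix
frame_coords <- function(x, frame = 1L, atoms = seq_len(nrow(x$atoms))) {
  matrix(x$xyz[frame, xyz_cols(atoms)], ncol = 3L, byrow = TRUE)
}

# index of a single atom by (chain, resno, elety[, insert]); NA if absent
atom_index <- function(x, chain, resno, elety, insert = NA) {
  a <- x$atoms
  hit <- which(a$chain == chain & a$resno == resno & a$elety == elety &
                 (is.na(insert) | (!is.na(a$insert) & a$insert == insert)))
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Subset a structure or trajectory to a set of atoms
#'
#' Keeps the frame count; renumbers nothing.
#'
#' @param x a `StructureModel` or `Trajectory`.
#' @param idx integer atom indices to keep.
#' @return Object of the same class with the reduced atom table.
#' @export
subset_atoms <- function(x, idx) {
  idx <- sort(unique(as.integer(idx)))
  out <- x
  out$atoms <- x$atoms[idx, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$xyz <- x$xyz[, xyz_cols(idx), drop = FALSE]
  out
}

#' Read a (multi-model) PDB file
#'
#' Single-model files yield a [structure_model()]; files with several
#' `MODEL` blocks yield a [trajectory()] with frames in `MODEL` order.
#' All models must share an identical atom table; the first divergent
#' atom is reported otherwise. Parsing is delegated to
#' [bio3d::read.pdb()] after the consistency check.
#'
#' @param file path to a PDB file.
#' @param timestep_ps time between models, picoseconds (trajectories).
#' @return `StructureModel` or `Trajectory`.
#' @export
read_models <- function(file, timestep_ps = 8) {
  lines <- readLines(file, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  atom_line <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    blocks <- findInterval(which(atom_line), model_starts)
    sig <- substr(lines[atom_line], 13L, 27L)  # name/altloc/resname/chain/resseq/icode
    per <- split(sig, blocks)
    ref <- per[[1L]]
    for (m in seq_along(per)[-1L]) {
      if (length(per[[m]]) != length(ref) || any(per[[m]] != ref)) {
        at <- if (length(per[[m]]) < length(ref)) {
          k <- which(per[[m]] != ref[seq_along(per[[m]])])
          if (length(k)) per[[m]][k[1L]] else ref[length(per[[m]]) + 1L]
        } else {
          k <- which(per[[m]][seq_along(ref)] != ref)
          if (length(k)) per[[m]][k[1L]] else per[[m]][length(ref) + 1L]
        }
        stop("inconsistent atom table at model ", m, ": atom record '",
             trimws(at), "' diverges from model 1")
      }
    }
  }
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom[, c("type", "eleno", "elety", "resid", "chain", "resno",
                        "insert", "elesy")]
  atoms$elesy[is.na(atoms$elesy) | atoms$elesy == ""] <- guess_element(
    atoms$elety[is.na(atoms$elesy) | atoms$elesy == ""])
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (nrow(xyz) == 1L) structure_model(atoms, xyz)
  else trajectory(atoms, xyz, timestep_ps = timestep_ps)
}

#' Write a structure (or one trajectory frame set) to PDB
#'
#' @param x `StructureModel` or `Trajectory` (all frames are written as
#'   `MODEL` blocks).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(x, file) {
  a <- x$atoms
  bio3d::write.pdb(file = file, xyz = x$xyz,
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = a$eleno, elety = a$elety, chain = a$chain,
                   insert = ifelse(is.na(a$insert), "", a$insert),
                   elesy = a$elesy)
  invisible(file)
}

#' Frame bookkeeping for a production run
#'
#' Converts a run length and snapshot interval into the produced and
#' analysed frame counts. A 40 ns run sampled every 8 ps yields 5000
#' snapshots, of which the final 2500 (the equilibrated tail) enter the
#' analysis by default.
#'
#' @param total_ns production run length, nanoseconds.
#' @param snapshot_ps snapshot interval, picoseconds.
#' @param tail number of trailing frames retained for analysis (capped
#'   at the produced count).
#' @return List with `n_frames`, `n_analysis`, `analysis_frames`
#'   (indices of the retained tail).
#' @export
trajectory_plan <- function(total_ns = 40, snapshot_ps = 8, tail = 2500) {
  stopifnot(total_ns > 0, snapshot_ps > 0, tail >= 1)
  n <- as.integer(round(total_ns * 1000 / snapshot_ps))
  k <- min(as.integer(tail), n)
  list(n_frames = n, n_analysis = k, analysis_frames = seq.int(n - k + 1L, n))
}

#' Keep only the trailing analysis window of a trajectory
#'
#' @param traj a `Trajectory`.
#' @param tail number of trailing frames to keep.
#' @return `Trajectory` with at most `tail` frames.
#' @export
trajectory_tail <- function(traj, tail = 2500) {
  n <- n_frames(traj)
  k <- min(tail, n)
  out <- traj
  out$xyz <- traj$xyz[seq.int(n - k + 1L, n), , drop = FALSE]
  out
}
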