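.water_resids_default <- c("HOH", "WAT", "TIP3", "SOL")
.ion_resids_default <- c("NA+", "CL-", "K+", "MG2", "SOD", "CLA", "MG", "ZN", "CA2")

#' Select active-site residues around a ligand
#'
#' Returns every residue with at least one atom within `cutoff`
#' angstroms of any ligand atom, in the given (reference) frame. By
#' default only heavy atoms are considered (the typical crystal
#' reference carries no hydrogens), waters/ions are excluded, and the
#' ligand itself is not part of the returned set.
#'
#' @param model `StructureModel` or `Trajectory` (frame `frame` used).
#' @param ligand ligand selector: residue name(s) matched against the
#'   atom table's `resid`, or residue key(s) (`"<chain>:<resno>"`).
#' @param cutoff distance cutoff, angstrom (default 5.0).
#' @param frame frame index used for distances.
#' @param include_hydrogens consider hydrogen atoms in the distance test.
#' @param include_ligand keep the ligand residue(s) in the output.
#' @param exclude_resids residue names never reported (waters/ions).
#' @return Sorted character vector of residue keys.
#' @export
select_active_site <- function(model, ligand, cutoff = 5.0, frame = 1L,
                               include_hydrogens = FALSE, include_ligand = FALSE,
                               exclude_resids = c(.water_resids_default,
                                                  .ion_resids_default)) {
  keys <- residue_keys(model)
  lig_idx <- ligand_atoms(model, ligand)
  if (length(lig_idx) == 0L) stop("ligand selector matched no atoms")
  heavy <- if (include_hydrogens) rep(TRUE, nrow(model$atoms)) else model$atoms$elesy != "H"
  lig_idx <- lig_idx[heavy[lig_idx]]
  cand <- which(heavy & !(keys %in% keys[lig_idx]) &
                  !(model$atoms$resid %in% exclude_resids))
  if (include_ligand) cand <- union(cand, lig_idx)
  if (length(cand) == 0L) return(character(0L))
  lc <- frame_coords(model, frame, lig_idx)
  cc <- frame_coords(model, frame, cand)
  d2 <- outer(rowSums(cc^2), rowSums(lc^2), `+`) - 2 * tcrossprod(cc, lc)
  near <- apply(d2, 1L, min) <= cutoff^2 + 1e-12
  sort(unique(keys[cand[near]]))
}

# atom indices matched by a ligand selector (residue names or keys)
ligand_atoms <- function(model, ligand) {
  keys <- residue_keys(model)
  if (any(grepl(":", ligand, fixed = TRUE))) which(keys %in% ligand)
  else which(model$atoms$resid %in% ligand)
}

#' Geometric parameter specification
#'
#' Describes one named per-frame scalar: an interatomic `"distance"`, a
#' `"min_distance"` (per-frame minimum over several donor atoms to one
#' target, used for e.g. carboxylate Od1/Od2 ambiguity), or a
#' three-point `"angle"` in degrees. Atoms are given as
#' `list(chain=, resno=, elety=)`.
#'
#' @param name label of the series (e.g. `"d1"`).
#' @param kind `"distance"`, `"min_distance"` or `"angle"`.
#' @param atoms list of atom selectors: 2 for a distance, 3 (ordered
#'   a-b-c, vertex b) for an angle; ignored for `min_distance`.
#' @param donors,target for `min_distance`: list of donor atom
#'   selectors and the single target atom selector.
#' @return A `geometry_spec` list.
#' @export
geometry_spec <- function(name, kind = c("distance", "min_distance", "angle"),
                          atoms = NULL, donors = NULL, target = NULL) {
  kind <- match.arg(kind)
  if (kind == "distance" && length(atoms) != 2L) stop("distance needs 2 atoms")
  if (kind == "angle" && length(atoms) != 3L) stop("angle needs 3 atoms")
  if (kind == "min_distance" && (is.null(donors) || is.null(target)))
    stop("min_distance needs donors and target")
  structure(list(name = name, kind = kind, atoms = atoms,
                 donors = donors, target = target), class = "geometry_spec")
}

resolve_atom <- function(traj, sel, spec_name) {
  i <- atom_index(traj, sel$chain, sel$resno, sel$elety, sel$insert %||% NA)
  if (is.na(i))
    stop("geometry spec '", spec_name, "': atom ", sel$chain, ":", sel$resno,
         ":", sel$elety, " not found")
  i
}

#' Compute per-frame geometric parameter series
#'
#' Distances in angstrom; angles in degrees via the standard
#' three-point formula; `min_distance` takes the per-frame minimum over
#' the listed donors.
#'
#' @param traj `Trajectory`.
#' @param specs list of [geometry_spec()] objects.
#' @return Numeric matrix, frames x parameters, spec names as columns.
#' @export
compute_geometry_series <- function(traj, specs) {
  if (inherits(specs, "geometry_spec")) specs <- list(specs)
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, length(specs),
                dimnames = list(NULL, vapply(specs, `[[`, "", "name")))
  co <- function(i) matrix(traj$xyz[, xyz_cols(i)], ncol = 3L)
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    if (sp$kind == "distance") {
      i <- resolve_atom(traj, sp$atoms[[1L]], sp$name)
      j <- resolve_atom(traj, sp$atoms[[2L]], sp$name)
      out[, k] <- sqrt(rowSums((co(i) - co(j))^2))
    } else if (sp$kind == "min_distance") {
      tgt <- co(resolve_atom(traj, sp$target, sp$name))
      d <- sapply(sp$donors, function(s) sqrt(rowSums((co(resolve_atom(traj, s, sp$name)) - tgt)^2)))
      out[, k] <- if (is.matrix(d)) apply(d, 1L, min) else min(d)
    } else {
      a <- co(resolve_atom(traj, sp$atoms[[1L]], sp$name))
      b <- co(resolve_atom(traj, sp$atoms[[2L]], sp$name))
      cc <- co(resolve_atom(traj, sp$atoms[[3L]], sp$name))
      u <- a - b; v <- cc - b
      cosv <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
      out[, k] <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
    }
  }
  out
}

#' Catalytic-dyad geometry specs for an OGG1-like active site
#'
#' The three parameters tracking productive positioning of the
#' catalytic lysine amine and the everted damaged nucleoside:
#' `d1` = Nz(Lys)-C1'(oxodG) distance, `d2` = min over Od1/Od2(Asp) of
#' the distance to O4'(oxodG), `a1` = Nz-C1'-N9 angle.
#'
#' @param lys,asp,oxodg residue selectors `list(chain=, resno=)` for the
#'   catalytic lysine, aspartate and the damaged nucleoside.
#' @return List of three [geometry_spec()] objects.
#' @export
catalytic_dyad_specs <- function(lys, asp, oxodg) {
  at <- function(res, elety) list(chain = res$chain, resno = res$resno, elety = elety)
  list(
    geometry_spec("d1", "distance",
                  atoms = list(at(lys, "NZ"), at(oxodg, "C1'"))),
    geometry_spec("d2", "min_distance",
                  donors = list(at(asp, "OD1"), at(asp, "OD2")),
                  target = at(oxodg, "O4'")),
    geometry_spec("a1", "angle",
                  atoms = list(at(lys, "NZ"), at(oxodg, "C1'"), at(oxodg, "N9"))))
}

#' Strip bulk solvent and counter-ions from a trajectory
#'
#' Keeps the solute unchanged; a water molecule is retained iff it has
#' at least one atom within `cutoff` angstrom of the ligand in at least
#' `min_fraction` of the frames; all other waters and all counter-ions
#' are removed. The frame count is unchanged, so the operation is
#' idempotent.
#'
#' @param traj `Trajectory`.
#' @param ligand ligand selector (see [select_active_site()]).
#' @param cutoff distance cutoff, angstrom.
#' @param min_fraction minimum fraction of frames with a contact.
#' @param water_resids,ion_resids residue names identifying waters and
#'   counter-ions.
#' @return `Trajectory` with bulk solvent removed; the kept waters'
#'   residue keys are attached as attribute `"kept_waters"`.
#' @export
strip_solvent <- function(traj, ligand, cutoff = 5.0, min_fraction = 0.10,
                          water_resids = c("HOH", "WAT"),
                          ion_resids = .ion_resids_default) {
  keys <- residue_keys(traj)
  is_water <- traj$atoms$resid %in% water_resids
  is_ion <- traj$atoms$resid %in% ion_resids
  lig_idx <- ligand_atoms(traj, ligand)
  if (length(lig_idx) == 0L) stop("ligand selector matched no atoms")
  keep <- !is_water & !is_ion
  kept_waters <- character(0L)
  nf <- n_frames(traj)
  for (w in unique(keys[is_water])) {
    widx <- which(keys == w & is_water)
    hits <- 0L
    for (f in seq_len(nf)) {
      wc <- frame_coords(traj, f, widx)
      lc <- frame_coords(traj, f, lig_idx)
      d2 <- outer(rowSums(wc^2), rowSums(lc^2), `+`) - 2 * tcrossprod(wc, lc)
      if (min(d2) <= cutoff^2 + 1e-12) hits <- hits + 1L
    }
    if (hits / nf >= min_fraction) {
      keep[widx] <- TRUE
      kept_waters <- c(kept_waters, w)
    }
  }
  out <- subset_atoms(traj, which(keep))
  attr(out, "kept_waters") <- kept_waters
  out
}
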