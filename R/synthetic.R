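#' Synthetic trajectory generators
#'
#' Seeded generators that emulate the statistical structure the
#' analysis pipeline assumes, without any physics: torsion series as
#' von Mises mixtures over a hidden metastable-state Markov chain, and
#' catalytic-geometry series as Gaussian mixtures with a dense
#' "optimal" cluster that wild-type-like variants populate heavily and
#' impaired variants barely visit. Planted ground truth travels with
#' the output so recovery tests never re-derive it from generator
#' internals.
#'
#' @name synthetic
NULL

#' Torsion-trajectory variant specification
#'
#' @param id variant identifier.
#' @param means numeric matrix, hidden states x torsions (degrees),
#'   with torsion labels as column names.
#' @param kappa von Mises concentration(s): scalar or one per torsion.
#' @param trans state-switch matrix (rows sum to 1); default: stay with
#'   probability 0.99.
#' @param init initial state distribution; default uniform.
#' @param label planted truth label, `"wt-like"` or `"impaired"`.
#' @return A `torsion_variant_spec` list.
#' @export
torsion_variant_spec <- function(id, means, kappa = 20, trans = NULL,
                                 init = NULL, label = "wt-like") {
  means <- as.matrix(means)
  if (is.null(colnames(means))) colnames(means) <- paste0("t", seq_len(ncol(means)))
  k <- nrow(means)
  if (length(kappa) == 1L) kappa <- rep(kappa, ncol(means))
  stopifnot(all(kappa > 0), length(kappa) == ncol(means))
  if (is.null(trans)) {
    trans <- if (k == 1L) matrix(1, 1L, 1L)
    else diag(0.99, k) + (1 - diag(1, k)) * (0.01 / (k - 1))
  }
  trans <- as.matrix(trans)
  if (any(abs(rowSums(trans) - 1) > 1e-8) || any(trans < 0))
    stop("state-switch matrix rows must be non-negative and sum to 1")
  if (is.null(init)) init <- rep(1 / k, k)
  stopifnot(label %in% c("wt-like", "impaired"))
  structure(list(id = id, means = means, kappa = kappa, trans = trans,
                 init = init, label = label), class = "torsion_variant_spec")
}

#' Generate torsion-angle series for a set of variants
#'
#' Per frame, a hidden state is sampled from the variant's Markov
#' switch chain and each torsion is drawn from the state's von Mises
#' distribution. All values lie in (-180, 180]; the output is a pure
#' function of (specs, n_frames, seed).
#'
#' @param specs list of [torsion_variant_spec()] objects sharing
#'   torsion labels.
#' @param n_frames frames per variant (default 2500, the analysis-tail
#'   length).
#' @param seed integer seed.
#' @return Named list of frames x torsions matrices; planted labels as
#'   attribute `"planted"`.
#' @export
gen_torsion_set <- function(specs, n_frames = 2500, seed = 1) {
  if (inherits(specs, "torsion_variant_spec")) specs <- list(specs)
  labs <- colnames(specs[[1L]]$means)
  for (sp in specs)
    if (!identical(colnames(sp$means), labs))
      stop("torsion labels of spec '", sp$id, "' differ from the first spec")
  out <- with_seed(seed, lapply(specs, function(sp) {
    k <- nrow(sp$means)
    z <- integer(n_frames)
    z[1L] <- sample.int(k, 1L, prob = sp$init)
    if (n_frames > 1L) for (t in 2L:n_frames)
      z[t] <- sample.int(k, 1L, prob = sp$trans[z[t - 1L], ])
    m <- matrix(NA_real_, n_frames, ncol(sp$means), dimnames = list(NULL, labs))
    for (s in seq_len(k)) {
      idx <- which(z == s)
      if (!length(idx)) next
      for (j in seq_along(labs))
        m[idx, j] <- rvonmises(length(idx), sp$means[s, j], sp$kappa[j])
    }
    m
  }))
  names(out) <- vapply(specs, `[[`, "", "id")
  attr(out, "planted") <- setNames(vapply(specs, `[[`, "", "label"), names(out))
  out
}

#' Geometric-trajectory variant specification
#'
#' Cluster centers are rows of a k x 3 matrix over the catalytic
#' parameters (d1, d2 in angstrom; a1 in degrees); covariances may be
#' given as per-cluster 3-vectors of standard deviations (diagonal) or
#' 3 x 3 positive-definite matrices.
#'
#' @param id variant identifier.
#' @param centers k x 3 matrix of cluster centers (columns d1, d2, a1).
#' @param weights mixture weights (sum 1).
#' @param sds list (length k) of sd 3-vectors or 3 x 3 covariance
#'   matrices.
#' @param label planted truth label, `"wt-like"` or `"impaired"`.
#' @return A `geometry_variant_spec` list.
#' @export
geometry_variant_spec <- function(id, centers, weights, sds, label = "wt-like") {
  centers <- as.matrix(centers)
  if (is.null(colnames(centers))) colnames(centers) <- c("d1", "d2", "a1")
  stopifnot(ncol(centers) == 3L, nrow(centers) == length(weights),
            abs(sum(weights) - 1) < 1e-8, all(weights >= 0),
            length(sds) == nrow(centers), label %in% c("wt-like", "impaired"))
  chols <- lapply(sds, function(s) {
    v <- if (is.matrix(s)) s else diag(s^2, 3L)
    ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("covariance is not positive definite")
    chol(v)
  })
  structure(list(id = id, centers = centers, weights = weights, chols = chols,
                 label = label), class = "geometry_variant_spec")
}

#' Generate catalytic-geometry series for a set of variants
#'
#' Per frame, a mixture component is drawn by weight and the three
#' parameters from the component's Gaussian; distances are truncated to
#' stay positive and the angle is clamped to \[0, 180\] degrees. Pure
#' function of (specs, n_frames, seed).
#'
#' @param specs list of [geometry_variant_spec()] objects.
#' @param n_frames frames per variant.
#' @param seed integer seed.
#' @return Named list of frames x 3 matrices (columns d1, d2, a1);
#'   planted labels as attribute `"planted"`.
#' @export
gen_geometry_set <- function(specs, n_frames = 2500, seed = 1) {
  if (inherits(specs, "geometry_variant_spec")) specs <- list(specs)
  out <- with_seed(seed, lapply(specs, function(sp) {
    comp <- sample.int(length(sp$weights), n_frames, replace = TRUE, prob = sp$weights)
    m <- matrix(NA_real_, n_frames, 3L, dimnames = list(NULL, colnames(sp$centers)))
    for (c_ in seq_along(sp$weights)) {
      idx <- which(comp == c_)
      if (!length(idx)) next
      z <- matrix(rnorm(3L * length(idx)), ncol = 3L) %*% sp$chols[[c_]]
      m[idx, ] <- sweep(z, 2L, sp$centers[c_, ], `+`)
    }
    m[, 1L] <- pmax(m[, 1L], 1e-3)
    m[, 2L] <- pmax(m[, 2L], 1e-3)
    m[, 3L] <- pmin(pmax(m[, 3L], 0), 180)
    m
  }))
  names(out) <- vapply(specs, `[[`, "", "id")
  attr(out, "planted") <- setNames(vapply(specs, `[[`, "", "label"), names(out))
  out
}

#' Default synthetic study preset: one wild type plus twenty mutants
#'
#' Emulates the study layout: a wild type and 20 mutants, of which
#' `n_impaired` (default 3) barely populate the catalytically optimal
#' geometry cluster. Wild-type-like variants put weight 0.9 on the
#' optimal cluster (d1 = 3.1 A, d2 = 2.7 A, a1 = 155 deg; sd 0.25 A /
#' 6 deg) and 0.1 on one of two mild excursion clusters; impaired
#' variants put weight 0.95 on a remote cluster (d1 = 7.5 A, d2 = 6.0
#' A, a1 = 95 deg), more than 3 sd from the optimal center on every
#' coordinate. Small deterministic per-variant center offsets create
#' variant individuality. The impaired identities are fixed by
#' position, evenly spread over the mutant list.
#'
#' @param n_variants total number of variants including the wild type.
#' @param n_impaired number of planted impaired mutants.
#' @param wt_id label of the wild type.
#' @return List of [geometry_variant_spec()]; planted impaired ids as
#'   attribute `"impaired"`.
#' @export
synthetic_geometry_preset <- function(n_variants = 21, n_impaired = 3, wt_id = "WT") {
  stopifnot(n_variants >= 5, n_impaired >= 1, n_impaired <= n_variants - 2)
  optimal <- c(d1 = 3.1, d2 = 2.7, a1 = 155)
  excursion <- rbind(c(4.6, 3.8, 130), c(5.2, 4.4, 115))
  remote <- c(7.5, 6.0, 95)
  sd_opt <- c(0.25, 0.25, 6)
  sd_exc <- c(0.3, 0.3, 7)
  n_mut <- n_variants - 1L
  impaired_pos <- unique(round(seq(2L, n_mut - 1L, length.out = n_impaired)))
  ids <- c(wt_id, sprintf("M%02d", seq_len(n_mut)))
  specs <- vector("list", n_variants)
  for (i in seq_len(n_variants)) {
    mut_i <- i - 1L                                # 0 for WT
    jit <- c(0.05 * ((mut_i %% 5L) - 2L), 0.05 * ((mut_i %% 4L) - 1.5), 1.5 * ((mut_i %% 3L) - 1L))
    if (mut_i %in% impaired_pos) {
      specs[[i]] <- geometry_variant_spec(
        ids[i], centers = rbind(optimal, remote + jit), weights = c(0.05, 0.95),
        sds = list(sd_opt, sd_exc), label = "impaired")
    } else {
      exc <- excursion[1L + (mut_i %% 2L), ] + jit
      specs[[i]] <- geometry_variant_spec(
        ids[i], centers = rbind(optimal + jit * c(0.2, 0.2, 0.2), exc),
        weights = c(0.9, 0.1), sds = list(sd_opt, sd_exc), label = "wt-like")
    }
  }
  names(specs) <- ids
  attr(specs, "impaired") <- ids[1L + impaired_pos]
  specs
}

#' Run the trajectory-classification pipeline on per-variant series
#'
#' Convenience front end chaining feature assembly, pooled PCA, shared
#' 10 x 10 PC1-PC2 occupancy grids, the Bhattacharyya-overlap distance
#' matrix, UPGMA and branch classification.
#'
#' @param series named list of frames x variables matrices (torsion
#'   series for `mode = "dihedral"`, geometric series otherwise).
#' @param wt_id wild-type entry name.
#' @param mode feature construction mode (see [build_feature_matrix()]).
#' @param subset optional variable subset (e.g. divergent torsions).
#' @param nx,ny grid resolution.
#' @param rule classification rule (see [classify_by_branch()]).
#' @param standardize z-score geometric variables.
#' @return List: `calls` (named affected/unaffected vector), `tree`
#'   (`ClusterTree`), `distance` (N-BC matrix), `pca`, `grids`.
#' @export
classify_variant_trajectories <- function(series, wt_id = "WT",
                                          mode = c("geometric", "dihedral"),
                                          subset = NULL, nx = 10L, ny = 10L,
                                          rule = "distal_affected",
                                          standardize = TRUE) {
  mode <- match.arg(mode)
  fm <- build_feature_matrix(mode, series, subset = subset, standardize = standardize)
  pca <- fit_project_pca(fm)
  gh <- grid_histogram(pca$projections, nx = nx, ny = ny)
  dm <- bhattacharyya_distance_matrix(gh$grids)
  tree <- upgma(dm)
  calls <- classify_by_branch(tree, wt_id, rule = rule)
  list(calls = calls, tree = tree, distance = dm, pca = pca, grids = gh)
}

# ---------------------------------------------------------------------------
# Toy molecular complex with scripted internal coordinates
# ---------------------------------------------------------------------------

.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
            ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5, cb = 1.53)

# side-chain internal coordinates: atom, ref atoms, r, theta, dihedral
# ("chiK" = scripted chi, "chiK+x" = offset from it)
.sidechain_zmat <- list(
  ALA = list(),
  SER = list(list("OG", c("N", "CA", "CB"), 1.42, 110.5, "chi1")),
  VAL = list(list("CG1", c("N", "CA", "CB"), 1.53, 110.5, "chi1"),
             list("CG2", c("N", "CA", "CB"), 1.53, 110.5, "chi1+122")),
  LEU = list(list("CG", c("N", "CA", "CB"), 1.53, 114, "chi1"),
             list("CD1", c("CA", "CB", "CG"), 1.53, 110.5, "chi2"),
             list("CD2", c("CA", "CB", "CG"), 1.53, 110.5, "chi2+122")),
  ASP = list(list("CG", c("N", "CA", "CB"), 1.52, 114, "chi1"),
             list("OD1", c("CA", "CB", "CG"), 1.25, 118, "chi2"),
             list("OD2", c("CA", "CB", "CG"), 1.25, 118, "chi2+180")),
  LYS = list(list("CG", c("N", "CA", "CB"), 1.53, 114, "chi1"),
             list("CD", c("CA", "CB", "CG"), 1.53, 111, "chi2"),
             list("CE", c("CB", "CG", "CD"), 1.53, 111, "chi3"),
             list("NZ", c("CG", "CD", "CE"), 1.49, 110, "chi4")),
  ARG = list(list("CG", c("N", "CA", "CB"), 1.53, 114, "chi1"),
             list("CD", c("CA", "CB", "CG"), 1.53, 111, "chi2"),
             list("NE", c("CB", "CG", "CD"), 1.46, 112, "chi3"),
             list("CZ", c("CG", "CD", "NE"), 1.33, 124, "chi4"),
             list("NH1", c("CD", "NE", "CZ"), 1.33, 120, "chi5"),
             list("NH2", c("CD", "NE", "CZ"), 1.33, 120, "chi5+180")))

#' Build a small scripted protein-DNA-ligand complex with motion
#'
#' Constructs, by exact internal-coordinate placement, a toy complex of
#' 8 amino acids (chain A: Gly-Ala-Arg-Lys-Asp-Ser-Val-Leu), 3 purine
#' nucleotides (chain B), one damaged-nucleoside ligand residue (chain
#' C, residue name `8OG` with sugar and base heavy atoms), 4 waters and
#' 2 sodium ions, over `n_frames` models. Because atoms are placed from
#' bond lengths, angles and dihedrals, every scripted torsion is
#' recovered exactly by dihedral measurement, and water contact
#' fractions are scripted by construction (one water always near the
#' ligand, one near in 15% of frames, one in 5%, one never).
#'
#' Attributes of the returned trajectory:
#' `reference` (frame-1 `StructureModel`), `ligand` (selector `"8OG"`),
#' `active_site` (planted residue keys within 5 A of the ligand in the
#' reference frame), `scripted_torsions` (frames x labels matrix of the
#' placed dihedral values), `water_truth` (kept / removed residue keys
#' under the 5 A / 10% rule), `catalytic_specs` (the d1/d2/a1
#' [geometry_spec()] list for the toy's Lys-Asp dyad and ligand).
#'
#' @param seed integer seed (used only to jitter the positions of the
#'   far-away bulk waters and ions; the scripted content is fixed).
#' @param n_frames number of models (>= 20 recommended).
#' @return A `Trajectory` with the attributes above.
#' @export
gen_toy_complex <- function(seed = 1, n_frames = 20) {
  stopifnot(n_frames >= 2)
  aa_seq <- c("GLY", "ALA", "ARG", "LYS", "ASP", "SER", "VAL", "LEU")
  chi_fixed <- list(ALA = NULL, GLY = NULL,
                    ARG = c(-60, 60, 180, -120, 90),
                    LYS = c(NA, 180, 60, -65),      # chi1 scripted per frame
                    ASP = c(-60, -20), SER = c(60), VAL = c(175),
                    LEU = c(-60, 170))
  phi_fixed <- -120; psi_fixed <- 140
  lys_phi <- function(f) wrap_angle(-120 + 1.0 * (f - 1))
  lys_chi1 <- function(f) wrap_angle(60 + 5 * (f - 1))
  nuc_tors <- c(alpha = -60, beta = 175, gamma = 55, delta = 80,
                epsilon = -150, zeta = -75, chi = -110)
  b1_chi <- function(f) wrap_angle(-120 + 4 * (f - 1))

  atoms <- list(); coords <- list()   # coords[[atom]] = n_frames x 3
  scripted <- list()
  add_atom <- function(type, elety, resid, chain, resno, xyz_mat) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      type = type, elety = elety, resid = resid, chain = chain,
      resno = resno, insert = NA_character_,
      elesy = guess_element(elety), stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz_mat
  }
  rep_frames <- function(p) matrix(rep(as.numeric(p), each = n_frames), ncol = 3L)
  pa <- function(A, B, C, r, theta, phi) {
    # frame-wise NeRF placement; A,B,C are n_frames x 3, phi scalar/vector
    out <- matrix(NA_real_, n_frames, 3L)
    phi <- rep_len(phi, n_frames)
    for (f in seq_len(n_frames))
      out[f, ] <- place_atom(A[f, ], B[f, ], C[f, ], r, theta, phi[f])
    out
  }
  note <- function(label, phi) scripted[[label]] <<- rep_len(phi, n_frames)

  # ---- protein chain A ----------------------------------------------------
  prot <- list()  # per residue: named list of coordinate matrices
  n1 <- rep_frames(c(0, 0, 0)); ca1 <- rep_frames(c(.bb$n_ca, 0, 0))
  c1 <- pa(rep_frames(c(0, 0, -1)), n1, ca1, .bb$ca_c, .bb$ang_n_ca_c, -60)
  prot[[1L]] <- list(N = n1, CA = ca1, C = c1)
  for (i in seq_along(aa_seq)) {
    res <- aa_seq[i]
    phi_i <- if (res == "LYS") lys_phi(seq_len(n_frames)) else phi_fixed
    psi_i <- psi_fixed
    if (i > 1L) {
      pr <- prot[[i - 1L]]
      n_i <- pa(pr$N, pr$CA, pr$C, .bb$c_n, .bb$ang_ca_c_n, psi_fixed)
      note(paste0("A:", i - 1L, ":psi"), psi_fixed)
      ca_i <- pa(pr$CA, pr$C, n_i, .bb$n_ca, .bb$ang_c_n_ca, 180)
      c_i <- pa(pr$C, n_i, ca_i, .bb$ca_c, .bb$ang_n_ca_c, phi_i)
      note(paste0("A:", i, ":phi"), phi_i)
      prot[[i]] <- list(N = n_i, CA = ca_i, C = c_i)
    }
    r <- prot[[i]]
    r$O <- pa(r$N, r$CA, r$C, .bb$c_o, .bb$ang_ca_c_o, wrap_angle(psi_i + 180))
    if (res != "GLY")
      r$CB <- pa(r$C, r$N, r$CA, .bb$cb, .bb$ang_n_ca_cb, -122.5)
    chis <- chi_fixed[[res]]
    if (!is.null(chis) && length(chis)) {
      chi_vals <- as.list(chis)
      if (res == "LYS") chi_vals[[1L]] <- lys_chi1(seq_len(n_frames))
      for (entry in .sidechain_zmat[[res]]) {
        tor <- entry[[5L]]
        base <- as.integer(sub("^chi([0-9]).*$", "\\1", tor))
        off <- if (grepl("\\+", tor)) as.numeric(sub("^chi[0-9]\\+", "", tor)) else 0
        phi_v <- wrap_angle(rep_len(chi_vals[[base]], n_frames) + off)
        r[[entry[[1L]]]] <- pa(r[[entry[[2L]][1L]]], r[[entry[[2L]][2L]]],
                               r[[entry[[2L]][3L]]], entry[[3L]], entry[[4L]], phi_v)
        if (off == 0)
          note(paste0("A:", i, ":chi", base), rep_len(chi_vals[[base]], n_frames))
      }
    }
    prot[[i]] <- r
  }

  # ---- nucleic chain B (3 purines) ----------------------------------------
  nuc <- list()
  p1 <- rep_frames(c(0, 0, 0)); o5_1 <- rep_frames(c(1.60, 0, 0))
  c5_1 <- pa(rep_frames(c(0, 1, -1)), p1, o5_1, 1.44, 120, 60)
  nuc[[1L]] <- list(P = p1, `O5'` = o5_1, `C5'` = c5_1)
  for (i in 1:3) {
    r <- nuc[[i]]
    chi_i <- if (i == 1L) b1_chi(seq_len(n_frames)) else nuc_tors[["chi"]]
    r$`C4'` <- pa(r$P, r$`O5'`, r$`C5'`, 1.51, 111, nuc_tors[["beta"]])
    note(paste0("B:", i, ":beta"), nuc_tors[["beta"]])
    r$`C3'` <- pa(r$`O5'`, r$`C5'`, r$`C4'`, 1.53, 115, nuc_tors[["gamma"]])
    note(paste0("B:", i, ":gamma"), nuc_tors[["gamma"]])
    r$`O3'` <- pa(r$`C5'`, r$`C4'`, r$`C3'`, 1.42, 110, nuc_tors[["delta"]])
    note(paste0("B:", i, ":delta"), nuc_tors[["delta"]])
    r$`O4'` <- pa(r$`O5'`, r$`C5'`, r$`C4'`, 1.45, 109, wrap_angle(nuc_tors[["gamma"]] - 121))
    r$`C1'` <- pa(r$`C5'`, r$`C4'`, r$`O4'`, 1.42, 109, 100)
    r$N9 <- pa(r$`C4'`, r$`O4'`, r$`C1'`, 1.47, 108, 150)
    r$C4 <- pa(r$`O4'`, r$`C1'`, r$N9, 1.37, 126, chi_i)
    note(paste0("B:", i, ":chi"), chi_i)
    nuc[[i]] <- r
    if (i < 3L) {
      p_n <- pa(r$`C4'`, r$`C3'`, r$`O3'`, 1.60, 119, nuc_tors[["epsilon"]])
      note(paste0("B:", i, ":epsilon"), nuc_tors[["epsilon"]])
      o5_n <- pa(r$`C3'`, r$`O3'`, p_n, 1.59, 104, nuc_tors[["zeta"]])
      note(paste0("B:", i, ":zeta"), nuc_tors[["zeta"]])
      c5_n <- pa(r$`O3'`, p_n, o5_n, 1.44, 120, nuc_tors[["alpha"]])
      note(paste0("B:", i + 1L, ":alpha"), nuc_tors[["alpha"]])
      nuc[[i + 1L]] <- list(P = p_n, `O5'` = o5_n, `C5'` = c5_n)
    }
  }

  # ---- ligand (8OG nucleoside heavy atoms), fixed near the origin ---------
  lig <- list(`C1'` = c(0, 0, 0), `O4'` = c(1.41, 0, 0),
              `C2'` = c(-0.70, 1.25, 0), `C3'` = c(0.45, 2.20, 0.30),
              N9 = c(-0.76, -1.17, 0.20), C4 = c(-2.10, -1.30, 0.20),
              C8 = c(-0.20, -2.40, 0.35), O8 = c(0.90, -2.65, 0.40))
  lig_center <- colMeans(do.call(rbind, lig))

  # rigid placement of the fragments around the ligand: protein anchored by
  # the frame-1 CB of Lys4, DNA by the frame-1 C1' of residue B1
  shift_A <- c(0, 4.0, 0) - prot[[4L]]$CB[1L, ]
  shift_B <- c(-4.2, -1.0, 1.0) - nuc[[1L]]$`C1'`[1L, ]
  for (i in seq_along(prot)) prot[[i]] <- lapply(prot[[i]], function(m) sweep(m, 2L, shift_A, `+`))
  for (i in seq_along(nuc)) nuc[[i]] <- lapply(nuc[[i]], function(m) sweep(m, 2L, shift_B, `+`))

  aa_order <- c("N", "CA", "C", "O", "CB", "CG", "CG1", "CG2", "CD", "CD1",
                "CD2", "NE", "CE", "CZ", "NZ", "NH1", "NH2", "OD1", "OD2", "OG")
  for (i in seq_along(prot)) {
    for (el in intersect(aa_order, names(prot[[i]])))
      add_atom("ATOM", el, aa_seq[i], "A", i, prot[[i]][[el]])
  }
  nuc_order <- c("P", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C1'", "N9", "C4")
  for (i in seq_along(nuc)) {
    for (el in intersect(nuc_order, names(nuc[[i]])))
      add_atom("ATOM", el, "DG", "B", i, nuc[[i]][[el]])
  }
  for (el in names(lig))
    add_atom("HETATM", el, "8OG", "C", 1L, rep_frames(lig[[el]]))

  # ---- waters and ions ----------------------------------------------------
  far <- with_seed(seed, matrix(runif(6L * 3L, 18, 25), ncol = 3L))
  n_near_w2 <- max(1L, round(0.15 * n_frames))
  n_near_w3 <- max(1L, floor(0.05 * n_frames + 1e-9))
  w_near <- function(offset) lig_center + offset
  w2 <- matrix(rep(far[2L, ], each = n_frames), ncol = 3L)
  w2[seq_len(n_near_w2), ] <- matrix(rep(w_near(c(0, 3.5, 0)), each = n_near_w2), ncol = 3L)
  w3 <- matrix(rep(far[3L, ], each = n_frames), ncol = 3L)
  w3[seq_len(n_near_w3), ] <- matrix(rep(w_near(c(0, -3.5, 0.5)), each = n_near_w3), ncol = 3L)
  add_atom("HETATM", "O", "HOH", "W", 1L, rep_frames(w_near(c(3.2, 0.5, 0.5))))
  add_atom("HETATM", "O", "HOH", "W", 2L, w2)
  add_atom("HETATM", "O", "HOH", "W", 3L, w3)
  add_atom("HETATM", "O", "HOH", "W", 4L, rep_frames(far[4L, ]))
  add_atom("HETATM", "NA", "NA+", "I", 1L, rep_frames(far[5L, ]))
  add_atom("HETATM", "NA", "NA+", "I", 2L, rep_frames(far[6L, ]))

  atom_tab <- do.call(rbind, atoms)
  atom_tab$eleno <- seq_len(nrow(atom_tab))
  xyz <- matrix(NA_real_, n_frames, 3L * nrow(atom_tab))
  for (k in seq_along(coords)) xyz[, xyz_cols(k)] <- coords[[k]]
  traj <- trajectory(atom_tab, xyz, timestep_ps = 8)

  # planted truth ---------------------------------------------------------
  keys <- residue_keys(traj)
  lig_idx <- which(atom_tab$resid == "8OG")
  planted <- character(0L)
  for (kk in setdiff(unique(keys), c(keys[lig_idx],
                                     unique(keys[atom_tab$resid %in% c("HOH", "NA+")])))) {
    idx <- which(keys == kk)
    d2 <- outer(rowSums(frame_coords(traj, 1L, idx)^2),
                rowSums(frame_coords(traj, 1L, lig_idx)^2), `+`) -
      2 * tcrossprod(frame_coords(traj, 1L, idx), frame_coords(traj, 1L, lig_idx))
    if (min(d2) <= 25) planted <- c(planted, kk)
  }
  sm <- structure_model(atom_tab, xyz[1L, ])
  st <- do.call(cbind, scripted)
  attr(traj, "reference") <- sm
  attr(traj, "ligand") <- "8OG"
  attr(traj, "active_site") <- sort(planted)
  attr(traj, "scripted_torsions") <- st
  attr(traj, "water_truth") <- list(
    kept = c("W:1", if (n_near_w2 / n_frames >= 0.10) "W:2"),
    removed = c(if (n_near_w2 / n_frames < 0.10) "W:2", "W:3", "W:4"))
  attr(traj, "catalytic_specs") <- catalytic_dyad_specs(
    lys = list(chain = "A", resno = 4L), asp = list(chain = "A", resno = 5L),
    oxodg = list(chain = "C", resno = 1L))
  traj
}
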