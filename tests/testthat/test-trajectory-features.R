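toy <- gen_toy_complex(seed = 1, n_frames = 20)

test_that("single- and multi-model PDB files round-trip through read_models", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(attr(toy, "reference"), f1)
  sm <- read_models(f1)
  expect_s3_class(sm, "StructureModel")
  expect_equal(nrow(sm$atoms), nrow(toy$atoms))
  expect_equal(as.numeric(sm$xyz), as.numeric(toy$xyz[1, ]), tolerance = 1e-3)

  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy, f2)
  tr <- read_models(f2)
  expect_s3_class(tr, "Trajectory")
  expect_equal(n_frames(tr), 20L)
  expect_equal(residue_keys(tr), residue_keys(toy))
})

test_that("a divergent atom table across models is a format error naming the model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy, f)
  lines <- readLines(f)
  starts <- grep("^MODEL", lines)
  i <- starts[3] + 5        # an ATOM record inside model 3
  substr(lines[i], 13, 16) <- " XX "
  writeLines(lines, f)
  expect_error(read_models(f), "model 3")
})

test_that("active-site selection applies the distance cutoff exactly", {
  mod <- structure_model(
    data.frame(type = c("HETATM", "ATOM", "ATOM"),
               elety = c("C1", "CA", "CA"), resid = c("LIG", "ALA", "ALA"),
               chain = c("L", "A", "A"), resno = c(1L, 1L, 2L),
               insert = NA_character_, elesy = "C"),
    c(0, 0, 0, 4.9, 0, 0, 5.1, 0, 0))
  expect_equal(select_active_site(mod, "LIG", 5.0), "A:1")
  expect_equal(select_active_site(mod, "LIG", 0), character(0))
  expect_error(select_active_site(mod, "XXX", 5.0), "matched no atoms")
})

test_that("active-site membership is monotone in the cutoff", {
  sets <- lapply(c(3, 4, 5, 7), function(ct) select_active_site(toy, "8OG", ct))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  expect_equal(select_active_site(toy, "8OG", 5.0), attr(toy, "active_site"))
})

test_that("torsion enumeration follows the standard residue templates", {
  defs <- suppressMessages(enumerate_torsions(toy))
  per_res <- function(key) sort(defs$torsion[grepl(paste0("^", key, ":"), defs$label)])
  # mid-chain Ala: phi and psi only
  expect_equal(per_res("A:2"), c("phi", "psi"))
  # mid-chain Arg: phi, psi, chi1..chi5
  expect_equal(per_res("A:3"), sort(c("phi", "psi", paste0("chi", 1:5))))
  # N-terminal Gly: no preceding C, so phi is dropped
  expect_false("A:1:phi" %in% defs$label)
  expect_true("A:1:psi" %in% defs$label)
  # nucleotide without a predecessor has no alpha; with one, it does
  expect_false("B:1:alpha" %in% defs$label)
  expect_true(all(c("B:2:alpha", "B:2:zeta", "B:1:chi") %in% defs$label))
})

test_that("dihedrals follow the IUPAC sign convention", {
  m <- function(...) matrix(c(...), 1)
  dd <- function(p1, p2, p3, p4) mdvar:::dihedral_deg(m(p1), m(p2), m(p3), m(p4))
  # coplanar cis -> 0; trans -> 180
  expect_equal(dd(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)
  expect_equal(dd(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)), 180)
  # staggered butane-like +/-60 against the independent two-plane oracle
  for (phi in c(60, -60, 135, -170)) {
    d <- as.vector(mdvar:::place_atom(c(-1, 1, 0), c(0, 0, 0), c(1.5, 0, 0), 1.5, 110, phi))
    expect_equal(dd(c(-1, 1, 0), c(0, 0, 0), c(1.5, 0, 0), d), phi, tolerance = 1e-9)
    expect_equal(dihedral_oracle(c(-1, 1, 0), c(0, 0, 0), c(1.5, 0, 0), d), phi,
                 tolerance = 1e-9)
  }
  # collinear central bond is undefined
  expect_true(is.na(dd(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))))
})

test_that("torsions are invariant under rigid motion and reverse-symmetric", {
  defs <- suppressMessages(enumerate_torsions(toy))
  base <- suppressMessages(compute_dihedral_series(toy, defs))
  set.seed(3)
  moved <- rigid_move(toy, rotation3(0.4, -1.1, 2.2), c(15, -8, 3))
  after <- suppressMessages(compute_dihedral_series(moved, defs))
  expect_lt(max(abs(circular_diff(after, base))), 1e-8)
  # theta(4,3,2,1) = theta(1,2,3,4)
  rdefs <- defs
  rdefs[, c("a1", "a2", "a3", "a4")] <- defs[, c("a4", "a3", "a2", "a1")]
  rev_ts <- suppressMessages(compute_dihedral_series(toy, rdefs))
  expect_lt(max(abs(circular_diff(rev_ts, base))), 1e-8)
})

test_that("scripted torsions of the toy complex are measured back exactly", {
  st <- attr(toy, "scripted_torsions")
  defs <- suppressMessages(enumerate_torsions(toy))
  ts <- suppressMessages(compute_dihedral_series(toy, defs))
  common <- intersect(colnames(ts), colnames(st))
  expect_gt(length(common), 40)
  expect_lt(max(abs(circular_diff(ts[, common], st[, common]))), 1e-6)
})

test_that("geometric parameters compute distances, minima and angles", {
  mod <- structure_model(
    data.frame(type = "ATOM", elety = c("NZ", "C1'", "N9", "O4'", "OD1", "OD2"),
               resid = c("LYS", "8OG", "8OG", "8OG", "ASP", "ASP"),
               chain = c("A", "C", "C", "C", "A", "A"),
               resno = c(1L, 9L, 9L, 9L, 2L, 2L), insert = NA_character_,
               elesy = c("N", "C", "N", "O", "O", "O")),
    c(0, 0, 3,   0, 0, 0,   2, 0, 0,   0, 1, 0,   0, 3.5, 0,   0, 6, 0))
  specs <- catalytic_dyad_specs(lys = list(chain = "A", resno = 1),
                                asp = list(chain = "A", resno = 2),
                                oxodg = list(chain = "C", resno = 9))
  g <- compute_geometry_series(mod, specs)
  expect_equal(unname(g[1, "d1"]), 3.0)     # straight-line distance NZ-C1'
  expect_equal(unname(g[1, "d2"]), 2.5)     # min over the two carboxylate oxygens
  expect_equal(unname(g[1, "a1"]), 90)      # right angle at C1'
  bad <- geometry_spec("dx", "distance",
                       atoms = list(list(chain = "A", resno = 1, elety = "XX"),
                                    list(chain = "C", resno = 9, elety = "C1'")))
  expect_error(compute_geometry_series(mod, list(bad)), "dx")
})

test_that("solvent stripping keeps waters by contact fraction", {
  stripped <- strip_solvent(toy, "8OG", cutoff = 5.0, min_fraction = 0.10)
  truth <- attr(toy, "water_truth")
  expect_setequal(attr(stripped, "kept_waters"), truth$kept)
  left <- unique(residue_keys(stripped)[stripped$atoms$resid == "HOH"])
  expect_setequal(left, truth$kept)
  # ions are gone, solute intact, frame count unchanged
  expect_false(any(stripped$atoms$resid == "NA+"))
  expect_equal(n_frames(stripped), n_frames(toy))
  expect_equal(sum(stripped$atoms$resid %in% c("8OG", "DG")),
               sum(toy$atoms$resid %in% c("8OG", "DG")))
  # idempotent
  again <- strip_solvent(stripped, "8OG", cutoff = 5.0, min_fraction = 0.10)
  expect_identical(again$atoms, stripped$atoms)
  expect_identical(again$xyz, stripped$xyz)
  # min_fraction 0 keeps every water
  all_w <- strip_solvent(toy, "8OG", min_fraction = 0)
  expect_equal(sum(all_w$atoms$resid == "HOH"), sum(toy$atoms$resid == "HOH"))
})

test_that("trajectory tails select the final analysis window", {
  tl <- trajectory_tail(toy, 5)
  expect_equal(n_frames(tl), 5L)
  expect_equal(tl$xyz[1, ], toy$xyz[16, ])
})
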