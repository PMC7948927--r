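test_that("protein-change strings parse in one- and three-letter notation", {
  expect_equal(parse_protein_change("p.I145M"),
               list(aa_ref = "I", aa_pos = 145L, aa_alt = "M"))
  expect_equal(parse_protein_change("p.Arg229Gln"),
               list(aa_ref = "R", aa_pos = 229L, aa_alt = "Q"))
  expect_equal(parse_protein_change("R131G"),
               list(aa_ref = "R", aa_pos = 131L, aa_alt = "G"))
})

test_that("non-missense and malformed changes are rejected with the reason", {
  expect_error(parse_protein_change("p.K249K"), "reference equals alternate")
  expect_error(parse_protein_change("p.R229*"), "nonsense")
  expect_error(parse_protein_change("p.G12fs"), "frameshift")
  expect_error(parse_protein_change("p.145M"), "malformed")
  expect_error(parse_protein_change("p.B7Q"), "unknown residue")
})

test_that("variant tables load, deduplicate and skip non-missense rows", {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  changes <- sprintf("p.%s%d%s", aa[(0:38 %% 20) + 1], 5 + (0:38) * 7,
                     aa[(3:41 %% 20) + 1])
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = "OGG1", protein_change = changes),
              f, sep = "\t", row.names = FALSE, quote = FALSE)
  recs <- load_variant_table(f, gene = "OGG1")
  expect_equal(nrow(recs), 39L)

  # duplicate row collapses; nonsense row is skipped with a message
  write.table(data.frame(gene = "OGG1",
                         protein_change = c("p.I145M", "p.I145M", "p.G202C", "p.R229*")),
              f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_message(recs <- load_variant_table(f, gene = "OGG1"), "1 non-missense")
  expect_equal(nrow(recs), 2L)
  expect_error(load_variant_table(f, gene = "OGG1", change_col = "nope"), "not found")
})

test_that("variants map through a global alignment with identity checks", {
  tgt <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  struct_seq <- data.frame(chain = "A", resno = seq_len(nchar(tgt)),
                           insert = NA, aa = strsplit(tgt, "")[[1]])
  # identical sequences: identity on positions
  m <- align_sequences(tgt, tgt)
  v <- list(aa_ref = substr(tgt, 7, 7), aa_pos = 7L, aa_alt = "W")
  expect_equal(map_variant(v, m, struct_seq)$resno, 7L)

  # 10-residue N-terminal extension on the reference: ref 15 -> structure 5
  ref <- paste0("GSSGSSGSSG", tgt)
  m2 <- align_sequences(ref, tgt)
  v2 <- list(aa_ref = substr(ref, 15, 15), aa_pos = 15L, aa_alt = "A")
  expect_equal(map_variant(v2, m2, struct_seq)$resno, 5L)

  # position aligned to a gap (segment absent from the structure)
  ref3 <- paste0(substr(tgt, 1, 10), "WWWWWWWW", substr(tgt, 11, nchar(tgt)))
  m3 <- align_sequences(ref3, tgt)
  v3 <- list(aa_ref = "W", aa_pos = 14L, aa_alt = "A")
  expect_equal(map_variant(v3, m3, struct_seq), "unmapped")

  # identity mismatch guards against numbering drift
  v4 <- list(aa_ref = "P", aa_pos = 7L, aa_alt = "W")
  expect_error(map_variant(v4, m, struct_seq), "reference mismatch")
})

test_that("variant sampling is uniform, seeded and reproducible", {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  recs <- data.frame(gene = "G", aa_ref = aa[(0:38 %% 20) + 1],
                     aa_pos = 5 + (0:38) * 7, aa_alt = aa[(3:41 %% 20) + 1])
  s1 <- sample_variants(recs, 20, seed = 1)
  s2 <- sample_variants(recs, 20, seed = 1)
  expect_equal(s1, s2)
  expect_equal(nrow(unique(s1)), 20L)
  s3 <- sample_variants(recs, 20, seed = 2)
  expect_false(identical(s1$aa_pos, s3$aa_pos))
  # input order does not matter
  s4 <- sample_variants(recs[rev(seq_len(nrow(recs))), ], 20, seed = 1)
  expect_equal(s1, s4)
  # whole set comes back for k = n
  expect_setequal(sample_variants(recs, nrow(recs), seed = 9)$aa_pos, recs$aa_pos)
  expect_error(sample_variants(recs, 40, seed = 1), "exceeds")
})

test_that("point mutations truncate side chains at C-beta", {
  mod <- tiny_model(list(
    list(resid = "ALA", atoms = c("N", "CA", "C", "O", "CB")),
    list(resid = "ARG", atoms = c("N", "CA", "C", "O", "CB", "CG", "CD",
                                  "NE", "CZ", "NH1", "NH2")),
    list(resid = "ILE", atoms = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"))))
  # Ala -> Val: Ala already ends at CB, only the name changes
  m1 <- mutate_structure(mod, list(chain = "A", resno = 1), "V")
  expect_equal(heavy_atoms(m1, "A:1"), c("N", "CA", "C", "O", "CB"))
  expect_equal(unique(m1$atoms$resid[residue_keys(m1) == "A:1"]), "VAL")
  # Arg -> Lys: 6 side-chain atoms beyond CB removed
  m2 <- mutate_structure(mod, list(chain = "A", resno = 2), "K")
  expect_equal(heavy_atoms(m2, "A:2"), c("N", "CA", "C", "O", "CB"))
  # Ile -> Gly: CB goes too
  m3 <- mutate_structure(mod, list(chain = "A", resno = 3), "G")
  expect_equal(heavy_atoms(m3, "A:3"), c("N", "CA", "C", "O"))
  # untouched residues are bit-identical, including coordinates
  keep <- residue_keys(m2) != "A:2"
  orig <- residue_keys(mod) != "A:2"
  expect_identical(m2$xyz[1, mdvar:::xyz_cols(which(keep))],
                   mod$xyz[1, mdvar:::xyz_cols(which(orig))])
  expect_error(mutate_structure(mod, list(chain = "A", resno = 9), "V"), "no residue")
})

test_that("mutation round trip leaves backbone coordinates bit-identical", {
  mod <- tiny_model(list(
    list(resid = "LYS", atoms = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"))))
  mut <- mutate_structure(mod, list(chain = "A", resno = 1), "A")
  bb <- c("N", "CA", "C", "O", "CB")
  i_new <- which(mut$atoms$elety %in% bb)
  i_old <- which(mod$atoms$elety %in% bb)
  expect_identical(mut$xyz[1, mdvar:::xyz_cols(i_new)], mod$xyz[1, mdvar:::xyz_cols(i_old)])
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(11)
  a <- matrix(rnorm(30), ncol = 3)
  # identity
  fit0 <- kabsch_superpose(a, a)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  # known 90-degree rotation about z plus translation
  r90 <- rotation3(0, 0, pi / 2)
  b <- a %*% t(r90) + matrix(c(3, -2, 7), nrow(a), 3, byrow = TRUE)
  fit <- kabsch_superpose(a, b)
  expect_equal(fit$rotation, r90, tolerance = 1e-8)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(sweep(a %*% t(fit$rotation), 2, fit$translation, `+`), b,
               tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("Kabsch RMSD matches an independent numeric minimization", {
  tri_a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  tri_b <- tri_a
  tri_b[2, ] <- tri_b[2, ] + c(0.3, 0, 0)   # one vertex perturbed by 0.3 A
  fit <- kabsch_superpose(tri_a, tri_b)
  # oracle: direct optimization over rotation angles + translation
  obj <- function(p) {
    r <- rotation3(p[1], p[2], p[3])
    moved <- sweep(tri_a %*% t(r), 2, p[4:6], `+`)
    sqrt(mean(rowSums((moved - tri_b)^2)))
  }
  best <- optim(rep(0, 6), obj, method = "BFGS")$value
  expect_equal(fit$rmsd, best, tolerance = 1e-5)
})

test_that("Kabsch RMSD is invariant under rigid pre-transformation", {
  set.seed(5)
  a <- matrix(rnorm(24), ncol = 3)
  b <- a + matrix(rnorm(24, sd = 0.2), ncol = 3)
  base <- kabsch_superpose(a, b)$rmsd
  for (i in 1:5) {
    r <- rotation3(runif(1, -pi, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    sh <- rnorm(3, sd = 10)
    a2 <- sweep(a %*% t(r), 2, sh, `+`)
    expect_equal(kabsch_superpose(a2, b)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("variant model emission writes PDBs and a manifest", {
  tgt <- "MKTAYIAKQR"
  mod <- tiny_model(lapply(strsplit(tgt, "")[[1]], function(a1)
    list(resid = mdvar:::.aa1[[a1]], atoms = c("N", "CA", "C", "O", "CB"))))
  struct_seq <- structure_sequence(mod)
  m <- align_sequences(tgt, attr(struct_seq, "sequence"))
  recs <- data.frame(gene = "TOY", aa_ref = c("T", "Y"), aa_pos = c(3L, 5L),
                     aa_alt = c("M", "F"))
  out <- withr::local_tempdir()
  man <- write_variant_models(mod, recs, m, struct_seq, out, gene = "TOY", seed = 7)
  expect_true(file.exists(file.path(out, "TOY_T3M.pdb")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_equal(sort(names(man$mapped)), c("T3M", "Y5F"))
  reread <- read_models(file.path(out, "TOY_T3M.pdb"))
  expect_equal(unique(reread$atoms$resid[reread$atoms$resno == 3]), "MET")
})
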