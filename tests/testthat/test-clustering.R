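test_that("grid histograms bin every point exactly once on pooled bounds", {
  proj <- data.frame(variant = factor(rep("A", 4)),
                     PC1 = c(0, 10, 0, 10), PC2 = c(0, 0, 5, 5))
  gh <- grid_histogram(proj, nx = 10, ny = 10)
  g <- gh$grids$A
  expect_equal(sum(g), 4)
  expect_equal(sum(g > 0), 4)      # four distinct corner bins
  expect_equal(g[1, 1] + g[10, 1] + g[1, 10] + g[10, 10], 4L)

  # all points identical: a degenerate axis is expanded and one bin holds N
  proj2 <- data.frame(variant = factor(rep("A", 7)), PC1 = 1, PC2 = 2)
  w <- capture_warnings(gh2 <- grid_histogram(proj2))
  expect_length(w, 2)                    # one degenerate axis warning per axis
  expect_match(w, "degenerate", all = TRUE)
  expect_equal(max(gh2$grids$A), 7L)
  expect_equal(sum(gh2$grids$A), 7L)

  # uniform points: totals preserved, counts near expectation
  set.seed(5)
  proj3 <- data.frame(variant = factor(rep("A", 2500)),
                      PC1 = runif(2500), PC2 = runif(2500))
  g3 <- grid_histogram(proj3)$grids$A
  expect_equal(sum(g3), 2500)
  expect_true(all(g3 > 25 - 5 * sqrt(25) & g3 < 25 + 5 * sqrt(25)))
})

test_that("Bhattacharyya distances follow the overlap identities", {
  gA <- count_grid(matrix(c(4, 0), 1)); gB <- count_grid(matrix(c(1, 3), 1))
  d <- bhattacharyya_distance_matrix(list(A = gA, B = gB, C = gA))
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["A", "C"], 0)                    # identical grids: BC = N
  expect_equal(d["A", "B"], 2)                    # sqrt(4*1) + sqrt(0*3) = 2
  expect_equal(d, t(d))
  gD <- count_grid(matrix(c(0, 4), 1))
  d2 <- bhattacharyya_distance_matrix(list(A = gA, D = gD))
  expect_equal(d2["A", "D"], 4)                   # disjoint supports: distance N
  expect_error(bhattacharyya_distance_matrix(list(A = gA, E = count_grid(matrix(c(2, 3), 1)))),
               "unequal")
})

test_that("0 <= BC <= N on random count grids (Cauchy-Schwarz)", {
  set.seed(17)
  for (i in 1:25) {
    n <- 50
    g1 <- count_grid(matrix(rmultinom(1, n, runif(25)), 5))
    g2 <- count_grid(matrix(rmultinom(1, n, runif(25)), 5))
    d <- bhattacharyya_distance_matrix(list(A = g1, B = g2))
    expect_gte(d["A", "B"], 0)
    expect_lte(d["A", "B"], n)
  }
})

test_that("UPGMA reproduces the textbook three-leaf tree", {
  m <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(m)
  expect_equal(tr$height, c(2, 6))
  nwk <- write_newick(tr)
  ph <- ape::read.tree(text = nwk)
  cph <- as.matrix(stats::cophenetic(ph))
  expect_equal(cph["A", "B"], 2)
  expect_equal(cph["A", "C"], 6)
  expect_equal(cph["B", "C"], 6)
  # two leaves: (A:2,B:2)
  m2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  ph2 <- ape::read.tree(text = write_newick(upgma(m2)))
  expect_equal(sort(ph2$edge.length), c(2, 2))
})

test_that("UPGMA trees are ultrametric and exact on ultrametric input", {
  set.seed(23)
  dm <- random_dm(7)
  tr <- upgma(dm)
  # equal root-to-leaf path lengths
  cph <- cophenetic_matrix(tr)
  expect_equal(max(abs(cph - t(cph))), 0)
  ph <- ape::read.tree(text = write_newick(tr))
  depth <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_lt(diff(range(depth)), 1e-8)
  # a cophenetic (ultrametric) matrix is reproduced exactly
  tr2 <- upgma(cph)
  expect_equal(cophenetic_matrix(tr2)[rownames(cph), colnames(cph)], cph,
               tolerance = 1e-8)
})

test_that("UPGMA matches independent average-linkage clustering", {
  set.seed(29)
  for (i in 1:20) {
    dm <- random_dm(sample(3:6, 1))
    tr <- upgma(dm)
    hc <- stats::hclust(as.dist(dm), method = "average")
    expect_equal(sort(tr$height), sort(hc$height), tolerance = 1e-10)
    labs <- rownames(dm)
    expect_equal(cophenetic_matrix(tr)[labs, labs],
                 as.matrix(stats::cophenetic(hc))[labs, labs], tolerance = 1e-10)
  }
})

test_that("UPGMA output is invariant under label permutation", {
  set.seed(37)
  dm <- random_dm(6)
  perm <- sample(6)
  tr1 <- upgma(dm)
  tr2 <- upgma(dm[perm, perm])
  labs <- rownames(dm)
  expect_equal(cophenetic_matrix(tr1)[labs, labs],
               cophenetic_matrix(tr2)[labs, labs], tolerance = 1e-10)
})

test_that("invalid distance matrices are rejected", {
  dm <- random_dm(4)
  dm[2, 3] <- dm[3, 2] <- NA
  expect_error(upgma(dm), "NA or negative")
  dm2 <- random_dm(4); dm2[1, 2] <- -1; dm2[2, 1] <- -1
  expect_error(upgma(dm2), "NA or negative")
  expect_error(upgma(random_dm(1)), "at least 2")
})

test_that("branch classification splits at the three-branch point", {
  # non-ultrametric imported tree: C and D are farthest from WT
  ph <- ape::read.tree(text = "((WT:1,A:1):1,(B:1.2,(C:3,D:3):2):1);")
  calls <- classify_by_branch(ph, "WT", rule = "distal_affected")
  expect_equal(calls[c("C", "D")], c(C = "affected", D = "affected"))
  expect_equal(calls[c("A", "B")], c(A = "unaffected", B = "unaffected"))
  expect_false("WT" %in% names(calls))
  calls2 <- classify_by_branch(ph, "WT", rule = "proximal_unaffected")
  expect_equal(unname(calls2[c("A", "B", "C", "D")]),
               c("unaffected", "affected", "affected", "affected"))
})

test_that("on ultrametric trees tied far branches pool into the distal set", {
  # WT+A tight, B intermediate, C+D far: root separates {WT,A,B} from {C,D}
  labs <- c("WT", "A", "B", "C", "D")
  dm <- matrix(10, 5, 5, dimnames = list(labs, labs))
  dm[1:3, 1:3] <- 6; dm["WT", "A"] <- dm["A", "WT"] <- 1
  dm["C", "D"] <- dm["D", "C"] <- 2
  diag(dm) <- 0
  tr <- upgma(dm)
  calls <- classify_by_branch(tr, "WT", rule = "distal_affected")
  expect_equal(sort(names(calls)[calls == "affected"]), c("C", "D"))
  br <- attr(calls, "branches")
  expect_setequal(br$wt_branch, c("WT", "A", "B"))
  # proximal rule: only the WT-side branch is unaffected
  calls2 <- classify_by_branch(tr, "WT", rule = "proximal_unaffected")
  expect_equal(sort(names(calls2)[calls2 == "unaffected"]), c("A", "B"))
})

test_that("a single-leaf far subtree degenerates with a warning", {
  labs <- c("WT", "A", "B", "X")
  dm <- matrix(2, 4, 4, dimnames = list(labs, labs))
  dm["X", ] <- dm[, "X"] <- 20; diag(dm) <- 0
  tr <- upgma(dm)
  expect_warning(calls <- classify_by_branch(tr, "WT"), "single leaf")
  expect_equal(unname(calls["X"]), "affected")
  expect_equal(sort(names(calls)[calls == "unaffected"]), c("A", "B"))
})

test_that("newick export round-trips through a standard reader", {
  set.seed(41)
  dm <- random_dm(5)
  tr <- upgma(dm)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, file = f)
  ph <- ape::read.tree(f)
  expect_setequal(ph$tip.label, rownames(dm))
  expect_equal(as.matrix(stats::cophenetic(ph))[rownames(dm), rownames(dm)],
               cophenetic_matrix(tr)[rownames(dm), rownames(dm)], tolerance = 1e-6)
})
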