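#' Occupancy histograms on a shared PC1-PC2 grid
#'
#' Partitions the PC1 vs PC2 plane into an `nx` x `ny` equidistant grid
#' whose bounds are the pooled min/max over all variants (shared bins
#' are required for the overlap coefficient to be meaningful). Bins are
#' half-open with the top/right edge closed, so every point is binned
#' exactly once.
#'
#' @param projections data frame with columns `variant`, `PC1`, `PC2`
#'   (e.g. `fit_project_pca(...)$projections`).
#' @param nx,ny grid resolution (default 10 x 10).
#' @return List with `spec` (grid bounds and resolution) and `grids`, a
#'   named list of `nx` x `ny` integer count matrices (one per variant,
#'   total count as attribute `"N"`).
#' @export
grid_histogram <- function(projections, nx = 10L, ny = 10L) {
  stopifnot(nx >= 1L, ny >= 1L,
            all(c("variant", "PC1", "PC2") %in% names(projections)))
  x <- projections$PC1; y <- projections$PC2
  bounds <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi <= lo) {
      warning("degenerate grid axis (max == min); expanding by epsilon")
      eps <- max(abs(lo), 1) * 1e-9
      lo <- lo - eps; hi <- hi + eps
    }
    c(lo, hi)
  }
  bx <- bounds(x); by <- bounds(y)
  ix <- pmin(nx, floor((x - bx[1L]) / (bx[2L] - bx[1L]) * nx) + 1L)
  iy <- pmin(ny, floor((y - by[1L]) / (by[2L] - by[1L]) * ny) + 1L)
  spec <- list(x_min = bx[1L], x_max = bx[2L], y_min = by[1L], y_max = by[2L],
               nx = as.integer(nx), ny = as.integer(ny))
  grids <- lapply(split(seq_along(x), projections$variant), function(idx) {
    g <- matrix(0L, nx, ny)
    t <- table(factor(ix[idx], levels = seq_len(nx)),
               factor(iy[idx], levels = seq_len(ny)))
    g[] <- as.integer(t)
    attr(g, "N") <- length(idx)
    g
  })
  list(spec = spec, grids = grids)
}

#' Bhattacharyya-overlap distance matrix between trajectories
#'
#' For occupancy counts p, q on a shared grid the Bhattacharyya
#' coefficient is `BC = sum_i sqrt(p_i * q_i)`; with equal totals N per
#' trajectory, `0 <= BC <= N` (Cauchy-Schwarz) and `N - BC` serves as
#' the inter-trajectory distance (0 for identical histograms, N for
#' disjoint supports). Counts, not frequencies, are used, so equal N
#' across trajectories is enforced. `N - BC` is not a metric (no
#' triangle inequality); it is used only as UPGMA input.
#'
#' @param grids named list of count matrices (see [grid_histogram()]),
#'   or the full result of [grid_histogram()].
#' @return Symmetric `DistanceMatrix` (base matrix with dimnames, zero
#'   diagonal, attribute `"N"`).
#' @export
bhattacharyya_distance_matrix <- function(grids) {
  if (!is.null(grids$grids)) grids <- grids$grids
  stopifnot(length(grids) >= 2L, !is.null(names(grids)))
  n_tot <- vapply(grids, function(g) attr(g, "N") %||% sum(g), numeric(1L))
  if (length(unique(n_tot)) != 1L)
    stop("unequal point totals across trajectories: ",
         paste(unique(n_tot), collapse = ", "))
  n <- length(grids); N <- n_tot[[1L]]
  d <- matrix(0, n, n, dimnames = list(names(grids), names(grids)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    bc <- sum(sqrt(as.numeric(grids[[i]]) * as.numeric(grids[[j]])))
    d[i, j] <- d[j, i] <- N - bc
  }
  attr(d, "N") <- N
  d
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the distance
#' between clusters is the unweighted arithmetic mean over all original
#' cross pairs. The merge height of a node is half the merge distance,
#' so the tree is ultrametric (equal root-to-leaf path lengths). Ties
#' are broken lexicographically on the smallest member label of each
#' cluster, for determinism.
#'
#' @param dm symmetric distance matrix with dimnames (NA/negative
#'   entries are rejected).
#' @return A `ClusterTree`: list with `labels`, `merge` (hclust-style:
#'   negative = leaf index, positive = earlier merge row), `height`
#'   (full merge distances; the ultrametric node heights are
#'   `height/2`), and the input `dm`.
#' @export
upgma <- function(dm) {
  dm <- as.matrix(dm)
  labels <- rownames(dm) %||% paste0("L", seq_len(nrow(dm)))
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 labels")
  if (any(is.na(dm)) || any(dm < 0)) stop("distance matrix has NA or negative entries")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  d <- dm; dimnames(d) <- NULL
  active <- seq_len(n)                 # indices into cluster bookkeeping
  members <- as.list(seq_len(n))       # leaf ids per cluster
  size <- rep(1L, n)
  node <- -seq_len(n)                  # hclust code of each cluster
  rep_lab <- labels                    # lexicographic representative
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (a in seq_len(k - 1L)) for (b in seq.int(a + 1L, k)) {
      ia <- active[a]; ib <- active[b]
      dv <- d[ia, ib]
      key <- sort(c(rep_lab[ia], rep_lab[ib]))
      better <- dv < best_d - 1e-12 ||
        (abs(dv - best_d) <= 1e-12 &&
           (key[1L] < best_key[1L] ||
              (key[1L] == best_key[1L] && key[2L] < best_key[2L])))
      if (is.null(best) || better) { best <- c(ia, ib); best_d <- dv; best_key <- key }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- best_d
    for (kk in setdiff(active, c(i, j)))
      d[i, kk] <- d[kk, i] <- (size[i] * d[i, kk] + size[j] * d[j, kk]) / (size[i] + size[j])
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- size[i] + size[j]
    node[i] <- step
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    active <- setdiff(active, j)
  }
  structure(list(labels = labels, merge = merge, height = height, dm = dm),
            class = "ClusterTree")
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat("<ClusterTree> ", length(x$labels), " leaves, root height ",
      signif(max(x$height) / 2, 6), "\n", sep = "")
  invisible(x)
}

#' Convert a ClusterTree to an hclust object
#'
#' @param x a `ClusterTree`.
#' @param ... unused.
#' @return A `stats::hclust` object (heights = full merge distances, as
#'   is conventional for hclust; cophenetic distances from it equal the
#'   tree path distances).
#' @export
as.hclust.ClusterTree <- function(x, ...) {
  ord <- integer(0L)
  walk <- function(code) {
    if (code < 0L) ord <<- c(ord, -code)
    else { walk(x$merge[code, 1L]); walk(x$merge[code, 2L]) }
  }
  walk(nrow(x$merge))
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "N-BC"),
            class = "hclust")
}

#' Cophenetic (tree path) distances of a ClusterTree
#' @param tree a `ClusterTree`.
#' @return Symmetric matrix of path distances between leaves.
#' @export
cophenetic_matrix <- function(tree) {
  as.matrix(stats::cophenetic(as.hclust(tree)))
}

#' Serialize a ClusterTree as Newick text
#'
#' Branch lengths are differences of ultrametric node heights (half the
#' merge distances); the output is parseable by standard readers.
#'
#' @param tree a `ClusterTree`.
#' @param file optional path; when given the text is written there.
#' @param digits significant digits for branch lengths.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 10L) {
  half <- tree$height / 2
  fmt <- function(x) sprintf("%.*g", digits, x)
  node_str <- function(code, parent_h) {
    if (code < 0L)
      paste0(tree$labels[-code], ":", fmt(parent_h))
    else {
      h <- half[code]
      paste0("(", node_str(tree$merge[code, 1L], h), ",",
             node_str(tree$merge[code, 2L], h), "):", fmt(parent_h - h))
    }
  }
  root <- nrow(tree$merge)
  txt <- paste0("(", node_str(tree$merge[root, 1L], half[root]), ",",
                node_str(tree$merge[root, 2L], half[root]), ");")
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

# --- three-branch decomposition -------------------------------------------

# Returns list(wt_branch, far1, far2, coph) of leaf-label character
# vectors; far2 may be empty when the far subtree is a single leaf.
three_branches <- function(tree, wt_label) {
  if (inherits(tree, "ClusterTree")) {
    coph <- cophenetic_matrix(tree)
    leaves_of <- function(code) {
      if (code < 0L) tree$labels[-code]
      else c(leaves_of(tree$merge[code, 1L]), leaves_of(tree$merge[code, 2L]))
    }
    root <- nrow(tree$merge)
    s1 <- leaves_of(tree$merge[root, 1L])
    s2 <- leaves_of(tree$merge[root, 2L])
    if (!wt_label %in% c(s1, s2)) stop("wild-type label '", wt_label, "' is not a leaf")
    wt_side <- if (wt_label %in% s1) s1 else s2
    far_code <- if (wt_label %in% s1) tree$merge[root, 2L] else tree$merge[root, 1L]
    if (far_code < 0L) {
      warning("far subtree is a single leaf; branches degenerate")
      far1 <- tree$labels[-far_code]; far2 <- character(0L)
    } else {
      far1 <- leaves_of(tree$merge[far_code, 1L])
      far2 <- leaves_of(tree$merge[far_code, 2L])
    }
  } else if (inherits(tree, "phylo")) {
    coph <- as.matrix(stats::cophenetic(tree))
    ntip <- length(tree$tip.label)
    if (!wt_label %in% tree$tip.label) stop("wild-type label '", wt_label, "' is not a leaf")
    kids <- function(node) tree$edge[tree$edge[, 1L] == node, 2L]
    tips_of <- function(node) {
      if (node <= ntip) return(tree$tip.label[node])
      unlist(lapply(kids(node), tips_of))
    }
    root <- ntip + 1L
    rk <- kids(root)
    if (length(rk) != 2L) stop("classification requires a rooted binary tree")
    s1 <- tips_of(rk[1L]); s2 <- tips_of(rk[2L])
    wt_side <- if (wt_label %in% s1) s1 else s2
    far_node <- if (wt_label %in% s1) rk[2L] else rk[1L]
    if (far_node <= ntip) {
      warning("far subtree is a single leaf; branches degenerate")
      far1 <- tree$tip.label[far_node]; far2 <- character(0L)
    } else {
      fk <- kids(far_node)
      far1 <- tips_of(fk[1L]); far2 <- tips_of(fk[2L])
    }
  } else stop("tree must be a ClusterTree or an ape phylo object")
  list(wt_branch = wt_side, far1 = far1, far2 = far2, coph = coph)
}

#' Classify variants by tree branch relative to the wild type
#'
#' The root of the tree splits the leaves into the wild-type-side
#' subtree and the far subtree; the far subtree's own root splits it
#' once more, giving three branches in total (the "three-branch
#' point"). The distal branch is the branch (among the three) whose
#' members have the largest mean cophenetic distance to the wild type;
#' branches tied at the maximum are pooled — on an exact ultrametric
#' UPGMA tree the two far branches always tie, so the distal set is
#' then the whole far subtree.
#'
#' Rules: `"distal_affected"` calls the distal branch affected and
#' everything else unaffected; `"proximal_unaffected"` calls the
#' wild-type branch unaffected and everything else affected. The wild
#' type itself is excluded from the output.
#'
#' @param tree a `ClusterTree` from [upgma()], or an `ape` `phylo`
#'   rooted binary tree with branch lengths.
#' @param wt_label leaf label of the wild type.
#' @param rule classification rule.
#' @param tol relative tolerance for distance ties.
#' @return Named character vector of `"affected"`/`"unaffected"` calls,
#'   one per non-wild-type leaf; branch membership is attached as
#'   attribute `"branches"`.
#' @export
classify_by_branch <- function(tree, wt_label,
                               rule = c("distal_affected", "proximal_unaffected"),
                               tol = 1e-8) {
  rule <- match.arg(rule)
  br <- three_branches(tree, wt_label)
  all_leaves <- c(br$wt_branch, br$far1, br$far2)
  if (length(all_leaves) < 4L) warning("fewer than 4 leaves; calls are weakly supported")
  branches <- list(wt_branch = br$wt_branch, far1 = br$far1, far2 = br$far2)
  mean_to_wt <- vapply(branches, function(b) {
    b <- setdiff(b, wt_label)
    if (length(b) == 0L) return(-Inf)
    mean(br$coph[wt_label, b])
  }, numeric(1L))
  mx <- max(mean_to_wt)
  distal <- unlist(branches[mean_to_wt >= mx - tol * max(abs(mx), 1)], use.names = FALSE)
  distal <- setdiff(distal, wt_label)
  items <- setdiff(all_leaves, wt_label)
  calls <- if (rule == "distal_affected") {
    ifelse(items %in% distal, "affected", "unaffected")
  } else {
    ifelse(items %in% br$wt_branch, "unaffected", "affected")
  }
  names(calls) <- items
  attr(calls, "branches") <- c(branches, list(distal = distal))
  calls
}
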