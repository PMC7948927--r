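#' Select torsions diverging from the wild type
#'
#' A torsion is selected when at least one mutant shows an absolute
#' circular-mean difference from the wild type above `threshold`
#' degrees AND that difference is significant under a two-sample
#' permutation test (frame labels permuted between the two series,
#' statistic = absolute circular-mean difference) at level `alpha`.
#' Frames are thinned (stride `thin`) before permutation to blunt the
#' autocorrelation of consecutive snapshots. Deterministic given
#' `seed`.
#'
#' @param series_by_variant named list of torsion matrices (frames x
#'   torsions, shared column labels), one per variant.
#' @param wt_id name of the wild-type entry.
#' @param threshold minimum absolute circular-mean difference, degrees.
#' @param alpha significance level of the permutation test.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param thin frame-thinning stride applied before permutation.
#' @return Character vector of selected torsion labels; the per-mutant
#'   shifts of the selected torsions are attached as attribute
#'   `"shifts"` (data frame: label, variant, shift_deg, p_value).
#' @export
select_divergent_torsions <- function(series_by_variant, wt_id, threshold = 36,
                                      alpha = 0.001, n_perm = 10000, seed = 1,
                                      thin = 10) {
  if (!wt_id %in% names(series_by_variant))
    stop("wild-type id '", wt_id, "' missing from the series list")
  labs <- colnames(series_by_variant[[1L]])
  for (v in names(series_by_variant))
    if (!identical(colnames(series_by_variant[[v]]), labs))
      stop("torsion labels of variant '", v, "' differ from the first variant")
  muts <- setdiff(names(series_by_variant), wt_id)
  wt <- series_by_variant[[wt_id]]
  selected <- character(0L)
  rows <- list()
  with_seed(seed, {
    for (lab in labs) {
      xw <- wt[, lab]; xw <- xw[!is.na(xw)]
      mw <- circular_mean(xw)
      for (v in muts) {
        xm <- series_by_variant[[v]][, lab]; xm <- xm[!is.na(xm)]
        shift <- circular_diff(circular_mean(xm), mw)
        if (is.na(shift) || abs(shift) <= threshold) next
        p <- perm_circmean_p(xw[seq(1L, length(xw), by = thin)],
                             xm[seq(1L, length(xm), by = thin)], n_perm)
        rows[[length(rows) + 1L]] <- data.frame(
          label = lab, variant = v, shift_deg = shift, p_value = p,
          stringsAsFactors = FALSE)
        if (p < alpha) selected <- union(selected, lab)
      }
    }
  })
  shifts <- do.call(rbind, rows) %||%
    data.frame(label = character(), variant = character(),
               shift_deg = numeric(), p_value = numeric())
  structure(selected, shifts = shifts)
}

# permutation p-value for |circular mean difference| of two angle
# samples (degrees); statistic recomputed under frame-label shuffles
perm_circmean_p <- function(x, y, n_perm) {
  z <- exp(1i * c(x, y) * pi / 180)
  n1 <- length(x); n <- length(z)
  stat <- function(idx1) {
    s1 <- sum(z[idx1]); s2 <- sum(z) - s1
    abs(wrap_angle((Arg(s1) - Arg(s2)) * 180 / pi))
  }
  obs <- stat(seq_len(n1))
  hits <- 0L
  for (i in seq_len(n_perm))
    if (stat(sample.int(n, n1)) >= obs - 1e-12) hits <- hits + 1L
  (hits + 1L) / (n_perm + 1L)
}

#' Assemble the PCA feature matrix
#'
#' Dihedral mode: every torsion angle theta contributes the pair of
#' columns cos(theta), sin(theta) — the standard dihedral-PCA
#' transformation that removes the discontinuity at +/-180 degrees.
#' Geometric mode: the named geometric parameters are pooled over all
#' variants and z-scored (each column mean 0, sd 1 over the pooled
#' frames) so that angstroms and degrees are commensurate.
#'
#' Frames containing `NA` are dropped per variant (reported); if the
#' remaining per-variant frame counts differ, all variants are
#' truncated to the common minimum (keeping the latest frames) so that
#' downstream histogram totals stay comparable.
#'
#' @param mode `"dihedral"` or `"geometric"`.
#' @param inputs named list of matrices (frames x variables), one per
#'   variant, with shared column labels. For dihedral mode optionally
#'   restricted to a selected torsion subset beforehand.
#' @param subset optional character vector of column labels to keep
#'   before assembly.
#' @param standardize z-score columns in geometric mode (default TRUE).
#' @return A `FeatureMatrix`: list with `X` (pooled rows x feature
#'   columns) and `variant` (factor tagging each row).
#' @export
build_feature_matrix <- function(mode = c("dihedral", "geometric"), inputs,
                                 subset = NULL, standardize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.list(inputs), length(inputs) >= 1L, !is.null(names(inputs)))
  labs <- colnames(inputs[[1L]])
  for (v in names(inputs))
    if (!identical(colnames(inputs[[v]]), labs))
      stop("variable labels of variant '", v, "' differ from the first variant")
  if (!is.null(subset)) {
    missing <- setdiff(subset, labs)
    if (length(missing)) stop("unknown label(s): ", paste(missing, collapse = ", "))
    inputs <- lapply(inputs, function(m) m[, subset, drop = FALSE])
    labs <- subset
  }
  clean <- lapply(inputs, function(m) m[stats::complete.cases(m), , drop = FALSE])
  dropped <- sum(vapply(inputs, nrow, 0L)) - sum(vapply(clean, nrow, 0L))
  if (dropped > 0L) message(dropped, " frame(s) with NA dropped")
  nmin <- min(vapply(clean, nrow, 0L))
  if (nmin < 1L) stop("a variant has no complete frames")
  if (any(vapply(clean, nrow, 0L) != nmin)) {
    warning("unequal frame counts; truncating every variant to the last ",
            nmin, " frames")
    clean <- lapply(clean, function(m) m[seq.int(nrow(m) - nmin + 1L, nrow(m)), , drop = FALSE])
  }
  X <- do.call(rbind, clean)
  variant <- factor(rep(names(clean), each = nmin), levels = names(clean))
  if (mode == "dihedral") {
    r <- X * pi / 180
    X <- cbind(cos(r), sin(r))
    colnames(X) <- c(paste0(labs, ":cos"), paste0(labs, ":sin"))
    X <- X[, as.vector(rbind(seq_along(labs), seq_along(labs) + length(labs))), drop = FALSE]
  } else if (standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    if (any(sdv == 0)) stop("zero-variance geometric column: ",
                            paste(labs[sdv == 0], collapse = ", "))
    X <- scale(X, center = mu, scale = sdv)
    attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
  }
  rownames(X) <- NULL
  structure(list(X = X, variant = variant), class = "FeatureMatrix")
}

#' Fit a single PCA over the pooled trajectory set and project frames
#'
#' Eigendecomposition of the covariance matrix of the pooled rows (one
#' fit for all variants; every frame is projected with the same
#' loadings). Sign convention: the largest-magnitude element of each
#' loading is positive.
#'
#' @param fm a `FeatureMatrix` from [build_feature_matrix()].
#' @return A `PCAResult`: list with `mean`, `loadings` (columns,
#'   orthonormal), `eigenvalues` (non-increasing), `projections` (data
#'   frame: `variant`, `PC1`, `PC2`, ...).
#' @export
fit_project_pca <- function(fm) {
  X <- fm$X
  if (nrow(X) < 2L || ncol(X) < 2L) stop("need at least 2 rows and 2 columns")
  if (all(apply(X, 2L, stats::sd) == 0)) stop("zero-variance feature matrix")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  proj <- data.frame(variant = fm$variant, scores, check.names = FALSE)
  structure(list(mean = pc$center, loadings = rot,
                 eigenvalues = pc$sdev^2, projections = proj),
            class = "PCAResult")
}

#' Per-variant means of the leading principal components
#'
#' Arithmetic means of the per-frame projections, the quantities shown
#' in variant-level PC1 vs PC2 maps.
#'
#' @param pca a `PCAResult`.
#' @param k number of components to summarize.
#' @return Data frame: `variant`, mean `PC1..PCk`.
#' @export
pc_means <- function(pca, k = 2L) {
  p <- pca$projections
  k <- min(k, ncol(p) - 1L)
  agg <- aggregate(p[, 1L + seq_len(k), drop = FALSE],
                   by = list(variant = p$variant), FUN = mean)
  agg
}
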