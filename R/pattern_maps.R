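# Weight back-projection from PCA space to voxel space and
# cross-validation ratio (CV-ratio) reliability maps.

#' Back-project a linear model's weights to voxel space
#'
#' Propagates the SVM/SVR weight vector through the chain's linear steps:
#' the min-max scaling is inverted analytically (weight / training range;
#' constant features contribute nothing) and the PCA basis maps component
#' weights back to voxels. Smoothing and z-normalization are not inverted —
#' the map lives in preprocessed (z-scored, residualized) voxel space.
#'
#' @param w model weight vector over retained components.
#' @param chain the model's fitted [fit_chain()].
#' @return numeric voxel weight vector (x-fastest order).
#' @export
backproject <- function(w, chain) {
  stopifnot(inherits(chain, "transform_chain"))
  if (length(w) != ncol(chain$pca$basis))
    stop("weight length does not match the PCA basis")
  r <- chain$minmax$range
  wk <- ifelse(r == 0, 0, w / ifelse(r == 0, 1, r))
  drop(chain$pca$basis %*% wk)
}

#' Back-project every model of an ensemble
#'
#' @param ensemble a trained `model_ensemble`.
#' @return voxels x models matrix of back-projected weight maps.
#' @export
backproject_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  vapply(ensemble$models, function(md) backproject(md$w, md$chain),
         numeric(prod(ensemble$grid_shape)))
}

#' Cross-validation ratio reliability map
#'
#' Per voxel: the median weight across fold maps divided by their standard
#' error (SD across folds over sqrt(k)). Voxels where the fold weights are
#' numerically constant but nonzero get a signed cap (the conventional
#' reliability threshold is |ratio| >= 3). The alternative reading that
#' sums per-group medians before dividing is available via `numerator` with
#' a fold-grouping vector.
#'
#' @param weight_maps voxels x folds matrix of back-projected maps.
#' @param numerator `"median"` (default) or `"sum_of_medians"`.
#' @param groups fold grouping (e.g. outer partition ids) for
#'   `"sum_of_medians"`.
#' @param cap magnitude assigned when the SE underflows (default 1e6).
#' @param threshold reliability threshold for the returned mask.
#' @return list of class `stat_map` with `values`, `mask`
#'   (|ratio| >= threshold), `median`, `se`.
#' @export
cv_ratio <- function(weight_maps, numerator = c("median", "sum_of_medians"),
                     groups = NULL, cap = 1e6, threshold = 3) {
  numerator <- match.arg(numerator)
  weight_maps <- as.matrix(weight_maps)
  k <- ncol(weight_maps)
  if (k < 3) stop("need at least 3 fold maps")
  num <- if (numerator == "median") {
    apply(weight_maps, 1, median)
  } else {
    if (is.null(groups)) groups <- rep(1, k)
    gs <- unique(groups)
    rowSums(vapply(gs, function(g) {
      apply(weight_maps[, groups == g, drop = FALSE], 1, median)
    }, numeric(nrow(weight_maps))))
  }
  se <- apply(weight_maps, 1, sd) / sqrt(k)
  ratio <- ifelse(se < 1e-12,
                  ifelse(abs(num) < 1e-12, 0, sign(num) * cap),
                  num / se)
  structure(list(values = ratio, mask = abs(ratio) >= threshold,
                 median = num, se = se),
            class = "stat_map")
}

#' Rank correlation between two voxel maps
#'
#' @param map_a,map_b numeric voxel vectors on the same grid.
#' @param method correlation method (default Spearman).
#' @param mask optional logical voxel subset.
#' @return correlation coefficient; `NA` (with a warning) for constant maps.
#' @export
map_correlation <- function(map_a, map_b, method = "spearman", mask = NULL) {
  a <- if (inherits(map_a, "stat_map")) map_a$values else map_a
  b <- if (inherits(map_b, "stat_map")) map_b$values else map_b
  if (length(a) != length(b)) stop("maps are on different grids")
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  if (sd(a) < 1e-15 || sd(b) < 1e-15) {
    warning("constant map: correlation undefined")
    return(NA_real_)
  }
  cor(a, b, method = method)
}
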