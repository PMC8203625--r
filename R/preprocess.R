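# In-fold preprocessing chain: control-based z-normalization, Gaussian
# smoothing, covariate regression learned on controls, PCA (80% variance),
# and [0,1] scaling. Every step is a fit/apply pair so fitted state never
# sees held-out rows.

# --- z-normalization ---------------------------------------------------------

#' Fit control-based z-normalization parameters
#'
#' Per-voxel mean and SD over the control subjects of a dataset. Datasets
#' from different scanners are standardized with their own controls before
#' any model is trained or applied, which removes per-scanner affine
#' intensity differences.
#'
#' @param stack a [gm_stack()].
#' @param control_idx integer or logical index of control rows (>= 2).
#' @param sd_floor SD values below this floor are replaced by it, so that
#'   near-constant (e.g. empty) voxels do not blow up the division.
#' @return list of class `znorm_params` with `mu_hc`, `sigma_hc`.
#' @export
fit_znorm <- function(stack, control_idx, sd_floor = 1e-6) {
  x <- stack$data[control_idx, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 controls to fit z-normalization")
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[sg < sd_floor] <- sd_floor
  structure(list(mu_hc = mu, sigma_hc = sg, n_controls = nrow(x)),
            class = "znorm_params")
}

#' Apply z-normalization
#'
#' Computes `z = (x_i - mu_hc) / sigma_hc` per voxel for every subject.
#'
#' @param stack a [gm_stack()].
#' @param params a [fit_znorm()] result.
#' @return z-scored `gm_stack`.
#' @export
apply_znorm <- function(stack, params) {
  stopifnot(inherits(params, "znorm_params"),
            ncol(stack$data) == length(params$mu_hc))
  z <- sweep(sweep(stack$data, 2, params$mu_hc, "-"), 2, params$sigma_hc, "/")
  gm_stack(z, stack$grid_shape, stack$voxel_size_mm, stack$subject_ids)
}

#' Z-normalize a dataset with its own controls
#'
#' Convenience wrapper: fit on the dataset's controls, apply to all rows.
#'
#' @param stack a [gm_stack()].
#' @param pheno matching phenotype table with a `group` column.
#' @param control_label label identifying controls.
#' @return z-scored `gm_stack`.
#' @export
znorm_dataset <- function(stack, pheno, control_label = "control") {
  apply_znorm(stack, fit_znorm(stack, pheno$group == control_label))
}

# --- Gaussian smoothing ------------------------------------------------------

# 1-D Gaussian convolution matrix with reflection boundary handling
# (mirrored about the volume edge, half-sample convention). The folded
# matrix is symmetric and doubly stochastic: constant inputs are unchanged
# and total mass is preserved exactly.
gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  off <- -r:r
  k <- exp(-off^2 / (2 * sigma^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    t <- i + off
    # reflect out-of-range indices back into 1..n
    while (any(t < 1 | t > n)) {
      t <- ifelse(t < 1, 1 - t, t)
      t <- ifelse(t > n, 2 * n + 1 - t, t)
    }
    for (j in seq_along(off)) M[i, t[j]] <- M[i, t[j]] + k[j]
  }
  M
}

# Smooth one 3-D volume with per-axis sigma in voxel units.
smooth_volume <- function(vol, sigma_vox) {
  shape <- dim(vol)
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    K <- gauss_conv_matrix(shape[ax], sigma_vox[ax])
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    dv <- dim(v)
    dim(v) <- c(dv[1], prod(dv[-1]))
    v <- K %*% v
    dim(v) <- dv
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Gaussian smoothing of a gray-matter stack
#'
#' Separable Gaussian smoothing of every subject's 3-D volume with
#' `sigma = FWHM / (2*sqrt(2*log(2)))` per axis, converted to voxel units
#' via the stack's voxel size. Boundaries are handled by reflection, which
#' preserves total mass. `fwhm_mm = 0` is the identity.
#'
#' @param stack a [gm_stack()].
#' @param fwhm_mm full width at half maximum of the kernel, in mm (>= 0).
#' @return smoothed `gm_stack`.
#' @export
gaussian_smooth <- function(stack, fwhm_mm) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(stack)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / stack$voxel_size_mm
  shape <- stack$grid_shape
  Ks <- lapply(1:3, function(ax) gauss_conv_matrix(shape[ax], sigma_vox[ax]))
  out <- stack$data
  for (i in seq_len(nrow(out))) {
    vol <- array(out[i, ], dim = shape)
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      v <- aperm(vol, perm)
      dv <- dim(v)
      dim(v) <- c(dv[1], prod(dv[-1]))
      v <- Ks[[ax]] %*% v
      dim(v) <- dv
      vol <- aperm(v, order(perm))
    }
    out[i, ] <- as.vector(vol)
  }
  gm_stack(out, shape, stack$voxel_size_mm, stack$subject_ids)
}

# --- covariate regression ----------------------------------------------------

#' Fit per-voxel covariate regression on a reference subset
#'
#' Ordinary least squares of every voxel on the covariates (with intercept),
#' fitted on the rows in `fit_idx` only — for the classifier chain these are
#' the training-fold healthy controls, so patient-related variance is never
#' absorbed into the nuisance model.
#'
#' @param stack a [gm_stack()].
#' @param covariates data.frame or matrix of numeric covariates, one row per
#'   stack row.
#' @param fit_idx rows used to estimate the betas (defaults to all).
#' @return list of class `covreg_params` with `betas` ((1+k) x voxels,
#'   intercept first) and `covariate_names`.
#' @export
fit_covariate_regression <- function(stack, covariates, fit_idx = NULL) {
  X <- as.matrix(covariates)
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(stack$data))
  Xf <- cbind(`(Intercept)` = 1, X[fit_idx, , drop = FALSE])
  if (qr(Xf)$rank < ncol(Xf))
    stop("covariate matrix is rank deficient on the fitting rows")
  Y <- stack$data[fit_idx, , drop = FALSE]
  betas <- solve(crossprod(Xf), crossprod(Xf, Y))
  structure(list(betas = betas,
                 covariate_names = colnames(X) %||% paste0("x", seq_len(ncol(X)))),
            class = "covreg_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove covariate effects from all subjects
#'
#' Subtracts the slope terms `X %*% beta` (the intercept is retained, so the
#' mean structure of the reference population stays in place).
#'
#' @param stack a [gm_stack()].
#' @param covariates covariate values for every stack row (same columns as
#'   at fit time).
#' @param params a [fit_covariate_regression()] result.
#' @return residualized `gm_stack`.
#' @export
apply_covariate_regression <- function(stack, covariates, params) {
  stopifnot(inherits(params, "covreg_params"))
  X <- as.matrix(covariates)
  res <- stack$data - X %*% params$betas[-1, , drop = FALSE]
  gm_stack(res, stack$grid_shape, stack$voxel_size_mm, stack$subject_ids)
}

# --- PCA ---------------------------------------------------------------------

#' Fit PCA retaining a target fraction of variance
#'
#' Centers on the training rows and keeps the smallest number of leading
#' components whose cumulative explained-variance ratio reaches
#' `variance_target`. For reproducible back-projection each component's
#' largest-magnitude loading is made positive.
#'
#' @param x numeric matrix (training rows x features).
#' @param variance_target fraction of variance to retain, in (0, 1].
#' @return list of class `pca_params` with `center`, `basis`
#'   (features x k), `explained_ratio` (all components), `k`.
#' @export
fit_pca <- function(x, variance_target = 0.8) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples to fit PCA")
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0)
  ev <- sv$d^2
  pos <- ev > max(ev) * 1e-12
  ev <- ev[pos]
  basis <- sv$v[, pos, drop = FALSE]
  ratio <- ev / sum(ev)
  k <- which(cumsum(ratio) >= variance_target - 1e-12)[1]
  basis <- basis[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    m <- which.max(abs(basis[, j]))
    if (basis[m, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(list(center = ctr, basis = basis, explained_ratio = ratio, k = k),
            class = "pca_params")
}

#' Project data onto a fitted PCA basis
#'
#' @param x numeric matrix with the same features as at fit time.
#' @param params a [fit_pca()] result.
#' @return scores matrix (rows x k).
#' @export
apply_pca <- function(x, params) {
  stopifnot(inherits(params, "pca_params"))
  sweep(as.matrix(x), 2, params$center) %*% params$basis
}

# --- min-max scaling ---------------------------------------------------------

#' Fit [0,1] scaling bounds on training features
#'
#' @param x numeric matrix (training rows x features).
#' @return list of class `minmax_params` with `min`, `range`.
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  mn <- apply(x, 2, min)
  mx <- apply(x, 2, max)
  structure(list(min = mn, range = mx - mn), class = "minmax_params")
}

#' Apply [0,1] scaling
#'
#' `(x - min) / (max - min)` with the training bounds. Constant training
#' features map to 0; held-out values outside the training range are NOT
#' clipped, so test scores can fall outside `[0, 1]`.
#'
#' @param x numeric matrix.
#' @param params a [fit_minmax()] result.
#' @return scaled matrix.
#' @export
apply_minmax <- function(x, params) {
  stopifnot(inherits(params, "minmax_params"))
  x <- sweep(as.matrix(x), 2, params$min)
  r <- params$range
  r[r == 0] <- Inf   # constant feature -> 0
  sweep(x, 2, r, "/")
}

# --- full chain --------------------------------------------------------------

#' Fit the in-fold preprocessing chain
#'
#' Covariate regression (fitted on the training-fold reference rows, by
#' default the controls), PCA, and min-max scaling, fitted strictly on
#' `train_idx` rows of an already-smoothed stack. Smoothing is treated as a
#' hyperparameter upstream (the smoothed stack versions are precomputed once
#' per dataset), and the chain records which FWHM it belongs to.
#'
#' @param stack the smoothed, z-normalized [gm_stack()].
#' @param covariates covariate data.frame for all stack rows.
#' @param train_idx integer indices of the training rows.
#' @param covreg_idx rows (subset of `train_idx`) on which the covariate
#'   betas are estimated; defaults to `train_idx`.
#' @param variance_target PCA variance target.
#' @param fwhm_mm FWHM tag recorded in the chain.
#' @return list of class `transform_chain`.
#' @export
fit_chain <- function(stack, covariates, train_idx, covreg_idx = train_idx,
                      variance_target = 0.8, fwhm_mm = NA_real_) {
  if (!all(covreg_idx %in% train_idx))
    stop("covreg_idx must be a subset of train_idx")
  covreg <- fit_covariate_regression(stack, covariates, covreg_idx)
  resid_tr <- as.matrix(covariates[train_idx, , drop = FALSE]) %*%
    covreg$betas[-1, , drop = FALSE]
  xtr <- stack$data[train_idx, , drop = FALSE] - resid_tr
  pca <- fit_pca(xtr, variance_target)
  sc <- apply_pca(xtr, pca)
  mm <- fit_minmax(sc)
  structure(list(covreg = covreg, pca = pca, minmax = mm,
                 fwhm_mm = fwhm_mm, variance_target = variance_target,
                 fit_rows = sort(train_idx), covreg_rows = sort(covreg_idx)),
            class = "transform_chain")
}

#' Apply a fitted preprocessing chain
#'
#' Pure function of the fitted state: residualize covariates, project onto
#' the PCA basis, scale to the training `[0,1]` bounds.
#'
#' @param chain a [fit_chain()] result.
#' @param stack smoothed z-scored [gm_stack()] (same FWHM as at fit time).
#' @param covariates covariates for the stack rows.
#' @param idx optional row subset to transform (default all rows).
#' @return feature matrix (rows x retained components).
#' @export
apply_chain <- function(chain, stack, covariates, idx = NULL) {
  stopifnot(inherits(chain, "transform_chain"))
  if (is.null(idx)) idx <- seq_len(nrow(stack$data))
  x <- stack$data[idx, , drop = FALSE] -
    as.matrix(covariates[idx, , drop = FALSE]) %*%
    chain$covreg$betas[-1, , drop = FALSE]
  apply_minmax(apply_pca(x, chain$pca), chain$minmax)
}
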