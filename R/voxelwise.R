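# Voxelwise inference for pattern-expression-change x timepoint
# interactions: covariate residualization, per-voxel interaction statistics,
# threshold-free cluster enhancement, and max-statistic permutation FWE.

#' Residualize images against nuisance covariates
#'
#' Per-voxel OLS of every voxel on the covariates (e.g. sex and TIV), with
#' the intercept retained, fitted and applied on all rows.
#'
#' @param stack a [gm_stack()].
#' @param covariates covariate data.frame for all rows.
#' @return residualized `gm_stack`.
#' @export
residualize_images <- function(stack, covariates) {
  params <- fit_covariate_regression(stack, covariates)
  apply_covariate_regression(stack, covariates, params)
}

# per-subject difference images D (t1 - t0) and the matching per-subject
# score differences; subjects with only one timepoint are dropped.
pair_diffs <- function(stack, pheno, scores) {
  stopifnot(nrow(stack$data) == nrow(pheno), length(scores) == nrow(pheno))
  tab <- table(pheno$subject_id)
  ok <- names(tab)[tab == 2]
  if (length(ok) < length(tab))
    warning(sum(tab != 2), " subject(s) without both timepoints dropped")
  i0 <- match(paste0(ok, "|0"), paste0(pheno$subject_id, "|", pheno$timepoint))
  i1 <- match(paste0(ok, "|1"), paste0(pheno$subject_id, "|", pheno$timepoint))
  keep <- !is.na(i0) & !is.na(i1)
  i0 <- i0[keep]; i1 <- i1[keep]
  list(D = stack$data[i1, , drop = FALSE] - stack$data[i0, , drop = FALSE],
       dx = scores[i1] - scores[i0], subjects = ok[keep])
}

# slope t- and F-statistics of per-voxel regression of D on centred x
diff_regression_stats <- function(D, x) {
  n <- nrow(D)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Dc <- sweep(D, 2, colMeans(D))
  beta <- drop(crossprod(xc, Dc)) / sxx
  rss <- colSums(Dc^2) - beta^2 * sxx
  rss[rss < 0] <- 0
  sigma2 <- rss / (n - 2)
  tt <- beta * sqrt(sxx) / sqrt(sigma2)
  tt[sigma2 < 1e-24] <- NA_real_
  list(t = tt, f = tt^2, df2 = n - 2, beta = beta)
}

#' Voxelwise expression-change by timepoint interaction map
#'
#' For a balanced two-timepoint design with subject as the random
#' (within-subject) factor, the mixed-effects interaction between a
#' per-subject expression difference and timepoint is algebraically
#' equivalent to the between-subject regression of within-subject image
#' differences on the score differences; the map holds the per-voxel F
#' statistic of that slope. Zero-variance voxels are returned as NA.
#'
#' @param stack longitudinal [gm_stack()] (one row per subject-timepoint).
#' @param pheno matching phenotype table with `subject_id` and `timepoint`
#'   (0/1).
#' @param scores per-observation pattern-expression scores.
#' @return list of class `stat_map` with `values` (F), `t`, `df1`, `df2`,
#'   `grid_shape`.
#' @export
interaction_map <- function(stack, pheno, scores) {
  pd <- pair_diffs(stack, pheno, scores)
  if (nrow(pd$D) < 3) stop("need at least 3 complete subjects")
  st <- diff_regression_stats(pd$D, pd$dx)
  structure(list(values = st$f, t = st$t, df1 = 1, df2 = st$df2,
                 grid_shape = stack$grid_shape),
            class = "stat_map")
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over all thresholds:
#' `TFCE(v) = sum_h e(v,h)^E * h^H * dh` for `h` from `dh` to the map
#' maximum, where `e(v,h)` is the extent of the connected supra-threshold
#' component containing `v`. Defaults E = 0.5, H = 2 are the method's
#' standard exponents. Expects a non-negative map; run the positive and
#' negated map separately for two-sided statistics.
#'
#' @param map non-negative 3-D array (or voxel vector with `grid_shape`).
#' @param E extent exponent.
#' @param H height exponent.
#' @param dh_frac integration step as a fraction of the map maximum.
#' @param connectivity 6, 18 or 26 neighbourhood.
#' @param grid_shape required when `map` is a bare vector.
#' @return 3-D array of TFCE scores.
#' @export
tfce <- function(map, E = 0.5, H = 2, dh_frac = 0.01, connectivity = 6,
                 grid_shape = NULL) {
  stopifnot(E > 0, H > 0, dh_frac > 0, connectivity %in% c(6, 18, 26))
  if (is.null(dim(map))) {
    if (is.null(grid_shape)) stop("grid_shape required for a bare vector")
    map <- array(map, dim = grid_shape)
  }
  dims <- dim(map)
  mx <- max(map)
  if (!is.finite(mx) || mx <= 0) return(array(0, dim = dims))
  tfce_cpp(as.numeric(map), as.integer(dims), E, H, mx * dh_frac,
           as.integer(connectivity))
}

#' Label connected components of a voxel mask
#'
#' @param mask logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 6) {
  stopifnot(connectivity %in% c(6, 18, 26))
  label_components_cpp(mask, as.integer(dim(mask)), as.integer(connectivity))
}

#' Voxelwise FWE-corrected interaction inference via permutation TFCE
#'
#' Computes the observed per-voxel slope t-map of within-subject image
#' differences on score differences, enhances the positive and negative map
#' separately with TFCE (two-sided), and builds the null distribution of
#' the maximum TFCE statistic by sign-flipping the per-voxel-centred
#' difference images at the subject level (the exchangeability unit of a
#' paired design). Corrected p(v) = (1 + #\{max_pi >= TFCE(v)\}) /
#' (n_perm + 1). When fewer than `n_perm` distinct sign patterns exist the
#' flips are enumerated exhaustively with a warning.
#'
#' @param stack longitudinal [gm_stack()].
#' @param pheno matching phenotype table (`subject_id`, `timepoint`).
#' @param scores per-observation expression scores.
#' @param n_perm number of sign-flip permutations (default 5000).
#' @param seed RNG seed.
#' @param E,H,dh_frac,connectivity TFCE parameters, see [tfce()].
#' @return list of class `fwe_result` with `t` (array), `tfce_signed`
#'   (array), `p_corrected` (array), `max_null`, `n_perm`.
#' @export
permutation_fwe <- function(stack, pheno, scores, n_perm = 5000, seed = 1L,
                            E = 0.5, H = 2, dh_frac = 0.01,
                            connectivity = 6) {
  pd <- pair_diffs(stack, pheno, scores)
  n <- nrow(pd$D)
  shape <- stack$grid_shape
  xc <- pd$dx - mean(pd$dx)
  sxx <- sum(xc^2)
  Dc <- sweep(pd$D, 2, colMeans(pd$D))
  css <- colSums(Dc^2)

  tstat_for_signs <- function(s) {
    m <- drop(crossprod(s, Dc)) / n
    num <- drop(crossprod(xc * s, Dc))
    beta <- num / sxx
    rss <- (css - n * m^2) - beta^2 * sxx
    rss[rss < 0] <- 0
    sigma2 <- rss / (n - 2)
    tt <- beta * sqrt(sxx) / sqrt(sigma2)
    tt[sigma2 < 1e-24] <- 0
    tt
  }

  tfce_two_sided <- function(tt) {
    pos <- tfce(array(pmax(tt, 0), dim = shape), E, H, dh_frac, connectivity)
    neg <- tfce(array(pmax(-tt, 0), dim = shape), E, H, dh_frac, connectivity)
    pos - neg
  }

  t_obs <- tstat_for_signs(rep(1, n))
  tfce_obs <- tfce_two_sided(t_obs)

  exhaustive <- 2^n <= n_perm
  if (exhaustive)
    warning("fewer than n_perm distinct sign patterns; enumerating all 2^n")
  max_null <- with_seed(seed, {
    if (exhaustive) {
      vapply(seq_len(2^n) - 1L, function(code) {
        s <- 1 - 2 * as.integer(intToBits(code)[seq_len(n)])
        max(abs(tfce_two_sided(tstat_for_signs(s))))
      }, 0)
    } else {
      vapply(seq_len(n_perm), function(i) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        max(abs(tfce_two_sided(tstat_for_signs(s))))
      }, 0)
    }
  })
  nn <- length(max_null)
  p <- array(vapply(abs(tfce_obs), function(v) {
    (1 + sum(max_null >= v - 1e-12)) / (nn + 1)
  }, 0), dim = shape)

  structure(list(t = array(t_obs, dim = shape), tfce_signed = tfce_obs,
                 p_corrected = p, max_null = max_null, n_perm = nn,
                 seed = seed),
            class = "fwe_result")
}
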