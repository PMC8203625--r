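#' Simulation configuration for synthetic gray-matter cohorts
#'
#' Bundles all generative parameters for the multi-site synthetic cohorts.
#' The generator plants two compact voxel patterns on the grid: a disorder
#' pattern whose expression is present only in patients and grows with
#' disorder duration, and a global aging pattern along which density declines
#' linearly with age. Scanner sites distort the maps with a per-site affine
#' (scale + offset) term, emulating between-scanner intensity differences.
#'
#' `disorder_effect` is a standardized (Cohen's d) effect size: the planted
#' patient-control difference at a disorder-pattern voxel equals
#' `disorder_effect * noise_sd` density units at duration 0, growing by the
#' fraction `progression_rate` per year of disorder duration.
#'
#' @param grid_shape integer length-3 voxel extents (all >= 4).
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param n_per_group subjects per group per cohort (>= 10 for realistic
#'   cohorts; simulate_cohort accepts >= 2).
#' @param age_range years, uniform age range for wide-age cross-sectional
#'   cohorts.
#' @param cohort_age,cohort_age_sd years; mean and (small) SD of age in the
#'   narrow-age birth cohort.
#' @param followup_gap years between the two timepoints of a longitudinal
#'   cohort.
#' @param disorder_effect standardized effect size delta at disorder-pattern
#'   voxels (>= 0).
#' @param progression_rate fractional increase of the disorder effect per
#'   year of disorder duration (>= 0), patients only.
#' @param aging_slope density units lost per year at aging-pattern voxels.
#' @param site_offset,site_scale numeric vectors, one entry per scanner
#'   site; site s maps a clean value v to `site_scale[s]*v + site_offset[s]`.
#' @param noise_sd additive Gaussian noise SD in density units (> 0).
#' @param baseline_mean mean of the baseline density map B(v).
#' @param overlap_fraction fraction of disorder-pattern voxels shared with
#'   the aging pattern, in `[0, 1]`.
#' @param duration_range years, uniform range of disorder duration at the
#'   first timepoint for synthetic patients.
#' @param clinical_couplings list of couplings used by [attach_clinical()];
#'   each entry is `list(name=, pattern="disorder"|"aging", slope=,
#'   noise_sd=, type="gaussian"|"binary")`.
#' @param seed integer RNG seed; the same config reproduces the identical
#'   dataset.
#' @return A list of class `sim_config`.
#' @seealso [make_ground_truth()], [simulate_cohort()]
#' @export
sim_config <- function(grid_shape = c(16, 16, 16),
                       voxel_size_mm = c(2, 2, 2),
                       n_per_group = 70,
                       age_range = c(20, 65),
                       cohort_age = 33.7,
                       cohort_age_sd = 0.7,
                       followup_gap = 9.1,
                       disorder_effect = 0.8,
                       progression_rate = 0.04,
                       aging_slope = 0.003,
                       site_offset = c(0, 0.05),
                       site_scale = c(1, 1.05),
                       noise_sd = 0.1,
                       baseline_mean = 0.5,
                       overlap_fraction = 0.25,
                       duration_range = c(2, 30),
                       clinical_couplings = default_clinical_couplings(),
                       seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 4))
    stop("grid_shape must have 3 extents, all >= 4")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (disorder_effect < 0) stop("disorder_effect must be >= 0")
  if (progression_rate < 0) stop("progression_rate must be >= 0")
  if (length(site_offset) != length(site_scale))
    stop("site_offset and site_scale must have one entry per site")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
         n_per_group = n_per_group, age_range = age_range,
         cohort_age = cohort_age, cohort_age_sd = cohort_age_sd,
         followup_gap = followup_gap, disorder_effect = disorder_effect,
         progression_rate = progression_rate, aging_slope = aging_slope,
         site_offset = site_offset, site_scale = site_scale,
         noise_sd = noise_sd, baseline_mean = baseline_mean,
         overlap_fraction = overlap_fraction,
         duration_range = duration_range,
         clinical_couplings = clinical_couplings, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default clinical couplings
#'
#' Clinical variables tied to the planted disorder-pattern expression
#' (symptoms, hospitalisations, BMI positively; verbal cognition negatively)
#' or to the aging pattern (antipsychotic dose-years), plus binary outcomes
#' (remission, functional recovery, being medication-free) drawn from a
#' logistic link with low pattern expression favouring good outcomes. Noise
#' SDs are on the scale of the standardized expression.
#'
#' @return list of coupling specifications for [attach_clinical()].
#' @export
default_clinical_couplings <- function() {
  list(
    list(name = "positive_symptoms", pattern = "disorder", slope = 0.5,
         noise_sd = 0.87, type = "gaussian"),
    list(name = "negative_symptoms", pattern = "disorder", slope = 0.5,
         noise_sd = 0.87, type = "gaussian"),
    list(name = "hospitalizations", pattern = "disorder", slope = 0.4,
         noise_sd = 0.92, type = "gaussian"),
    list(name = "cvlt", pattern = "disorder", slope = -0.5,
         noise_sd = 0.87, type = "gaussian"),
    list(name = "bmi", pattern = "disorder", slope = 0.3,
         noise_sd = 0.95, type = "gaussian"),
    list(name = "cpz_dose_years", pattern = "aging", slope = 0.5,
         noise_sd = 0.87, type = "gaussian"),
    list(name = "remission", pattern = "disorder", slope = -1.5,
         noise_sd = 0, type = "binary"),
    list(name = "recovery", pattern = "disorder", slope = -1.5,
         noise_sd = 0, type = "binary"),
    list(name = "medication_free", pattern = "disorder", slope = -1.5,
         noise_sd = 0, type = "binary")
  )
}

# Place a cuboid of dims `d` at anchor `a` (1-based) on grid `shape`;
# returns flat voxel indices in x-fastest order.
cuboid_idx <- function(shape, a, d) {
  stopifnot(all(a >= 1), all(a + d - 1 <= shape))
  xs <- a[1]:(a[1] + d[1] - 1)
  ys <- a[2]:(a[2] + d[2] - 1)
  zs <- a[3]:(a[3] + d[3] - 1)
  g <- expand.grid(x = xs, y = ys, z = zs)
  g$x + shape[1] * (g$y - 1) + shape[1] * shape[2] * (g$z - 1)
}

#' Generate the ground truth for a simulated study
#'
#' Draws the baseline density map B(v) (a smoothed random field around
#' `baseline_mean`) and plants two compact cuboid patterns: the disorder
#' pattern P and the aging pattern A, with a configurable fraction of shared
#' voxels. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list of class `ground_truth` with elements `baseline` (numeric
#'   voxel vector), `disorder_pattern` and `aging_pattern` (0/1 voxel weight
#'   vectors), `disorder_idx`, `aging_idx`, `grid_shape`, `voxel_size_mm`,
#'   and `config_seed`.
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  shape <- config$grid_shape
  V <- prod(shape)
  with_seed(config$seed + 1000L, {
    # smooth baseline field: low-frequency modulation around baseline_mean
    raw <- array(runif(V, -1, 1), dim = shape)
    sm <- smooth_volume(raw, sigma_vox = shape / 8)
    sm <- sm / max(abs(sm), 1e-12)
    baseline <- config$baseline_mean * (1 + 0.2 * as.vector(sm))

    d <- pmax(2L, as.integer(ceiling(shape / 3)))
    # disorder cuboid: random anchor leaving room for a disjoint shift
    amax <- shape - d + 1L
    a_dis <- vapply(seq_len(3), function(k) sample.int(amax[k], 1L), 1L)
    dis_idx <- cuboid_idx(shape, a_dis, d)

    # aging cuboid: same dims, shifted along x so that the shared fraction
    # of disorder voxels equals overlap_fraction (rounded to whole columns)
    keep_cols <- round(config$overlap_fraction * d[1])
    shift <- d[1] - keep_cols
    a_age <- a_dis
    if (a_dis[1] + shift + d[1] - 1 <= shape[1]) {
      a_age[1] <- a_dis[1] + shift
    } else if (a_dis[1] - shift >= 1) {
      a_age[1] <- a_dis[1] - shift
    } else {
      stop("grid too small to place patterns at the requested overlap")
    }
    age_idx <- cuboid_idx(shape, a_age, d)

    P <- numeric(V); P[dis_idx] <- 1
    A <- numeric(V); A[age_idx] <- 1
    structure(
      list(baseline = baseline, disorder_pattern = P, aging_pattern = A,
           disorder_idx = sort(dis_idx), aging_idx = sort(age_idx),
           grid_shape = shape, voxel_size_mm = config$voxel_size_mm,
           config_seed = config$seed),
      class = "ground_truth"
    )
  })
}

#' Simulate a synthetic cohort
#'
#' Generates per-subject gray-matter maps and the matching phenotype table.
#' The clean map for subject i is
#' `B(v) - aging_slope*A(v)*age_i - delta*noise_sd*P(v)*(1 + rho*duration_i)`
#' for patients (controls carry no disorder term), which is then distorted by
#' the subject's site affine, perturbed with i.i.d. Gaussian noise, and
#' clipped at zero (density is non-negative; clipping slightly biases means
#' where B(v) is small relative to the noise).
#'
#' With `longitudinal = TRUE` every subject is observed at two timepoints
#' `followup_gap` years apart (independent noise per timepoint, same site),
#' ages drawn near `cohort_age`; otherwise ages are uniform on `age_range`.
#'
#' @param config a [sim_config()].
#' @param truth a [make_ground_truth()] result from the same config grid.
#' @param longitudinal logical; add a second timepoint.
#' @param groups character subset of `c("patient", "control")` (a
#'   healthy-only training cohort uses `groups = "control"`).
#' @param n named integer vector of per-group sizes; defaults to
#'   `config$n_per_group` for every group.
#' @param cohort cohort label written into the phenotype table.
#' @param seed RNG seed for this dataset; defaults to `config$seed`.
#' @return list with `stack` (a [gm_stack()], one row per subject-timepoint)
#'   and `pheno` (data.frame with columns subject_id, cohort, group, age,
#'   sex, site, timepoint, tiv, duration, true_expression), rows aligned.
#' @export
simulate_cohort <- function(config, truth, longitudinal = FALSE,
                            groups = c("patient", "control"), n = NULL,
                            cohort = "cohort1", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (!identical(truth$grid_shape, config$grid_shape))
    stop("truth was generated for a different grid")
  groups <- match.arg(groups, c("patient", "control"), several.ok = TRUE)
  if (is.null(n)) n <- setNames(rep(config$n_per_group, length(groups)), groups)
  if (is.null(names(n))) names(n) <- groups
  if (any(n < 2)) stop("need at least 2 subjects per group")

  with_seed(seed, {
    group <- rep(names(n), n)
    nsub <- length(group)
    id <- sprintf("%s_%04d", cohort, seq_len(nsub))
    age0 <- if (longitudinal) {
      rnorm(nsub, config$cohort_age, config$cohort_age_sd)
    } else {
      runif(nsub, config$age_range[1], config$age_range[2])
    }
    sex <- rbinom(nsub, 1, 0.5)
    nsite <- length(config$site_offset)
    site <- sample.int(nsite, nsub, replace = TRUE)
    tiv <- 1350 + 150 * sex + rnorm(nsub, 0, 100)
    dur0 <- ifelse(group == "patient",
                   runif(nsub, config$duration_range[1],
                         config$duration_range[2]), 0)

    tps <- if (longitudinal) c(0L, 1L) else 0L
    rows <- do.call(rbind, lapply(tps, function(tp) {
      data.frame(subject_id = id, cohort = cohort, group = group,
                 age = age0 + tp * config$followup_gap, sex = sex,
                 site = site, timepoint = tp, tiv = tiv,
                 duration = ifelse(group == "patient",
                                   dur0 + tp * config$followup_gap, NA_real_),
                 stringsAsFactors = FALSE)
    }))
    delta_amp <- config$disorder_effect * config$noise_sd
    dur_eff <- ifelse(is.na(rows$duration), 0, rows$duration)
    rows$true_expression <- ifelse(
      rows$group == "patient",
      delta_amp * (1 + config$progression_rate * dur_eff), 0)

    V <- prod(config$grid_shape)
    nobs <- nrow(rows)
    clean <- matrix(rep(truth$baseline, each = nobs), nrow = nobs)
    clean <- clean -
      outer(config$aging_slope * rows$age, truth$aging_pattern) -
      outer(rows$true_expression, truth$disorder_pattern)
    data <- clean * config$site_scale[rows$site] +
      config$site_offset[rows$site] +
      matrix(rnorm(nobs * V, 0, config$noise_sd), nrow = nobs)
    data[data < 0] <- 0
    ids <- paste0(rows$subject_id, "_tp", rows$timepoint)
    stack <- gm_stack(data, config$grid_shape, config$voxel_size_mm,
                      subject_ids = ids)
    list(stack = stack, pheno = rows)
  })
}

#' Attach clinical variables and binary outcomes to a phenotype table
#'
#' Gaussian couplings generate, for patients only,
#' `slope * z(expression) + N(0, noise_sd)` where `z(expression)` is the
#' patients' standardized pattern expression (disorder pattern: the planted
#' `true_expression`; aging pattern: `aging_slope * age`). Binary couplings
#' draw outcomes from `plogis(intercept + slope * z(expression))` (the
#' intercept, default -1, sets the base rate). Controls receive NA.
#'
#' @param pheno phenotype table from [simulate_cohort()].
#' @param truth the matching [make_ground_truth()] object.
#' @param config the [sim_config()]; its `clinical_couplings` are used
#'   unless `couplings` is given.
#' @param couplings optional list overriding `config$clinical_couplings`.
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return the phenotype table with one extra column per coupling.
#' @export
attach_clinical <- function(pheno, truth, config, couplings = NULL,
                            seed = config$seed + 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(couplings)) couplings <- config$clinical_couplings
  pat <- pheno$group == "patient"
  if (!any(pat)) stop("no patients to attach clinical variables to")
  with_seed(seed, {
    for (cp in couplings) {
      expr <- switch(cp$pattern,
        disorder = pheno$true_expression,
        aging = config$aging_slope * pheno$age,
        stop("unknown pattern name: ", cp$pattern))
      ze <- expr[pat]
      s <- sd(ze)
      ze <- if (is.na(s) || s < 1e-12) ze - mean(ze) else (ze - mean(ze)) / s
      val <- rep(NA_real_, nrow(pheno))
      if (identical(cp$type, "binary")) {
        val[pat] <- rbinom(sum(pat), 1,
                           plogis((cp$intercept %||% -1) + cp$slope * ze))
      } else {
        val[pat] <- cp$slope * ze + rnorm(sum(pat), 0, cp$noise_sd)
      }
      pheno[[cp$name]] <- val
    }
    pheno
  })
}
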