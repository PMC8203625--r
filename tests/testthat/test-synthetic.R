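# Synthetic cohort generator: determinism, planted-pattern geometry,
# effect-size recovery, longitudinal consistency, clinical couplings.

test_that("identical config and seed reproduce the identical dataset", {
  cfg <- sim_config(grid_shape = c(8, 8, 8), seed = 7)
  t1 <- make_ground_truth(cfg)
  t2 <- make_ground_truth(cfg)
  expect_identical(t1, t2)
  a <- simulate_cohort(cfg, t1, n = c(patient = 12, control = 12))
  b <- simulate_cohort(cfg, t1, n = c(patient = 12, control = 12))
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$pheno, b$pheno)
  c2 <- attach_clinical(a$pheno, t1, cfg)
  c3 <- attach_clinical(b$pheno, t1, cfg)
  expect_identical(c2, c3)
})

test_that("zero overlap fraction gives disjoint pattern supports", {
  for (seed in 1:5) {
    cfg <- sim_config(grid_shape = c(10, 8, 8), overlap_fraction = 0,
                      seed = seed)
    tr <- make_ground_truth(cfg)
    # oracle: explicit mask intersection
    expect_length(intersect(tr$disorder_idx, tr$aging_idx), 0)
    expect_gt(length(tr$disorder_idx), 0)
    expect_setequal(which(tr$disorder_pattern > 0), tr$disorder_idx)
  }
})

test_that("requested overlap fraction is honoured up to column rounding", {
  cfg <- sim_config(grid_shape = c(12, 12, 12), overlap_fraction = 0.5,
                    seed = 3)
  tr <- make_ground_truth(cfg)
  got <- length(intersect(tr$disorder_idx, tr$aging_idx)) /
    length(tr$disorder_idx)
  expect_equal(got, 0.5, tolerance = 0.26)  # whole-column granularity
})

test_that("degenerate grids and parameters are rejected", {
  expect_error(sim_config(grid_shape = c(2, 8, 8)), "grid_shape")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(disorder_effect = -1), "disorder_effect")
  cfg <- sim_config(grid_shape = c(8, 8, 8))
  tr <- make_ground_truth(cfg)
  expect_error(simulate_cohort(cfg, tr, n = c(patient = 1, control = 5)),
               "at least 2")
})

test_that("null model: zero effect gives near-zero group separation", {
  cfg <- clean_config(disorder_effect = 0, seed = 11)
  tr <- make_ground_truth(cfg)
  sim <- simulate_cohort(cfg, tr, n = c(patient = 100, control = 100))
  g <- sim$pheno$group
  pm <- rowMeans(sim$stack$data[, tr$disorder_idx, drop = FALSE])
  d <- (mean(pm[g == "patient"]) - mean(pm[g == "control"])) / sd(pm)
  expect_lt(abs(d), 0.2)
})

test_that("planted standardized effect size is recovered as Cohen's d", {
  cfg <- clean_config(disorder_effect = 0.8, seed = 13)
  tr <- make_ground_truth(cfg)
  sim <- simulate_cohort(cfg, tr, n = c(patient = 100, control = 100))
  g <- sim$pheno$group
  # oracle: direct two-sample pooled-SD d per pattern voxel
  ds <- vapply(tr$disorder_idx, function(v) {
    x <- sim$stack$data[g == "control", v]
    y <- sim$stack$data[g == "patient", v]
    (mean(x) - mean(y)) /
      sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
             (length(x) + length(y) - 2))
  }, 0)
  expect_lt(abs(mean(ds) - 0.8), 0.15)
})

test_that("near-noiseless group difference equals the planted amplitude", {
  # amplitude in density units is delta * noise_sd; with baseline lifted
  # away from the clipping floor and noise_sd = 1 the patient-control
  # difference at pattern voxels is delta * (1 + rho * duration)
  cfg <- clean_config(disorder_effect = 0.5, noise_sd = 1,
                      baseline_mean = 20, seed = 17)
  tr <- make_ground_truth(cfg)
  sim <- simulate_cohort(cfg, tr, n = c(patient = 500, control = 500))
  g <- sim$pheno$group
  diff <- colMeans(sim$stack$data[g == "control", tr$disorder_idx]) -
    colMeans(sim$stack$data[g == "patient", tr$disorder_idx])
  # 3 standard errors of the mean difference over the pattern voxels
  expect_equal(mean(diff), 0.5,
               tolerance = 3 * sqrt(2 / 500) / sqrt(27) / 0.5)
})

test_that("control voxel means and SDs converge to B(v) and noise_sd", {
  cfg <- clean_config(seed = 19, baseline_mean = 0.6)
  tr <- make_ground_truth(cfg)
  sim <- simulate_cohort(cfg, tr, groups = "control", n = c(control = 500))
  mu <- colMeans(sim$stack$data)
  sg <- apply(sim$stack$data, 2, sd)
  n <- 500
  z_mu <- (mu - tr$baseline) / (cfg$noise_sd / sqrt(n))
  z_sg <- (sg - cfg$noise_sd) / (cfg$noise_sd / sqrt(2 * n))
  expect_lt(mean(abs(z_mu) > 3), 0.01)
  expect_lt(mean(abs(z_sg) > 3), 0.02)
})

test_that("longitudinal cohorts are internally consistent", {
  cfg <- sim_config(grid_shape = c(8, 8, 8), seed = 23)
  tr <- make_ground_truth(cfg)
  sim <- simulate_cohort(cfg, tr, longitudinal = TRUE,
                         n = c(patient = 15, control = 20))
  ph <- sim$pheno
  expect_false(any(duplicated(paste(ph$subject_id, ph$timepoint))))
  expect_setequal(ph$subject_id[ph$timepoint == 0],
                  ph$subject_id[ph$timepoint == 1])
  a0 <- ph$age[match(unique(ph$subject_id),
                     ph$subject_id[ph$timepoint == 0])]
  a1 <- ph$age[ph$timepoint == 1][match(unique(ph$subject_id),
                                        ph$subject_id[ph$timepoint == 1])]
  expect_true(all(abs((a1 - a0) - cfg$followup_gap) < 1e-9))
  expect_equal(nrow(sim$stack$data), nrow(ph))
})

test_that("expected separation grows with duration at the planted slope", {
  cfg <- clean_config(disorder_effect = 0.8, progression_rate = 0.05,
                      noise_sd = 0.02, duration_range = c(0, 30),
                      seed = 29)
  tr <- make_ground_truth(cfg)
  sim <- simulate_cohort(cfg, tr, n = c(patient = 300, control = 300))
  ph <- sim$pheno
  pat <- ph$group == "patient"
  # per-patient mean deficit over pattern voxels vs control mean
  ctrl_mu <- colMeans(sim$stack$data[!pat, tr$disorder_idx])
  deficit <- colMeans(t(sim$stack$data[pat, tr$disorder_idx]) - ctrl_mu) * -1
  fit <- lm(deficit ~ ph$duration[pat])
  expected_slope <- cfg$disorder_effect * cfg$noise_sd * cfg$progression_rate
  expect_equal(unname(coef(fit)[2]), expected_slope, tolerance = 0.15)
})

test_that("densities are clipped at zero, biasing low-baseline means up", {
  cfg <- clean_config(baseline_mean = 0.02, noise_sd = 0.1, seed = 31)
  tr <- make_ground_truth(cfg)
  sim <- simulate_cohort(cfg, tr, groups = "control", n = c(control = 200))
  expect_true(all(sim$stack$data >= 0))
  expect_gt(mean(sim$stack$data), mean(tr$baseline))
})

test_that("clinical couplings reproduce their planted correlations", {
  cfg <- clean_config(progression_rate = 0.05, seed = 37)
  tr <- make_ground_truth(cfg)
  sim <- simulate_cohort(cfg, tr, n = c(patient = 500, control = 20))
  pat <- sim$pheno$group == "patient"

  zero <- list(list(name = "v0", pattern = "disorder", slope = 0,
                    noise_sd = 1, type = "gaussian"))
  ph <- attach_clinical(sim$pheno, tr, cfg, couplings = zero)
  expect_lt(abs(cor(ph$v0[pat], ph$true_expression[pat])), 0.12)

  exact <- list(list(name = "v1", pattern = "disorder", slope = 1,
                     noise_sd = 0, type = "gaussian"))
  ph <- attach_clinical(sim$pheno, tr, cfg, couplings = exact)
  expect_equal(cor(ph$v1[pat], ph$true_expression[pat]), 1)

  # analytic R^2 = slope^2 / (slope^2 + noise^2) on the standardized
  # expression; slope 0.5 with noise sqrt(0.75) gives 0.25
  r25 <- list(list(name = "v2", pattern = "disorder", slope = 0.5,
                   noise_sd = sqrt(0.75), type = "gaussian"))
  ph <- attach_clinical(sim$pheno, tr, cfg, couplings = r25)
  r2 <- cor(ph$v2[pat], ph$true_expression[pat])^2
  expect_equal(r2, 0.25, tolerance = 0.07)

  expect_error(
    attach_clinical(sim$pheno, tr, cfg,
                    couplings = list(list(name = "x", pattern = "nope",
                                          slope = 1, noise_sd = 1,
                                          type = "gaussian"))),
    "unknown pattern")
})

test_that("binary outcomes follow the logistic link direction", {
  cfg <- clean_config(progression_rate = 0.08, seed = 41)
  tr <- make_ground_truth(cfg)
  sim <- simulate_cohort(cfg, tr, n = c(patient = 400, control = 10))
  ph <- attach_clinical(sim$pheno, tr, cfg)
  pat <- ph$group == "patient"
  # remission couples negatively to disorder expression
  expect_lt(mean(ph$true_expression[pat][ph$remission[pat] == 1]),
            mean(ph$true_expression[pat][ph$remission[pat] == 0]))
  expect_true(all(is.na(ph$remission[!pat])))
})
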