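# Shared small fixtures for the test suite. Everything is generated in
# code under fixed seeds; no data files.

# small grid, single site, no aging/progression: the cleanest setting for
# effect-size recovery checks
clean_config <- function(...) {
  args <- list(grid_shape = c(8, 8, 8), site_offset = 0, site_scale = 1,
               aging_slope = 0, progression_rate = 0, overlap_fraction = 0)
  do.call(sim_config, modifyList(args, list(...)))
}

# tiny random stack for preprocessing unit tests
random_stack <- function(n = 12, shape = c(4, 4, 3), seed = 1,
                         voxel = c(2, 2, 2)) {
  with_seed <- brainpattern:::with_seed
  with_seed(seed, {
    gm_stack(matrix(runif(n * prod(shape), 0.2, 0.8), n), shape, voxel)
  })
}

# brute-force AUC by exhaustive pair counting (ties count one half)
pairwise_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
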