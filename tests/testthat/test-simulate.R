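test_that("cohort simulation is bit-reproducible from the seed", {
  cfg <- sim_config(n_biomolecules = c(protein = 40), size_factor = 0.1,
                    seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(unclass(a$tumor$protein), unclass(b$tumor$protein))
  expect_identical(unclass(a$normal$protein), unclass(b$normal$protein))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$de, b$truth$de)
})

test_that("with decay off the differential effect is time-invariant", {
  cfg <- sim_config(n_biomolecules = c(protein = 200),
                    group_sizes = c(T1 = 120, T5 = 120),
                    decay_rate = c(protein = 0),
                    confounder_effects = c(grade_high = 0, stage_IV = 0,
                                           alcohol_active = 0),
                    missingness_base = 0, missingness_time_slope = 0,
                    seed = 4)
  ch <- simulate_cohort(cfg)
  design <- paired_design(ch$metadata)
  fc <- unclass(log2_fold_changes(ch$tumor$protein, ch$normal$protein,
                                  design))
  md <- assign_time_groups(ch$truth$covariates, time_schemes("refined_3min"))
  de <- ch$truth$de
  for (i in seq_len(5)) {
    id <- de$biomolecule_id[i]
    for (grp in c("T1", "T5")) {
      pats <- md$patient_id[md$time_group == grp]
      mc_se <- cfg$noise_sd * sqrt(2 / length(pats))
      expect_equal(mean(fc[id, pats]), de$effect[i],
                   tolerance = 5 * mc_se / abs(de$effect[i]))
    }
  }
})

test_that("decay shrinks the differential effect by the closed-form factor", {
  # one group far beyond onset: drift factor f = min(1, rate * (t - onset))
  cfg <- sim_config(n_biomolecules = c(protein = 300),
                    group_sizes = c(T5 = 500),
                    decay_rate = c(protein = 0.05), decay_onset_min = 10,
                    decaying_fraction = 1,
                    confounder_effects = c(grade_high = 0, stage_IV = 0,
                                           alcohol_active = 0),
                    missingness_base = 0, missingness_time_slope = 0,
                    seed = 8)
  ch <- simulate_cohort(cfg)
  design <- paired_design(ch$metadata)
  fc <- unclass(log2_fold_changes(ch$tumor$protein, ch$normal$protein,
                                  design))
  t_of <- setNames(ch$truth$covariates$ischemia_min,
                   ch$truth$covariates$patient_id)
  de <- ch$truth$de
  for (i in seq_len(8)) {
    id <- de$biomolecule_id[i]
    f <- pmin(1, 0.05 * (t_of[colnames(fc)] - 10))
    expected <- mean((1 - f)) * de$effect[i]
    # residual noise per patient: 2 base + 2 decay-step draws
    mc_se <- 2 * cfg$noise_sd / sqrt(ncol(fc))
    expect_lt(abs(mean(fc[id, ]) - expected), 4 * mc_se)
  }
})

test_that("group sizes below 2 are rejected", {
  expect_error(sim_config(group_sizes = c(T1 = 1, T2 = 10)), "at least 2")
  expect_error(sim_config(true_de_fraction = 1.5), "fractions")
  expect_error(sim_config(noise_sd = 0), "positive")
})

test_that("DNA submodalities are reproducible and honour explicit rates", {
  cfg <- sim_config(size_factor = 0.1, n_loci = 50, seed = 3)
  a <- simulate_dna_submodalities(cfg)
  b <- simulate_dna_submodalities(cfg)
  expect_identical(unclass(a$matrices$PAM), unclass(b$matrices$PAM))
  probs <- rep(0.2, 50); probs[7] <- 0
  d <- simulate_dna_submodalities(cfg, binary_probs = probs)
  expect_true(all(unclass(d$matrices$CNV_amp)[7, ] == 0))
  expect_true(all(unclass(d$matrices$CNV_amp) %in% c(0, 1)))
})

test_that("trajectory fixture is reproducible, labelled and separated", {
  sim <- simulate_trajectories(k_clusters = 3, n_per_cluster = 20,
                               timepoints = 5, separation = 5,
                               noise_sd = 0.5, seed = 6)
  sim2 <- simulate_trajectories(3, 20, 5, 5, 0.5, seed = 6)
  expect_identical(sim$trajectories, sim2$trajectories)
  expect_equal(sort(unique(sim$labels)), 1:3)

  # separation = 10 * noise_sd: clusters linearly separable at every timepoint
  for (tp in 1:5) {
    v <- sim$trajectories[, tp]
    rng <- tapply(v, sim$labels, range)
    for (k in 1:2) expect_lt(rng[[k]][2], rng[[k + 1]][1])
  }

  one <- simulate_trajectories(1, 10, 4, 3, 0.2, seed = 1)
  expect_true(all(one$labels == 1))
})
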