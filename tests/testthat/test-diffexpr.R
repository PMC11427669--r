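test_that("paired Wilcoxon matches sign-flip enumeration on small samples", {
  # all-positive differences, n = 6: W = 21, exact p = 2/64
  res <- paired_wilcoxon(7:12, 6:1, min_pairs = 5)
  expect_equal(res$statistic, 21)
  expect_equal(res$p, 2 / 64)
  expect_equal(res$p, enumerate_signed_rank_p(7:12 - 6:1))

  set.seed(11)
  for (n in c(5, 7, 10)) {
    for (rep in 1:5) {
      d <- round(rnorm(n, 0.3, 1), 4)
      d <- d + seq_len(n) * 1e-6  # break accidental magnitude ties
      res <- paired_wilcoxon(d, rep(0, n), min_pairs = 5)
      expect_equal(res$p, enumerate_signed_rank_p(d), tolerance = 1e-12)
    }
  }
})

test_that("paired Wilcoxon conventions: zeros, ties, few pairs", {
  x <- c(3, 4, 5, 6, 7)
  expect_equal(paired_wilcoxon(x, x)$p, 1)
  tie <- paired_wilcoxon(c(1, 0), c(0, 1), min_pairs = 2)
  expect_equal(tie$p, 1)
  few <- paired_wilcoxon(1:3, 4:6, min_pairs = 5)
  expect_true(is.na(few$p))
  expect_equal(few$n_pairs, 3L)
  na_side <- paired_wilcoxon(c(1:6, NA), c(0, 0, 0, 0, 0, 0, 5))
  expect_equal(na_side$n_pairs, 6L)
})

test_that("paired Wilcoxon is calibrated under a symmetric null", {
  set.seed(21)
  p <- replicate(500, paired_wilcoxon(rnorm(20), rnorm(20))$p)
  rej <- mean(p < 0.05)
  expect_lt(rej, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 500))
})

test_that("BH adjustment equals its brute-force definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 10)), rep(0.05, 10))

  set.seed(31)
  for (rep in 1:10) {
    p <- runif(50)^2
    expect_equal(bh_adjust(p), bh_brute_force(p), tolerance = 1e-12)
  }
  # NAs pass through and are excluded from m
  p <- c(0.01, NA, 0.03)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bh_brute_force(c(0.01, 0.03)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential selection applies both the FDR and effect boundary", {
  # null case: tumor == normal everywhere selects nothing
  set.seed(41)
  vals <- matrix(rnorm(100 * 12, 10), 100, 12)
  tum <- toy_expr(vals, samples = sprintf("p%02d_T", 1:12))
  nrm <- toy_expr(vals, samples = sprintf("p%02d_N", 1:12))
  design <- tibble::tibble(patient_id = sprintf("p%02d", 1:12),
                           tumor_sample_id = colnames(tum),
                           normal_sample_id = colnames(nrm))
  res <- select_differential(tum, nrm, design)
  expect_equal(sum(res$selected), 0L)
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))

  # significant but central effect is excluded by the percentile boundary
  set.seed(42)
  n_pat <- 20
  vals <- matrix(rnorm(100 * n_pat, 10), 100, n_pat)
  tum_v <- vals
  tum_v[1:5, ] <- tum_v[1:5, ] + 3       # large positive effects
  tum_v[6:10, ] <- tum_v[6:10, ] - 3     # large negative effects
  tum_v[11, ] <- vals[11, ] + 0.05       # significant, near-median effect
  tum <- toy_expr(tum_v, samples = sprintf("p%02d_T", 1:n_pat))
  nrm <- toy_expr(vals, samples = sprintf("p%02d_N", 1:n_pat))
  design <- tibble::tibble(patient_id = sprintf("p%02d", 1:n_pat),
                           tumor_sample_id = colnames(tum),
                           normal_sample_id = colnames(nrm))
  res <- select_differential(tum, nrm, design)
  r11 <- res[res$biomolecule_id == "b011", ]
  expect_lt(r11$p_adj, 0.01)
  expect_false(r11$selected)
  expect_true(all(res$selected[1:10]))
})

test_that("selection results are invariant to biomolecule and pair order", {
  cfg <- sim_config(n_biomolecules = c(protein = 80),
                    group_sizes = c(T1 = 30), decay_rate = c(protein = 0),
                    seed = 12)
  ch <- simulate_cohort(cfg)
  design <- paired_design(ch$metadata)
  res <- select_differential(ch$tumor$protein, ch$normal$protein, design)

  perm <- sample(nrow(ch$tumor$protein))
  tum_p <- ch$tumor$protein[perm, , drop = FALSE]
  nrm_p <- ch$normal$protein[perm, , drop = FALSE]
  res_p <- select_differential(
    expression_matrix(tum_p, "protein", "log2_intensity"),
    expression_matrix(nrm_p, "protein", "log2_intensity"), design)
  expect_equal(dplyr::arrange(res_p, biomolecule_id),
               dplyr::arrange(res, biomolecule_id))

  res_d <- select_differential(ch$tumor$protein, ch$normal$protein,
                               design[sample(nrow(design)), ])
  expect_equal(dplyr::arrange(res_d, biomolecule_id),
               dplyr::arrange(res, biomolecule_id))
})

test_that("intergroup shifts respect the fold band and FDR rule", {
  set.seed(51)
  n1 <- 15; n2 <- 15
  fc <- matrix(rnorm(60 * (n1 + n2), 0, 0.05), 60)
  fc[1, (n1 + 1):(n1 + n2)] <- fc[1, (n1 + 1):(n1 + n2)] + 0.6
  fc[2, (n1 + 1):(n1 + n2)] <- fc[2, (n1 + 1):(n1 + n2)] + 0.4
  m <- toy_expr(fc, scale = "log2_fc",
                samples = sprintf("p%02d", seq_len(n1 + n2)))
  g <- rep(c("T1", "T2"), c(n1, n2))
  res <- intergroup_shift(m, g)
  r1 <- res[res$biomolecule_id == "b001", ]
  r2 <- res[res$biomolecule_id == "b002", ]
  expect_true(r1$reported)
  expect_equal(r1$direction, "up")
  expect_lt(r2$p_adj, 0.01)
  expect_false(r2$reported)  # |0.4| < 0.5 band

  # identical distributions: nothing reported
  null_res <- intergroup_shift(toy_expr(matrix(rnorm(60 * 30, 0, 0.5), 60),
                                        scale = "log2_fc"), g)
  expect_equal(sum(null_res$reported), 0L)

  expect_warning(
    intergroup_shift(m, rep(c("T1", "T2"), c(27, 3))),
    "skipped")
})
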