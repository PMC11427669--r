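test_that("SRH matches the rank two-way ANOVA oracle on balanced designs", {
  # pure tissue shift, no noise
  a <- rep(c("tumor", "normal"), each = 10)
  b <- rep(rep(paste0("T", 1:5), each = 2), 2)
  y <- ifelse(a == "tumor", 10, 5)
  fit <- srh_test(y, a, b)
  orc <- srh_oracle(y, a, b)
  expect_equal(fit$table$statistic,
               unname(orc$H[c("tissue", "time", "interaction")]),
               tolerance = 1e-10)
  expect_gt(fit$table$statistic[1], 10)
  expect_equal(fit$table$statistic[2], 0)

  set.seed(61)
  for (rep in 1:8) {
    n_cell <- 4
    a <- rep(c("tumor", "normal"), each = n_cell * 3)
    b <- rep(rep(paste0("T", 1:3), each = n_cell), 2)
    y <- rnorm(length(a)) + (a == "tumor") * rnorm(1) +
      as.integer(factor(b)) * rnorm(1, 0, 0.5)
    fit <- srh_test(y, a, b)
    orc <- srh_oracle(y, a, b)
    expect_equal(fit$table$statistic,
                 unname(orc$H[c("tissue", "time", "interaction")]),
                 tolerance = 1e-10)
  }
})

test_that("SRH sums of squares decompose and ties are handled", {
  set.seed(62)
  a <- rep(c("tumor", "normal"), each = 12)
  b <- rep(rep(paste0("T", 1:4), each = 3), 2)
  y <- round(rnorm(24), 1)  # induces ties
  fit <- srh_test(y, a, b)
  rss_full <- sum(lm(rank(y) ~ factor(a) * factor(b))$residuals^2)
  expect_equal(unname(fit$ss["total"]),
               unname(fit$ss["tissue"] + fit$ss["time"] +
                        fit$ss["interaction"]) + rss_full,
               tolerance = 1e-8)
  expect_true(all(fit$table$statistic >= 0))
  expect_lt(fit$tie_D, 1)

  flat <- srh_test(rep(3, 24), a, b)
  expect_equal(flat$table$p.value, rep(1, 3))

  expect_error(srh_test(y, rep("tumor", 24), b), "two levels")
})

test_that("SRH is invariant under strictly monotone transforms", {
  set.seed(63)
  a <- rep(c("tumor", "normal"), each = 15)
  b <- rep(rep(paste0("T", 1:5), each = 3), 2)
  y <- rnorm(30, 8, 2)
  f1 <- srh_test(y, a, b)
  f2 <- srh_test(exp(y / 2), a, b)
  expect_equal(f1$table$statistic, f2$table$statistic, tolerance = 1e-12)
})

test_that("SRH screen concentrates time effects on decaying biomolecules", {
  cfg <- sim_config(n_biomolecules = c(phosphosite = 150),
                    size_factor = 0.5,
                    decay_rate = c(phosphosite = 0.12),
                    decaying_fraction = 0.3,
                    missingness_base = 0, missingness_time_slope = 0,
                    seed = 13)
  ch <- simulate_cohort(cfg)
  md <- assign_time_groups(ch$metadata, time_schemes("refined_3min")) |>
    dplyr::filter(time_group != "over") |>
    dplyr::mutate(time_group = droplevels(time_group))
  both <- cbind(unclass(ch$tumor$phosphosite),
                unclass(ch$normal$phosphosite))[, md$sample_id]
  scr <- srh_screen(expression_matrix(both, "phosphosite", "log2_intensity"),
                    md, alpha_fdr = 0.05)
  time_sig <- scr$per_biomolecule |>
    dplyr::filter(effect == "time", p_adj < 0.05)
  decaying <- ch$truth$decaying$biomolecule_id
  sens <- mean(decaying %in% time_sig$biomolecule_id)
  fpr <- mean(setdiff(rownames(both), decaying) %in% time_sig$biomolecule_id)
  expect_gt(sens, 0.7)
  expect_lt(fpr, 0.1)
  # single implicit cluster: totals row equals the cluster row
  expect_equal(scr$summary$time[1], scr$summary$time[2])
})

test_that("Kruskal-Wallis screen matches the rank formula and conventions", {
  y <- c(1, 3, 2, 6, 8, 7, 12, 15, 11)  # distinct: no tie correction
  g <- rep(c("T1", "T2", "T3"), each = 3)
  res <- kruskal_mutation_load(
    toy_expr(matrix(c(y, rep(2, 9)), 2, 9, byrow = TRUE), "PAM",
             "count", samples = paste0("s", 1:9)), g)
  expect_equal(res$statistic[1], kw_oracle(y, g), tolerance = 1e-10)
  expect_equal(res$p[2], 1)  # constant locus convention

  # null loci: nothing significant after BH
  cfg <- sim_config(size_factor = 0.2, n_loci = 300, seed = 14)
  dna <- simulate_dna_submodalities(cfg)
  glab <- assign_time_groups(dna$metadata,
                             time_schemes("refined_3min"))$time_group
  scr <- kruskal_mutation_load(dna$matrices$PAM, setNames(
    as.character(glab), dna$metadata$sample_id))
  expect_lt(attr(scr, "fraction_significant"), 0.01)
})

test_that("Fisher screen matches hypergeometric enumeration", {
  # [[10,0],[0,10]]: both margins 10, p = 2 / choose(20, 10)
  bin <- matrix(c(rep(1, 10), rep(0, 10)), 1, 20,
                dimnames = list("L1", paste0("s", 1:20)))
  g <- rep(c("T2", "T1"), each = 10)
  res <- fisher_binary_vs_reference(
    expression_matrix(bin, "CNV_amp", "binary"), g, "T1")
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)

  even <- matrix(rep(c(1, 0), 10), 1, 20,
                 dimnames = list("L1", paste0("s", 1:20)))
  res_even <- fisher_binary_vs_reference(
    expression_matrix(even, "CNV_amp", "binary"), g, "T1")
  expect_equal(res_even$p, 1)

  zero <- matrix(0, 1, 20, dimnames = list("L1", paste0("s", 1:20)))
  res_zero <- fisher_binary_vs_reference(
    expression_matrix(zero, "CNV_del", "binary"), g, "T1")
  expect_equal(res_zero$p, 1)

  expect_error(fisher_binary_vs_reference(
    expression_matrix(zero, "CNV_del", "binary"), g, "T9"), "T9")
})
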