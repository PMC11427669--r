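test_that("extreme set follows the interpolated quantile definition", {
  m <- toy_expr(matrix(1:100, 100, 1), ids = sprintf("b%03d", 1:100))
  es <- extreme_set(m, "s001")
  expect_equal(unname(es$bounds), c(3.475, 97.525))
  expect_equal(sort(es$members),
               sprintf("b%03d", c(1, 2, 3, 98, 99, 100)))

  flat <- toy_expr(matrix(5, 30, 2))
  expect_equal(length(extreme_set(flat, c("s001", "s002"))$members), 0L)

  set.seed(71)
  rnd <- toy_expr(matrix(rnorm(500), 500, 1))
  frac <- length(extreme_set(rnd, "s001")$members) / 500
  expect_equal(frac, 0.05, tolerance = 0.3)

  expect_error(extreme_set(toy_expr(matrix(1:10, 10, 1)), "s001"), ">= 20")
})

test_that("extreme membership is invariant to affine transforms", {
  set.seed(72)
  vals <- matrix(rnorm(200, 10, 3), 200, 4)
  m <- toy_expr(vals)
  m2 <- toy_expr(vals * 2.7 + 11)
  smp <- colnames(m)
  expect_equal(extreme_set(m, smp)$members, extreme_set(m2, smp)$members)
})

test_that("relative loss implements the set-difference percentage", {
  expect_equal(relative_loss(c("a", "b"), c("a", "b")), 0)
  expect_equal(relative_loss(c("a", "b"), c("c", "d")), 100)
  expect_equal(relative_loss(c("a", "b", "c", "d"), c("c", "d", "e")), 50)
  expect_error(relative_loss(character(), "a"), "empty")

  # anti-monotone in the overlap
  ref <- letters[1:10]
  other <- letters[5:8]
  expect_gte(relative_loss(ref, other), relative_loss(ref, c(other, "a")))
})

test_that("differential-set loss covers the printed examples", {
  sets <- list(T1 = sprintf("g%02d", 1:10),
               T2 = sprintf("g%02d", 1:10),
               T3 = sprintf("g%02d", 5:10),
               T5 = c("x1", "x2"))
  loss <- de_set_difference_loss(sets)
  expect_equal(loss$loss_pct, c(0, 40, 100))
  expect_equal(loss$group, c("T2", "T3", "T5"))
  expect_error(de_set_difference_loss(list(T1 = character(), T2 = "a")),
               "empty")
})

test_that("extreme loss table has a zero diagonal against itself", {
  set.seed(73)
  cfg <- sim_config(n_biomolecules = c(protein = 120), size_factor = 0.2,
                    decay_rate = c(protein = 0), seed = 15)
  ch <- simulate_cohort(cfg)
  md <- assign_time_groups(ch$metadata, time_schemes("refined_3min")) |>
    dplyr::filter(time_group != "over") |>
    dplyr::mutate(time_group = droplevels(time_group))
  tbl <- extreme_loss_table(ch$tumor$protein, ch$normal$protein, md)
  expect_true(all(tbl$loss_pct >= 0 & tbl$loss_pct <= 100))
  expect_setequal(unique(tbl$tissue), c("tumor", "normal"))

  # comparing a group against itself gives zero loss
  md_t1 <- dplyr::filter(md, time_group == "T1")
  s1 <- extreme_set(ch$tumor$protein,
                    md_t1$sample_id[md_t1$tissue == "tumor"])
  expect_equal(relative_loss(s1, s1), 0)
})

test_that("cut-off rule picks the last contiguous qualifying group", {
  scheme <- time_schemes("refined_3min")
  mk_loss <- function(l) tidyr::expand_grid(
    modality = c("mRNA", "protein"), group = paste0("T", 2:5)) |>
    dplyr::mutate(loss_pct = rep(l, 2))
  mk_coef <- function(v) tidyr::expand_grid(
    modality = c("mRNA", "protein"), group = paste0("T", 2:5)) |>
    dplyr::mutate(mean_abs_coef = rep(v, 2))
  stage4 <- tibble::tibble(modality = c("mRNA", "protein"),
                           mean_abs_coef = 0.5)

  # criteria hold through T2 (<= 12 min), fail from T3 on
  rep12 <- recommend_cutoff(mk_loss(c(10, 60, 70, 90)),
                            mk_coef(c(0.2, 0.8, 0.9, 1.2)), stage4, scheme)
  expect_equal(rep12$recommendation_min, 12)
  expect_equal(rep12$recommended_group, "T2")

  # nothing binds: recommendation is the last group bound
  all_ok <- recommend_cutoff(mk_loss(rep(5, 4)), mk_coef(rep(0.1, 4)),
                             stage4, scheme)
  expect_equal(all_ok$recommendation_min, 20)

  # strictest rule: nothing qualifies, fall back to the reference bound
  expect_warning(
    none <- recommend_cutoff(mk_loss(c(10, 60, 70, 90)),
                             mk_coef(c(0.2, 0.8, 0.9, 1.2)), stage4,
                             scheme, loss_threshold = 0),
    "no group")
  expect_equal(none$recommendation_min, 10)

  # a later group passing after a failure does not extend the prefix
  gap <- recommend_cutoff(mk_loss(c(10, 60, 10, 10)),
                          mk_coef(c(0.2, 0.8, 0.2, 0.2)), stage4, scheme)
  expect_equal(gap$recommendation_min, 12)
})
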