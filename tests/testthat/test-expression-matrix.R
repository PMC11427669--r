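test_that("TSV parsing flags missing cells, duplicates and bad values", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "g1\t1.5\tNA", "g2\t2\t3", "g3\t\t4"), tmp)
  m <- read_expression_matrix(tmp, "protein", "log2_intensity")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(is.na(m)), 2L)
  expect_equal(unclass(m)["g2", "s2"], 3)

  writeLines(c("id\ts1\ts1", "g1\t1\t2"), tmp)
  expect_error(read_expression_matrix(tmp, "protein", "log2_intensity"),
               "s1")
  writeLines(c("id\ts1", "g1\tabc"), tmp)
  expect_error(read_expression_matrix(tmp, "protein", "log2_intensity"),
               "g1.*s1")
})

test_that("write/read round trip is bit-exact for finite entries", {
  set.seed(42)
  m <- toy_expr(matrix(rnorm(30) * 1e3, 6, 5))
  m[2, 3] <- NA
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, tmp)
  m2 <- read_expression_matrix(tmp, "protein", "log2_intensity")
  expect_identical(unclass(m2), unclass(m))
})

test_that("modality/scale invariants are enforced", {
  bad_bin <- matrix(c(0, 1, 2, 0), 2, 2,
                    dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(bad_bin, "CNV_amp", "binary"), "binary")
  bad_cnt <- matrix(c(1, -2, 0, 3), 2, 2,
                    dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(bad_cnt, "PAM", "count"), "count")
  dup <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(expression_matrix(dup, "protein", "log2_intensity"), "a")
})

test_that("counts_to_tpm matches hand-derived values and sums to 1e6", {
  m <- toy_expr(matrix(c(10, 20), 2, 1), "mRNA", "raw_count")
  tpm <- counts_to_tpm(m, c(1000, 2000))
  expect_equal(as.vector(unclass(tpm)), c(5e5, 5e5))

  m1 <- toy_expr(matrix(7, 1, 1), "mRNA", "raw_count")
  expect_equal(as.vector(unclass(counts_to_tpm(m1, 500))), 1e6)

  m3 <- toy_expr(matrix(c(3, 5, 2), 3, 1), "mRNA", "raw_count")
  tpm3 <- counts_to_tpm(m3, c(300, 500, 200))
  expect_equal(as.vector(unclass(tpm3)), rep(1e6 / 3, 3))
  expect_equal(as.vector(unclass(log2_tpm1(tpm3))),
               rep(log2(1e6 / 3 + 1), 3))

  set.seed(1)
  big <- toy_expr(matrix(rpois(200, 20), 20, 10), "mRNA", "raw_count")
  big[sample(200, 15)] <- NA
  out <- counts_to_tpm(big, runif(20, 200, 3000))
  expect_equal(colSums(unclass(out), na.rm = TRUE), rep(1e6, 10),
               ignore_attr = TRUE, tolerance = 1e-6)

  zero <- toy_expr(matrix(c(0, 0, 1, 2), 2, 2), "mRNA", "raw_count")
  expect_error(counts_to_tpm(zero, c(100, 100)), "s001")
})

test_that("median_normalize aligns run medians to the global median", {
  vals <- matrix(c(4, 5, 5, 6, 6, 7, 7, 8), 2, 4)
  m <- toy_expr(vals)
  runs <- c(s001 = "r1", s002 = "r1", s003 = "r2", s004 = "r2")
  out <- median_normalize(m, runs)
  # run medians 5 and 7, global median 6: run1 + 1, run2 - 1
  expect_equal(unclass(out)[, 1:2], vals[, 1:2] + 1, ignore_attr = TRUE)
  expect_equal(unclass(out)[, 3:4], vals[, 3:4] - 1, ignore_attr = TRUE)
  expect_equal(median(unclass(out)[, 1:2]), median(vals))
  expect_equal(median(unclass(out)[, 3:4]), median(vals))

  single <- median_normalize(m, rep("r1", 4))
  expect_equal(unclass(single), unclass(m))

  cst <- toy_expr(matrix(3, 2, 4))
  expect_equal(unclass(median_normalize(cst, runs)), unclass(cst))

  all_na <- toy_expr(matrix(c(1, 2, NA, NA), 2, 2))
  expect_error(median_normalize(all_na, c(s001 = "a", s002 = "b")), "b")
})

test_that("median_normalize is idempotent", {
  set.seed(3)
  m <- toy_expr(matrix(rnorm(80, 10), 8, 10))
  runs <- rep(c("r1", "r2"), each = 5)
  names(runs) <- colnames(m)
  once <- median_normalize(m, runs)
  twice <- median_normalize(once, runs)
  expect_equal(unclass(twice), unclass(once), tolerance = 1e-12)
})

test_that("log2_fold_changes subtracts pairs and propagates missingness", {
  tum <- toy_expr(matrix(c(5, 1, 4, 2), 2, 2), samples = c("p1_T", "p2_T"))
  nrm <- toy_expr(matrix(c(3, 1, NA, 2), 2, 2), samples = c("p1_N", "p2_N"))
  design <- tibble::tibble(patient_id = c("p1", "p2"),
                           tumor_sample_id = c("p1_T", "p2_T"),
                           normal_sample_id = c("p1_N", "p2_N"))
  fc <- log2_fold_changes(tum, nrm, design)
  expect_equal(unclass(fc)["b001", "p1"], 2)
  expect_true(is.na(unclass(fc)["b001", "p2"]))
  expect_equal(unclass(fc)["b002", "p2"], 0)

  same <- log2_fold_changes(tum, tum, dplyr::mutate(
    design, normal_sample_id = tumor_sample_id))
  expect_true(all(unclass(same) == 0))

  bad <- dplyr::mutate(design, tumor_sample_id = c("p1_T", "missing_T"))
  expect_error(log2_fold_changes(tum, nrm, bad), "missing_T")
})

test_that("standardize_rows yields mean 0 / SD 1 and rejects degenerate rows", {
  m <- toy_expr(matrix(c(1, 2, 3), 1, 3))
  expect_equal(as.vector(unclass(standardize_rows(m))), c(-1, 0, 1))

  m2 <- toy_expr(matrix(c(10, 20), 1, 2))
  expect_equal(as.vector(unclass(standardize_rows(m2))),
               c(-0.70710678, 0.70710678), tolerance = 1e-8)

  std <- standardize_rows(toy_expr(matrix(rnorm(12), 2, 6)))
  expect_equal(unclass(standardize_rows(std)), unclass(std),
               tolerance = 1e-12)

  flat <- toy_expr(matrix(c(1, 1, 1, 2, 3, 4), 2, 3, byrow = TRUE))
  expect_error(standardize_rows(flat), "b001")
})

test_that("metadata validation enforces the paired design", {
  md <- tibble::tibble(
    sample_id = c("p1_T", "p1_N", "p2_T"), patient_id = c("p1", "p1", "p2"),
    tissue = c("tumor", "normal", "tumor"), ischemia_min = c(5, 5, 12),
    age = 60, gender = "female", alcohol = "inactive", meat = "low",
    grade = "low", stage = "II", run_label = "r1")
  expect_silent(validate_metadata(md))
  expect_equal(nrow(paired_design(md)), 1L)

  bad_time <- md
  bad_time$ischemia_min[2] <- 7
  expect_error(validate_metadata(bad_time), "p1")

  dup <- dplyr::bind_rows(md, md[1, ] |>
                            dplyr::mutate(sample_id = "p1_T2"))
  expect_error(validate_metadata(dup), "tissue")
  expect_error(validate_metadata(md[, -3]), "tissue")
})
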