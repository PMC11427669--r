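#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the paired differences. Zero differences
#' are dropped before ranking (classical treatment) or kept in the ranking
#' and dropped afterwards (Pratt). The exact null distribution is used for
#' n <= 25 without ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param tumor_values,normal_values Aligned numeric vectors.
#' @param min_pairs Minimum number of complete pairs; below it the result
#'   is flagged untestable (`p = NA`) rather than raising an error.
#' @param zero_method `"drop"` (classical) or `"pratt"`.
#' @return A one-row tibble with `n_pairs`, `statistic` and `p`. All-zero
#'   differences give `p = 1` by convention.
#' @export
paired_wilcoxon <- function(tumor_values, normal_values, min_pairs = 5,
                            zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(tumor_values) == length(normal_values))
  ok <- !is.na(tumor_values) & !is.na(normal_values)
  d <- tumor_values[ok] - normal_values[ok]
  n <- length(d)
  if (n < min_pairs) {
    return(tibble(n_pairs = n, statistic = NA_real_, p = NA_real_))
  }
  dz <- d[d != 0]
  if (!length(dz)) {
    return(tibble(n_pairs = n, statistic = NA_real_, p = 1))
  }
  if (zero_method == "drop") {
    exact <- length(dz) <= 25 && !anyDuplicated(abs(dz))
    wt <- suppressWarnings(
      stats::wilcox.test(dz, exact = exact, correct = TRUE)
    )
    tibble(n_pairs = n, statistic = unname(wt$statistic), p = wt$p.value)
  } else {
    # Pratt: rank |d| with zeros included, drop zero ranks, normal approx
    r <- rank(abs(d))
    nz <- d != 0
    w <- sum(r[nz][d[nz] > 0])
    e_w <- sum(r[nz]) / 2
    var_w <- sum(r[nz]^2) / 4
    z <- (w - e_w) / sqrt(var_w)
    tibble(n_pairs = n, statistic = w,
           p = min(1, 2 * stats::pnorm(-abs(z))))
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Missing entries are passed through as missing and excluded from the
#' number of tests m.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, order-preserving with the input.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Select differentially expressed biomolecules
#'
#' Per biomolecule: paired Wilcoxon test of tumor versus normal, BH
#' adjustment over all testable biomolecules, and the mean tumor-minus-normal
#' log2 difference as effect. A biomolecule is selected when its adjusted p
#' falls below `alpha_fdr` AND its effect lies at or beyond the configured
#' percentiles of the effect distribution over all testable biomolecules.
#'
#' @param tumor,normal [expression_matrix()] objects sharing biomolecules.
#' @param design A [paired_design()] tibble.
#' @param alpha_fdr FDR level for selection.
#' @param boundary_percentiles Lower/upper percentiles of the effect
#'   distribution forming the effect boundary, or `NULL` to select on the
#'   FDR criterion alone (used for the per-group selections of the
#'   set-difference loss analysis, where only the FDR level applies).
#' @inheritParams paired_wilcoxon
#' @return A tibble with one row per biomolecule: `biomolecule_id`,
#'   `n_pairs`, `statistic`, `p`, `p_adj`, `effect`, `selected`.
#' @export
select_differential <- function(tumor, normal, design, alpha_fdr = 0.01,
                                boundary_percentiles = c(5, 95),
                                min_pairs = 5,
                                zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (!identical(rownames(tumor), rownames(normal))) {
    stop("tumor and normal matrices must share the same biomolecule list",
         call. = FALSE)
  }
  tum <- unclass(tumor)[, design$tumor_sample_id, drop = FALSE]
  nrm <- unclass(normal)[, design$normal_sample_id, drop = FALSE]
  res <- purrr::map_dfr(seq_len(nrow(tum)), function(i) {
    paired_wilcoxon(tum[i, ], nrm[i, ], min_pairs = min_pairs,
                    zero_method = zero_method)
  })
  res <- dplyr::mutate(res, biomolecule_id = rownames(tum), .before = 1)
  d <- tum - nrm
  res$effect <- ifelse(res$n_pairs > 0, rowMeans(d, na.rm = TRUE), NA_real_)
  res$effect[res$n_pairs < min_pairs] <- NA_real_
  testable <- !is.na(res$p)
  if (!any(testable)) stop("no testable biomolecule", call. = FALSE)
  res$p_adj <- bh_adjust(res$p)
  if (is.null(boundary_percentiles)) {
    res$selected <- !is.na(res$p_adj) & res$p_adj < alpha_fdr
  } else {
    bounds <- quantile(res$effect[testable], boundary_percentiles / 100,
                       na.rm = TRUE, type = 7, names = FALSE)
    res$selected <- !is.na(res$p_adj) & res$p_adj < alpha_fdr &
      (res$effect <= bounds[1] | res$effect >= bounds[2])
    attr(res, "effect_boundary") <- bounds
  }
  res
}

#' Consecutive-group expression shifts
#'
#' For each consecutive pair of ischemia time groups, tests every
#' biomolecule's fold-change values between the two (different) patient
#' groups with a two-sided unpaired Wilcoxon rank-sum test, adjusts by BH
#' within the pair, and reports biomolecules whose adjusted p falls below
#' `alpha_fdr` with a mean shift outside the fold band
#' (|effect| >= `band` on the log2 scale, i.e. outside (2^-band, 2^band)).
#'
#' @param fc_matrix An `expr_matrix` of per-patient log2 fold changes
#'   (columns = patients).
#' @param group_labels Factor of time-group labels, named by or aligned with
#'   the columns of `fc_matrix`; consecutive level pairs are compared.
#' @param band Half-width of the excluded effect band in log2 units.
#' @param alpha_fdr FDR level within each pair.
#' @param min_group Minimum patients per group; smaller pairs are skipped
#'   with a warning.
#' @return A tibble with columns `pair`, `biomolecule_id`, `statistic`, `p`,
#'   `p_adj`, `effect` (later minus earlier group mean), `direction`
#'   (`"up"`/`"down"`) and `reported`.
#' @export
intergroup_shift <- function(fc_matrix, group_labels, band = 0.5,
                             alpha_fdr = 0.05, min_group = 5) {
  if (!is.null(names(group_labels))) {
    group_labels <- group_labels[colnames(fc_matrix)]
  }
  stopifnot(length(group_labels) == ncol(fc_matrix))
  g <- droplevels(as.factor(group_labels))
  levs <- levels(g)
  if (length(levs) < 2) stop("need at least 2 groups", call. = FALSE)
  vals <- unclass(fc_matrix)
  out <- list()
  for (k in seq_len(length(levs) - 1)) {
    g1 <- levs[k]; g2 <- levs[k + 1]
    i1 <- which(g == g1); i2 <- which(g == g2)
    if (length(i1) < min_group || length(i2) < min_group) {
      warning(sprintf("pair %s vs %s skipped: group below %d patients",
                      g2, g1, min_group), call. = FALSE)
      next
    }
    pair_res <- purrr::map_dfr(seq_len(nrow(vals)), function(i) {
      x2 <- vals[i, i2]; x1 <- vals[i, i1]
      x2 <- x2[!is.na(x2)]; x1 <- x1[!is.na(x1)]
      if (length(x1) < 2 || length(x2) < 2) {
        return(tibble(statistic = NA_real_, p = NA_real_,
                      effect = NA_real_))
      }
      wt <- suppressWarnings(stats::wilcox.test(x2, x1, exact = FALSE,
                                                correct = TRUE))
      tibble(statistic = unname(wt$statistic), p = wt$p.value,
             effect = mean(x2) - mean(x1))
    })
    pair_res <- dplyr::mutate(pair_res,
                              pair = paste0(g2, "-", g1),
                              biomolecule_id = rownames(vals),
                              .before = 1)
    pair_res$p_adj <- bh_adjust(pair_res$p)
    pair_res$reported <- !is.na(pair_res$p_adj) &
      pair_res$p_adj < alpha_fdr & abs(pair_res$effect) >= band
    pair_res$direction <- ifelse(pair_res$effect > 0, "up", "down")
    out[[length(out) + 1]] <- pair_res
  }
  if (!length(out)) {
    return(tibble(pair = character(), biomolecule_id = character(),
                  statistic = double(), p = double(), effect = double(),
                  p_adj = double(), reported = logical(),
                  direction = character()))
  }
  dplyr::bind_rows(out)
}
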