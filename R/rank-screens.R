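#' Scheirer-Ray-Hare two-factor rank test
#'
#' Rank-based analogue of two-way ANOVA: all non-missing observations are
#' ranked jointly (midranks for ties), two-way sums of squares are computed
#' on the ranks for the tissue and time main effects and their interaction,
#' and each effect's statistic `H = SS_effect / MS_total` (divided by the
#' tie correction `D = 1 - sum(t^3 - t) / (N^3 - N)`) is referred to the
#' chi-square distribution at the effect's degrees of freedom.
#'
#' With unequal cell sizes the sums of squares are computed type-II by
#' default (each main effect adjusted for the other, the interaction
#' adjusted for both); `ss_type = "sequential"` gives the classical
#' tissue -> time -> interaction decomposition.
#'
#' @param values Numeric response (normalized expression), NAs dropped.
#' @param tissue_factor Two-level factor (tumor/normal).
#' @param time_factor Time-group factor with >= 2 levels.
#' @param ss_type `"II"` or `"sequential"`.
#' @param tie_correction Apply the tie correction D (default) or not.
#' @return An object of class `srh_test`; use [generics::tidy()] for the
#'   per-effect table (`effect`, `df`, `statistic`, `p.value`). All-tied
#'   data yield `p = 1` for every effect by convention.
#' @export
srh_test <- function(values, tissue_factor, time_factor,
                     ss_type = c("II", "sequential"), tie_correction = TRUE) {
  ss_type <- match.arg(ss_type)
  ok <- !is.na(values)
  y <- values[ok]
  a <- droplevels(as.factor(tissue_factor[ok]))
  b <- droplevels(as.factor(time_factor[ok]))
  if (nlevels(a) != 2) stop("tissue factor must have exactly two levels",
                            call. = FALSE)
  if (nlevels(b) < 2) stop("time factor must have at least two levels",
                           call. = FALSE)
  n <- length(y)
  r <- rank(y)
  ss_total <- sum((r - mean(r))^2)
  dfs <- c(tissue = nlevels(a) - 1L, time = nlevels(b) - 1L,
           interaction = (nlevels(a) - 1L) * (nlevels(b) - 1L))
  if (ss_total == 0) {
    tab <- tibble(effect = names(dfs), df = as.integer(dfs),
                  statistic = 0, p.value = 1)
    return(structure(list(table = tab, ss = c(tissue = 0, time = 0,
                                              interaction = 0, total = 0),
                          ms_total = 0, n = n, tie_D = 0),
                     class = "srh_test"))
  }
  ms_total <- ss_total / (n - 1)
  rss <- function(form) sum(stats::lm(form, data = data.frame(r = r, a = a,
                                                              b = b))$residuals^2)
  rss_a <- rss(r ~ a); rss_b <- rss(r ~ b)
  rss_ab <- rss(r ~ a + b); rss_full <- rss(r ~ a * b)
  if (ss_type == "II") {
    ss <- c(tissue = rss_b - rss_ab, time = rss_a - rss_ab,
            interaction = rss_ab - rss_full)
  } else {
    ss <- c(tissue = ss_total - rss_a, time = rss_a - rss_ab,
            interaction = rss_ab - rss_full)
  }
  ss <- pmax(ss, 0)
  tie_tab <- table(r)
  D <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  denom <- ms_total * (if (tie_correction) D else 1)
  H <- ss / denom
  tab <- tibble(effect = names(dfs), df = as.integer(dfs),
                statistic = unname(H),
                p.value = stats::pchisq(unname(H), dfs, lower.tail = FALSE))
  structure(list(table = tab, ss = c(ss, total = ss_total),
                 ms_total = ms_total, n = n, tie_D = D),
            class = "srh_test")
}

#' @export
print.srh_test <- function(x, ...) {
  cat(sprintf("Scheirer-Ray-Hare test (N = %d, tie D = %.4f)\n", x$n, x$tie_D))
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname srh_test
#' @param x An `srh_test` object.
#' @param ... Unused.
#' @export
tidy.srh_test <- function(x, ...) x$table

#' Scheirer-Ray-Hare screen over a biomolecule matrix
#'
#' Runs [srh_test()] per biomolecule on normalized expression with tissue
#' and time-group factors, adjusts p-values per effect across biomolecules
#' by BH, and summarises significant counts per trajectory cluster.
#'
#' @param matrix An `expr_matrix` whose columns cover tumor and normal
#'   samples.
#' @param metadata Metadata tibble with `sample_id`, `tissue` and
#'   `time_group` columns covering the matrix columns.
#' @param cluster_assignments Tibble with `biomolecule_id` and `cluster`
#'   (e.g. from [hierarchical_cluster()]); biomolecules without a cluster
#'   are screened under cluster `NA`.
#' @param alpha_fdr FDR level for the significance counts.
#' @inheritParams srh_test
#' @return A list with `per_biomolecule` (tibble of per-effect H and
#'   adjusted p per biomolecule) and `summary` (per-cluster counts of
#'   significant tissue/time/interaction effects plus a totals row).
#' @export
srh_screen <- function(matrix, metadata, cluster_assignments = NULL,
                       alpha_fdr = 0.05, ss_type = "II") {
  md <- as_tibble(metadata)
  stopifnot(all(c("sample_id", "tissue", "time_group") %in% names(md)))
  md <- md[match(colnames(matrix), md$sample_id), ]
  if (any(is.na(md$sample_id))) {
    stop("metadata does not cover every matrix column", call. = FALSE)
  }
  vals <- unclass(matrix)
  res <- purrr::map(seq_len(nrow(vals)), function(i) {
    y <- vals[i, ]
    ok <- !is.na(y)
    if (sum(ok) < 4 ||
        length(unique(md$tissue[ok])) < 2 ||
        length(unique(md$time_group[ok])) < 2) {
      return(NULL)
    }
    fit <- srh_test(y, md$tissue, droplevels(factor(md$time_group)),
                    ss_type = ss_type)
    tibble(biomolecule_id = rownames(vals)[i],
           effect = fit$table$effect, statistic = fit$table$statistic,
           p = fit$table$p.value)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped) {
    message(dropped, " biomolecule(s) untestable and excluded from the screen")
  }
  per <- dplyr::bind_rows(res)
  if (!nrow(per)) stop("no testable biomolecule", call. = FALSE)
  per <- per |>
    dplyr::group_by(.data$effect) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p)) |>
    dplyr::ungroup()
  cl <- if (is.null(cluster_assignments)) {
    tibble(biomolecule_id = unique(per$biomolecule_id), cluster = 1L)
  } else {
    as_tibble(cluster_assignments)[, c("biomolecule_id", "cluster")]
  }
  summary <- per |>
    dplyr::left_join(cl, by = "biomolecule_id") |>
    dplyr::group_by(.data$cluster, .data$effect) |>
    dplyr::summarise(n_significant = sum(.data$p_adj < alpha_fdr,
                                         na.rm = TRUE),
                     n_total = dplyr::n_distinct(.data$biomolecule_id),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "effect",
                       values_from = "n_significant") |>
    dplyr::select("cluster", "n_total", "tissue", "time", "interaction")
  totals <- summary |>
    dplyr::summarise(cluster = NA, n_total = sum(.data$n_total),
                     tissue = sum(.data$tissue), time = sum(.data$time),
                     interaction = sum(.data$interaction))
  list(per_biomolecule = per,
       summary = dplyr::bind_rows(summary, totals))
}

#' Kruskal-Wallis mutation-load screen
#'
#' Tests each locus's protein-affecting-mutation counts across ischemia
#' time groups, adjusting by BH across loci. Constant loci get `p = 1` by
#' convention.
#'
#' @param pam_counts An `expr_matrix` of per-locus mutation counts.
#' @param group_labels Time-group factor named by or aligned with the
#'   columns.
#' @param alpha_fdr FDR level for the reported significant fraction.
#' @return A tibble (`locus`, `statistic`, `p`, `p_adj`, `significant`)
#'   with attribute `fraction_significant`.
#' @export
kruskal_mutation_load <- function(pam_counts, group_labels,
                                  alpha_fdr = 0.01) {
  if (!is.null(names(group_labels))) {
    group_labels <- group_labels[colnames(pam_counts)]
  }
  g <- droplevels(as.factor(group_labels))
  if (nlevels(g) < 2 || min(table(g)) < 2) {
    stop("need >= 2 groups with >= 2 samples", call. = FALSE)
  }
  vals <- unclass(pam_counts)
  res <- purrr::map_dfr(seq_len(nrow(vals)), function(i) {
    y <- vals[i, ]
    ok <- !is.na(y)
    if (length(unique(y[ok])) < 2) {
      return(tibble(statistic = 0, p = 1))
    }
    kt <- stats::kruskal.test(y[ok], g[ok])
    tibble(statistic = unname(kt$statistic), p = kt$p.value)
  })
  res <- dplyr::mutate(res, locus = rownames(vals), .before = 1)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha_fdr
  attr(res, "fraction_significant") <- mean(res$significant)
  res
}

#' Fisher screen of binary submodalities against the reference group
#'
#' For each locus and each non-reference time group, builds the 2x2 table
#' of event presence/absence in that group versus the shortest-time
#' reference group and applies the two-sided Fisher exact test; BH is
#' applied per group across loci.
#'
#' @param binary_matrix An `expr_matrix` of 0/1 indicators.
#' @param group_labels Time-group factor named by or aligned with the
#'   columns.
#' @param reference_label Label of the reference (shortest-time) group.
#' @param alpha_fdr FDR level for the `significant` flag.
#' @return A tibble (`locus`, `group`, `p`, `p_adj`, `significant`).
#' @export
fisher_binary_vs_reference <- function(binary_matrix, group_labels,
                                       reference_label, alpha_fdr = 0.01) {
  if (!is.null(names(group_labels))) {
    group_labels <- group_labels[colnames(binary_matrix)]
  }
  g <- as.character(group_labels)
  if (!any(g == reference_label)) {
    stop("reference group absent: ", reference_label, call. = FALSE)
  }
  vals <- unclass(binary_matrix)
  ref_idx <- which(g == reference_label)
  out <- list()
  for (grp in setdiff(unique(g), reference_label)) {
    idx <- which(g == grp)
    if (!length(idx)) {
      warning("empty group skipped: ", grp, call. = FALSE)
      next
    }
    res <- purrr::map_dfr(seq_len(nrow(vals)), function(i) {
      x_ref <- vals[i, ref_idx]; x_g <- vals[i, idx]
      x_ref <- x_ref[!is.na(x_ref)]; x_g <- x_g[!is.na(x_g)]
      tab <- rbind(c(sum(x_g == 1), sum(x_g == 0)),
                   c(sum(x_ref == 1), sum(x_ref == 0)))
      if (any(rowSums(tab) == 0) || sum(tab[, 1]) == 0) {
        return(tibble(p = 1))
      }
      tibble(p = stats::fisher.test(tab)$p.value)
    })
    res <- dplyr::mutate(res, locus = rownames(vals), group = grp,
                         .before = 1)
    res$p_adj <- bh_adjust(res$p)
    res$significant <- !is.na(res$p_adj) & res$p_adj < alpha_fdr
    out[[length(out) + 1]] <- res
  }
  dplyr::bind_rows(out)
}
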