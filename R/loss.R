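#' Extreme-expression set of a sample subset
#'
#' Summarises each biomolecule by its mean expression over the subset's
#' non-missing samples and flags biomolecules whose summary lies outside
#' the (Q_low, Q_high) quantile interval of the summary distribution
#' across biomolecules (linear-interpolation/type-7 quantiles).
#'
#' @param matrix An `expr_matrix`.
#' @param sample_subset Character vector of sample ids to summarise over.
#' @param q_low,q_high Quantile bounds in percent (defaults 2.5 / 97.5, so
#'   roughly 5 percent of biomolecules are extreme by construction).
#' @param label Optional group label carried on the result.
#' @return An `extreme_set` object: list with `members` (biomolecule ids),
#'   `bounds` (the two quantile values), `summaries` and `label`.
#' @export
extreme_set <- function(matrix, sample_subset, q_low = 2.5, q_high = 97.5,
                        label = NA_character_) {
  stopifnot(length(sample_subset) >= 1)
  missing_smp <- setdiff(sample_subset, colnames(matrix))
  if (length(missing_smp)) {
    stop("sample(s) absent from matrix: ",
         paste(missing_smp, collapse = ", "), call. = FALSE)
  }
  if (nrow(matrix) < 20) {
    stop("need >= 20 biomolecules for stable quantiles", call. = FALSE)
  }
  vals <- unclass(matrix)[, sample_subset, drop = FALSE]
  summ <- rowMeans(vals, na.rm = TRUE)
  summ <- summ[!is.nan(summ)]
  bounds <- quantile(summ, c(q_low, q_high) / 100, type = 7, names = FALSE)
  members <- names(summ)[summ < bounds[1] | summ > bounds[2]]
  structure(list(members = members, bounds = bounds, summaries = summ,
                 label = label),
            class = "extreme_set")
}

#' @export
print.extreme_set <- function(x, ...) {
  cat(sprintf("<extreme_set>%s %d members, bounds (%.4g, %.4g)\n",
              if (is.na(x$label)) "" else paste0(" ", x$label),
              length(x$members), x$bounds[1], x$bounds[2]))
  invisible(x)
}

set_members <- function(x) {
  if (inherits(x, "extreme_set")) x$members else as.character(x)
}

#' Relative loss of a reference set in another set
#'
#' `L = 100 * |reference \ other| / |reference|`: the percentage of the
#' reference group's members absent from the other group's set.
#'
#' @param reference,other [extreme_set()] objects or character vectors of
#'   member ids; the reference must be non-empty.
#' @return The loss percentage in `[0, 100]`.
#' @export
relative_loss <- function(reference, other) {
  ref <- set_members(reference)
  oth <- set_members(other)
  if (!length(ref)) stop("reference set is empty", call. = FALSE)
  100 * length(setdiff(ref, oth)) / length(ref)
}

#' Extreme-expression loss over time groups
#'
#' Computes, per tissue and per non-reference time group, the relative loss
#' of the reference (first) group's extreme biomolecules.
#'
#' @param tumor,normal `expr_matrix` objects.
#' @param metadata Metadata tibble with `sample_id`, `tissue` and
#'   `time_group`; the first factor level is the reference group.
#' @inheritParams extreme_set
#' @return A tibble (`tissue`, `group`, `loss_pct`).
#' @export
extreme_loss_table <- function(tumor, normal, metadata, q_low = 2.5,
                               q_high = 97.5) {
  md <- as_tibble(metadata)
  stopifnot(all(c("sample_id", "tissue", "time_group") %in% names(md)))
  groups <- levels(droplevels(factor(md$time_group)))
  out <- list()
  for (tis in c("normal", "tumor")) {
    mat <- if (tis == "tumor") tumor else normal
    sets <- lapply(groups, function(grp) {
      smp <- md$sample_id[md$tissue == tis & md$time_group == grp]
      smp <- intersect(smp, colnames(mat))
      if (!length(smp)) return(NULL)
      extreme_set(mat, smp, q_low, q_high, label = grp)
    })
    names(sets) <- groups
    if (is.null(sets[[1]])) {
      stop("reference group absent in ", tis, " tissue", call. = FALSE)
    }
    for (grp in groups[-1]) {
      if (is.null(sets[[grp]])) next
      out[[length(out) + 1]] <- tibble(
        tissue = tis, group = grp,
        loss_pct = relative_loss(sets[[1]], sets[[grp]]))
    }
  }
  dplyr::bind_rows(out)
}

#' Differential-set loss across time groups
#'
#' Percentage of the reference group's differentially expressed biomolecules
#' no longer selected in each later group:
#' `100 * |DE(T1) \ DE(Ti)| / |DE(T1)|`.
#'
#' @param de_sets Named, ordered list of per-group selected biomolecule id
#'   vectors; the first element is the reference group and must be
#'   non-empty.
#' @return A tibble (`group`, `loss_pct`) over the non-reference groups.
#' @export
de_set_difference_loss <- function(de_sets) {
  stopifnot(is.list(de_sets), length(de_sets) >= 2)
  ref <- set_members(de_sets[[1]])
  if (!length(ref)) stop("reference differential set is empty", call. = FALSE)
  grp <- names(de_sets)[-1] %||% paste0("G", seq_along(de_sets)[-1])
  tibble(group = grp,
         loss_pct = unname(vapply(de_sets[-1],
                                  function(s) relative_loss(ref, s),
                                  numeric(1))))
}

#' Recommend an ischemia time cut-off
#'
#' Codifies the trade-off between collecting samples and preserving
#' differential signal into an explicit rule: the recommended cut-off is
#' the upper bound of the last group G (scanning T2 upward contiguously)
#' such that, for every modality, (a) the differential-set loss at G stays
#' at or below `loss_threshold` percent and (b) the mean absolute ischemia
#' coefficient of G stays below the mean absolute stage-IV coefficient
#' (ischemia must not dominate the strongest clinical predictor).
#'
#' @param de_loss Tibble (`modality`, `group`, `loss_pct`) from
#'   [de_set_difference_loss()] per modality.
#' @param ischemia_coef Tibble (`modality`, `group`, `mean_abs_coef`) of
#'   mean absolute ischemia-group regression coefficients (see
#'   [mean_abs_coefficient()]).
#' @param stage4_coef Tibble (`modality`, `mean_abs_coef`) of mean absolute
#'   stage-IV coefficients.
#' @param scheme The [time_scheme()] the groups refer to.
#' @param loss_threshold Maximum tolerated loss percentage.
#' @return A `cutoff_report` list: `recommendation_min`, the per-group
#'   decision `table`, and the `rule` applied. If no group qualifies the
#'   recommendation falls back to the reference-group bound with a warning.
#' @export
recommend_cutoff <- function(de_loss, ischemia_coef, stage4_coef, scheme,
                             loss_threshold = 25) {
  cuts <- scheme_cutoffs(scheme)
  groups <- scheme$intervals$label
  if (length(groups) < 3) stop("need a refined scheme with >= 3 groups",
                               call. = FALSE)
  tab <- tidyr::expand_grid(group = groups[-1],
                            modality = unique(de_loss$modality)) |>
    dplyr::left_join(de_loss, by = c("group", "modality")) |>
    dplyr::left_join(ischemia_coef, by = c("group", "modality")) |>
    dplyr::left_join(stage4_coef |>
                       dplyr::rename(stage4_abs_coef = "mean_abs_coef"),
                     by = "modality") |>
    dplyr::mutate(
      loss_ok = !is.na(.data$loss_pct) & .data$loss_pct <= loss_threshold,
      coef_ok = !is.na(.data$mean_abs_coef) &
        !is.na(.data$stage4_abs_coef) &
        .data$mean_abs_coef < .data$stage4_abs_coef,
      ok = .data$loss_ok & .data$coef_ok)
  by_group <- tab |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(ok = all(.data$ok), .groups = "drop") |>
    dplyr::arrange(match(.data$group, groups))
  ok_run <- cumprod(by_group$ok) == 1
  if (any(ok_run)) {
    last_ok <- by_group$group[max(which(ok_run))]
    rec <- cuts[[last_ok]]
    warn <- NULL
  } else {
    last_ok <- groups[1]
    rec <- cuts[[groups[1]]]
    warn <- "no group satisfies both criteria; falling back to the reference group bound"
    warning(warn, call. = FALSE)
  }
  structure(list(recommendation_min = unname(rec),
                 recommended_group = last_ok, table = tab,
                 rule = sprintf(
                   "loss <= %.1f%% and mean |ischemia coef| < mean |stage-IV coef| for every modality, contiguously from T2",
                   loss_threshold),
                 warning = warn),
            class = "cutoff_report")
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat(sprintf("Recommended ischemia time cut-off: %g min (group %s)\n",
              x$recommendation_min, x$recommended_group))
  cat("Rule:", x$rule, "\n")
  print(x$table)
  invisible(x)
}
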