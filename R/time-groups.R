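#' Ischemia time-group schemes
#'
#' A scheme is an ordered list of non-overlapping cold-ischemia-minute
#' intervals with printed closed integer bounds, plus an overflow label for
#' times above the last interval. The first interval is always of the form
#' `t < upper-of-second-interval`. Fractional minutes falling in a printed
#' gap (the source tables record integer minutes) are assigned to the lower
#' group.
#'
#' @param name Scheme name.
#' @param intervals A data frame with columns `label`, `lower`, `upper`
#'   (closed integer bounds as printed; `upper = Inf` allowed for the last
#'   interval).
#' @param overflow_label Label for samples with time above the last upper
#'   bound, or `NA` if the last interval is unbounded.
#' @return A `time_scheme` object.
#' @export
time_scheme <- function(name, intervals, overflow_label = NA_character_) {
  iv <- as_tibble(intervals)
  stopifnot(all(c("label", "lower", "upper") %in% names(iv)), nrow(iv) >= 1)
  if (is.unsorted(iv$lower, strictly = TRUE)) {
    stop("intervals must be ordered by lower bound", call. = FALSE)
  }
  if (any(iv$upper[-nrow(iv)] >= iv$lower[-1])) {
    stop("intervals overlap", call. = FALSE)
  }
  if (is.infinite(iv$upper[nrow(iv)]) && !is.na(overflow_label)) {
    stop("unbounded last interval cannot have an overflow group", call. = FALSE)
  }
  structure(list(name = name, intervals = iv, overflow_label = overflow_label),
            class = "time_scheme")
}

#' @export
print.time_scheme <- function(x, ...) {
  cat(sprintf("<time_scheme> %s\n", x$name))
  print(x$intervals)
  if (!is.na(x$overflow_label)) {
    cat(sprintf("overflow: %s (t > %g)\n", x$overflow_label,
                x$intervals$upper[nrow(x$intervals)]))
  }
  invisible(x)
}

#' Built-in time-group schemes
#'
#' * `original_5min`: T1 t<10, T2 10-14, T3 15-19, T4 20-24, T5 t>=25.
#' * `refined_3min`: T1 t<10, then 3-minute groups T2 10-12, T3 13-15,
#'   T4 16-18, T5 19-20, overflow t>20.
#' * `hcc_adapted`: T1 t<10, T2 10-12, T3 13-18, T4 19-30, overflow t>30
#'   (wider late groups for small cohorts).
#'
#' @param name One of `"original_5min"`, `"refined_3min"`, `"hcc_adapted"`.
#' @return A [time_scheme()].
#' @export
time_schemes <- function(name = c("refined_3min", "original_5min",
                                  "hcc_adapted")) {
  name <- match.arg(name)
  switch(name,
    original_5min = time_scheme("original_5min", tibble(
      label = paste0("T", 1:5),
      lower = c(0, 10, 15, 20, 25),
      upper = c(9, 14, 19, 24, Inf))),
    refined_3min = time_scheme("refined_3min", tibble(
      label = paste0("T", 1:5),
      lower = c(0, 10, 13, 16, 19),
      upper = c(9, 12, 15, 18, 20)), overflow_label = "over"),
    hcc_adapted = time_scheme("hcc_adapted", tibble(
      label = paste0("T", 1:4),
      lower = c(0, 10, 13, 19),
      upper = c(9, 12, 18, 30)), overflow_label = "over")
  )
}

#' Group labels of a scheme
#'
#' @param scheme A [time_scheme()].
#' @param overflow Include the overflow label?
#' @return Character vector of ordered labels.
#' @export
scheme_labels <- function(scheme, overflow = TRUE) {
  lab <- scheme$intervals$label
  if (overflow && !is.na(scheme$overflow_label)) {
    lab <- c(lab, scheme$overflow_label)
  }
  lab
}

# cut-off minute associated with each group: for T1 ("t < b") the bound is b,
# for later groups the printed closed upper bound
scheme_cutoffs <- function(scheme) {
  iv <- scheme$intervals
  cuts <- iv$upper
  if (nrow(iv) > 1) cuts[1] <- iv$lower[2]
  stats::setNames(cuts, iv$label)
}

#' Assign samples to ischemia time groups
#'
#' Integer minutes map by the printed closed interval bounds; fractional
#' minutes follow the same inequalities, falling to the lower group inside a
#' printed gap. Times above the last upper bound receive the overflow label.
#'
#' @param metadata A metadata data frame with an `ischemia_min` column.
#' @param scheme A [time_scheme()].
#' @return The metadata tibble with a `time_group` factor column (levels in
#'   scheme order, overflow last).
#' @export
assign_time_groups <- function(metadata, scheme) {
  md <- as_tibble(metadata)
  t <- md$ischemia_min
  if (any(is.na(t))) stop("ischemia_min missing for some samples", call. = FALSE)
  if (any(t < 0)) stop("negative ischemia_min", call. = FALSE)
  iv <- scheme$intervals
  last_upper <- iv$upper[nrow(iv)]
  lowers <- c(-Inf, iv$lower[-1])
  idx <- findInterval(t, lowers)
  lab <- iv$label[idx]
  over <- t > last_upper
  if (any(over)) {
    if (is.na(scheme$overflow_label)) {
      stop("times above the last interval but scheme has no overflow group",
           call. = FALSE)
    }
    lab[over] <- scheme$overflow_label
  }
  md$time_group <- factor(lab, levels = scheme_labels(scheme))
  md
}

#' Sample counts per time group and tissue
#'
#' Reproduces the layout of a cohort description table: one row per group,
#' one column per tissue.
#'
#' @param metadata A metadata tibble carrying `time_group` (from
#'   [assign_time_groups()]) and `tissue`.
#' @return A tibble of counts; empty input yields an empty tibble.
#' @export
group_counts <- function(metadata) {
  md <- as_tibble(metadata)
  if (!nrow(md)) return(tibble(time_group = factor(), tissue = character(),
                               n = integer()))
  md |>
    dplyr::count(.data$time_group, .data$tissue, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "n",
                       values_fill = 0L)
}
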