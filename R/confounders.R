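CONFOUNDER_REFERENCES <- list(
  gender = c("female", "male"),
  alcohol = c("inactive", "active"),
  meat = c("low", "high"),
  grade = c("low", "high"),
  stage = c("I", "II", "III", "IV")
)

# build the per-patient design frame with the stated reference levels;
# time_group levels come from the (refined) scheme with T1 as reference
confounder_design <- function(covariates) {
  cov <- as_tibble(covariates)
  need <- c("patient_id", "age", names(CONFOUNDER_REFERENCES), "time_group")
  missing_cols <- setdiff(need, names(cov))
  if (length(missing_cols)) {
    stop("covariates missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (v in names(CONFOUNDER_REFERENCES)) {
    cov[[v]] <- factor(cov[[v]], levels = CONFOUNDER_REFERENCES[[v]])
  }
  cov$time_group <- droplevels(factor(cov$time_group))
  cov
}

#' Per-biomolecule confounder regression
#'
#' Ordinary least squares of a biomolecule's per-patient log2 fold change
#' (tumor minus normal) on age, gender, alcohol, meat consumption, grade,
#' stage and the refined ischemia time group, with the clinical reference
#' levels (female, inactive, low meat, low grade, stage I, T1). Inestimable
#' coefficients (empty levels, rank deficiency) are flagged rather than
#' fatal.
#'
#' @param fc_values Named numeric vector of per-patient log2 fold changes
#'   (names = patient ids); patients with a missing value are dropped.
#' @param covariates Per-patient covariate tibble with `patient_id`, `age`,
#'   `gender`, `alcohol`, `meat`, `grade`, `stage`, `time_group`.
#' @param min_extra_n Guard: at least `parameters + min_extra_n`
#'   observations are required, otherwise the fit is flagged untestable.
#' @return A tibble (`term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `estimable`, `n_used`).
#' @export
fit_biomolecule_lm <- function(fc_values, covariates, min_extra_n = 5) {
  cov <- confounder_design(covariates)
  y <- fc_values[cov$patient_id]
  ok <- !is.na(y)
  dat <- cov[ok, , drop = FALSE]
  dat$y <- y[ok]
  form <- y ~ age + gender + alcohol + meat + grade + stage + time_group
  # full coefficient naming, even for levels absent from the data
  full_terms <- c("(Intercept)", "age", "gendermale", "alcoholactive",
                  "meathigh", "gradehigh",
                  paste0("stage", CONFOUNDER_REFERENCES$stage[-1]),
                  paste0("time_group", levels(cov$time_group)[-1]))
  n_par <- length(full_terms)
  empty_tbl <- tibble(term = full_terms, estimate = NA_real_,
                      std_error = NA_real_, statistic = NA_real_,
                      p_value = NA_real_, estimable = FALSE,
                      n_used = nrow(dat))
  if (nrow(dat) < n_par + min_extra_n) return(empty_tbl)
  dat2 <- droplevels(dat)
  fit <- stats::lm(form, data = dat2)
  sm <- summary(fit)$coefficients
  out <- empty_tbl
  present <- intersect(rownames(sm), full_terms)
  idx <- match(present, out$term)
  out$estimate[idx] <- sm[present, 1]
  out$std_error[idx] <- sm[present, 2]
  out$statistic[idx] <- sm[present, 3]
  out$p_value[idx] <- sm[present, 4]
  out$estimable[idx] <- TRUE
  out
}

#' Confounder regressions across a fold-change matrix
#'
#' @param fc_matrix An `expr_matrix` of per-patient log2 fold changes
#'   (columns = patients).
#' @inheritParams fit_biomolecule_lm
#' @return A tibble of [fit_biomolecule_lm()] records with a leading
#'   `biomolecule_id` column.
#' @export
confounder_lm <- function(fc_matrix, covariates, min_extra_n = 5) {
  vals <- unclass(fc_matrix)
  cov <- confounder_design(covariates)
  purrr::map_dfr(seq_len(nrow(vals)), function(i) {
    fit_biomolecule_lm(vals[i, ], cov, min_extra_n = min_extra_n) |>
      dplyr::mutate(biomolecule_id = rownames(vals)[i], .before = 1)
  })
}

#' Signed-coefficient confounder summary
#'
#' Keeps biomolecules with at least one significant coefficient
#' (`p < p_threshold`, intercept excluded) and, per predictor level among
#' the records where that level is significant, reports the mean and SD of
#' the estimates split by coefficient sign together with the per-sign
#' counts. Levels with no significant biomolecule are omitted.
#'
#' @param records Output of [confounder_lm()].
#' @param p_threshold Raw (unadjusted) significance threshold; the screen
#'   deliberately uses unadjusted p-values.
#' @return A tibble (`term`, `sign`, `mean_estimate`, `sd_estimate`, `n`).
#' @export
summarize_confounders <- function(records, p_threshold = 0.01) {
  sig <- records |>
    dplyr::filter(.data$term != "(Intercept)", .data$estimable,
                  !is.na(.data$p_value), .data$p_value < p_threshold)
  if (!nrow(sig)) {
    return(tibble(term = character(), sign = character(),
                  mean_estimate = double(), sd_estimate = double(),
                  n = integer()))
  }
  sig |>
    dplyr::mutate(sign = ifelse(.data$estimate >= 0, "positive",
                                "negative")) |>
    dplyr::group_by(.data$term, .data$sign) |>
    dplyr::summarise(mean_estimate = mean(.data$estimate),
                     sd_estimate = sd(.data$estimate),
                     n = dplyr::n(), .groups = "drop")
}

#' Mean absolute coefficient of a predictor level
#'
#' Mean of |estimate| over the biomolecules where the level is significant
#' at `p_threshold`; 0 if none is.
#'
#' @inheritParams summarize_confounders
#' @param term Coefficient name (e.g. `"time_groupT3"` or `"stageIV"`).
#' @return A single number.
#' @export
mean_abs_coefficient <- function(records, term, p_threshold = 0.01) {
  sel <- records$term == term & records$estimable &
    !is.na(records$p_value) & records$p_value < p_threshold
  if (!any(sel)) return(0)
  mean(abs(records$estimate[sel]))
}
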