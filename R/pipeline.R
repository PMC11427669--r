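#' Pipeline configuration
#'
#' Bundles the cohort source (a simulation config; TSV inputs can be
#' supplied via `input_paths`), the time-group scheme, all stage
#' thresholds, clustering settings and the root seed. Every random stage
#' derives its own seed from the root seed.
#'
#' @param simulate A [sim_config()] describing the cohort to generate, or
#'   `NULL` when `input_paths` is given.
#' @param input_paths Optional named list with `tumor`, `normal` (named
#'   lists of TSV paths per modality) and `metadata`.
#' @param scheme_name Built-in scheme name (see [time_schemes()]).
#' @param alpha_fdr_de FDR level of the differential selection (0.01).
#' @param alpha_fdr_srh FDR level of the rank screen (0.05).
#' @param confounder_p Raw p threshold of the confounder screen (0.01).
#' @param quantile_bounds Extreme-expression quantile bounds in percent.
#' @param shift_band Half-width of the excluded shift band (log2 units).
#' @param loss_threshold Cut-off rule loss tolerance in percent.
#' @param hier_k Number of hierarchical clusters.
#' @param dpgp A [dpgp_config()].
#' @param dpgp_modality Modality whose trajectories feed the DPGP stage.
#' @param include_overflow Keep overflow-group samples in the refined-scheme
#'   stages (default: excluded).
#' @param min_pairs Minimum complete pairs per paired test.
#' @param seed Root seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = sim_config(), input_paths = NULL,
                            scheme_name = "refined_3min",
                            alpha_fdr_de = 0.01, alpha_fdr_srh = 0.05,
                            confounder_p = 0.01,
                            quantile_bounds = c(2.5, 97.5),
                            shift_band = 0.5, loss_threshold = 25,
                            hier_k = 10, dpgp = dpgp_config(),
                            dpgp_modality = "protein",
                            include_overflow = FALSE, min_pairs = 5,
                            seed = 1L) {
  stopifnot(alpha_fdr_de > 0, alpha_fdr_de < 1,
            alpha_fdr_srh > 0, alpha_fdr_srh < 1,
            confounder_p > 0, confounder_p < 1,
            length(quantile_bounds) == 2,
            quantile_bounds[1] > 0, quantile_bounds[2] < 100,
            quantile_bounds[1] < quantile_bounds[2],
            shift_band >= 0, loss_threshold >= 0, hier_k >= 1)
  structure(list(simulate = simulate, input_paths = input_paths,
                 scheme_name = scheme_name, alpha_fdr_de = alpha_fdr_de,
                 alpha_fdr_srh = alpha_fdr_srh, confounder_p = confounder_p,
                 quantile_bounds = quantile_bounds, shift_band = shift_band,
                 loss_threshold = loss_threshold, hier_k = hier_k,
                 dpgp = dpgp, dpgp_modality = dpgp_modality,
                 include_overflow = include_overflow, min_pairs = min_pairs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_stage_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, paste0(name, ".tsv"))
  df <- as.data.frame(df)
  df[] <- lapply(df, function(x) {
    out <- if (is.double(x)) sprintf("%.10g", x) else as.character(x)
    out[is.na(x) | out == "NA"] <- "NA"
    out
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full ischemia quality-control pipeline
#'
#' Stage order: cohort (simulation or TSV input) -> normalization (per-run
#' median normalization of protein/phosphosite intensities) -> time-group
#' assignment -> reference-group differential selection -> hierarchical
#' clustering of standardized group-mean fold changes -> Scheirer-Ray-Hare
#' screen -> extreme-expression loss -> per-group differential selection
#' and set-difference loss -> DPGP pseudo-time clustering and consecutive
#' group shifts -> confounder regressions -> cut-off recommendation.
#'
#' With an output directory every stage writes a TSV, plus a JSON run
#' summary (`summary.json`) and a plain-text log (`pipeline.log`; the log
#' carries wall-clock timings and is the only output that differs between
#' identical runs).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return Invisibly, a named list with every stage result.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- character()
  t0 <- Sys.time()
  stage <- function(msg) {
    log_lines <<- c(log_lines,
                    sprintf("[%7.2fs] %s",
                            as.numeric(difftime(Sys.time(), t0, units = "secs")),
                            msg))
  }

  # --- cohort ---------------------------------------------------------
  if (!is.null(config$input_paths)) {
    ip <- config$input_paths
    metadata <- read_sample_metadata(ip$metadata)
    tumor <- purrr::imap(ip$tumor, function(p, mod) {
      read_expression_matrix(p, mod, "log2_intensity")
    })
    normal <- purrr::imap(ip$normal, function(p, mod) {
      read_expression_matrix(p, mod, "log2_intensity")
    })
    truth <- NULL
    covariates <- metadata |> dplyr::filter(.data$tissue == "tumor")
    stage("cohort read from TSV inputs")
  } else {
    sim <- config$simulate
    sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
    metadata <- cohort$metadata
    tumor <- cohort$tumor; normal <- cohort$normal
    truth <- cohort$truth
    covariates <- cohort$truth$covariates
    stage(sprintf("cohort simulated: %d pairs, %d modalities",
                  nrow(covariates), length(tumor)))
  }
  metadata <- validate_metadata(metadata)
  modalities <- names(tumor)

  # --- normalization --------------------------------------------------
  run_of <- stats::setNames(metadata$run_label, metadata$sample_id)
  for (mod in intersect(modalities, c("protein", "phosphosite"))) {
    tumor[[mod]] <- median_normalize(tumor[[mod]], run_of)
    normal[[mod]] <- median_normalize(normal[[mod]], run_of)
  }
  stage("per-run median normalization applied to protein/phosphosite")

  # --- time groups ----------------------------------------------------
  scheme <- time_schemes(config$scheme_name)
  metadata <- assign_time_groups(metadata, scheme)
  if (!config$include_overflow && !is.na(scheme$overflow_label)) {
    dropped <- sum(metadata$time_group == scheme$overflow_label)
    metadata <- metadata |>
      dplyr::filter(.data$time_group != scheme$overflow_label) |>
      dplyr::mutate(time_group = droplevels(.data$time_group))
    stage(sprintf("time groups assigned (%s); %d overflow sample(s) excluded",
                  scheme$name, dropped))
  } else {
    stage(sprintf("time groups assigned (%s)", scheme$name))
  }
  counts <- group_counts(metadata)
  write_stage_tsv(counts, out_dir, "group_counts")
  design_all <- paired_design(metadata)
  pat_groups <- metadata |>
    dplyr::filter(.data$tissue == "tumor") |>
    dplyr::select("patient_id", "time_group")
  covariates <- covariates |>
    dplyr::inner_join(pat_groups, by = "patient_id")

  groups <- levels(metadata$time_group)
  ref_group <- groups[1]
  results <- list(metadata = metadata, group_counts = counts,
                  scheme = scheme)

  fc <- list(); de_ref <- list(); de_by_group <- list()
  hier <- list(); srh <- list(); ex_loss <- list(); de_loss <- list()
  conf_records <- list(); conf_summary <- list()

  for (mod in modalities) {
    fc[[mod]] <- log2_fold_changes(tumor[[mod]], normal[[mod]], design_all)

    # reference-group differential selection (FDR + effect boundary) feeds
    # the clustering/screen/confounder stages; the per-group selections of
    # the set-difference loss analysis use the FDR criterion alone
    pats_by_group <- split(pat_groups$patient_id, pat_groups$time_group)
    de_by_group[[mod]] <- purrr::map(groups, function(grp) {
      d <- design_all |> dplyr::filter(.data$patient_id %in%
                                         pats_by_group[[grp]])
      if (nrow(d) < config$min_pairs) return(NULL)
      select_differential(tumor[[mod]], normal[[mod]], d,
                          alpha_fdr = config$alpha_fdr_de,
                          boundary_percentiles = NULL,
                          min_pairs = config$min_pairs)
    })
    names(de_by_group[[mod]]) <- groups
    if (is.null(de_by_group[[mod]][[ref_group]])) {
      stop("stage diffexpr: reference group below min_pairs for ", mod,
           call. = FALSE)
    }
    d_ref <- design_all |> dplyr::filter(.data$patient_id %in%
                                           pats_by_group[[ref_group]])
    de_ref[[mod]] <- select_differential(tumor[[mod]], normal[[mod]], d_ref,
                                         alpha_fdr = config$alpha_fdr_de,
                                         min_pairs = config$min_pairs)
    write_stage_tsv(de_ref[[mod]], out_dir, paste0("de_", mod, "_", ref_group))
    selected <- de_ref[[mod]]$biomolecule_id[de_ref[[mod]]$selected]
    stage(sprintf("%s: %d/%d biomolecules selected in %s", mod,
                  length(selected), nrow(de_ref[[mod]]), ref_group))

    # standardized group-mean fold changes of the selected biomolecules
    grp_means <- vapply(groups, function(grp) {
      cols <- intersect(pats_by_group[[grp]], colnames(fc[[mod]]))
      rowMeans(unclass(fc[[mod]])[selected, cols, drop = FALSE],
               na.rm = TRUE)
    }, numeric(length(selected)))
    if (length(selected) >= 2) {
      grp_means[is.nan(grp_means)] <- NA_real_
      sds <- apply(grp_means, 1, sd, na.rm = TRUE)
      usable <- rowSums(is.na(grp_means)) == 0 & !is.na(sds) & sds > 0
      std_means <- (grp_means[usable, , drop = FALSE] -
                      rowMeans(grp_means[usable, , drop = FALSE])) /
        apply(grp_means[usable, , drop = FALSE], 1, sd)
      k_use <- min(config$hier_k, nrow(std_means))
      hier[[mod]] <- hierarchical_cluster(std_means, k_use)
      write_stage_tsv(hier[[mod]]$assignment, out_dir,
                      paste0("clusters_hier_", mod))
    }
    stage(sprintf("%s: hierarchical clustering into %d clusters", mod,
                  if (is.null(hier[[mod]])) 0L else hier[[mod]]$k))

    # SRH screen on the selected biomolecules
    both <- cbind(unclass(tumor[[mod]])[selected, , drop = FALSE],
                  unclass(normal[[mod]])[selected, , drop = FALSE])
    both <- both[, intersect(colnames(both), metadata$sample_id),
                 drop = FALSE]
    if (length(selected) >= 2) {
      srh[[mod]] <- srh_screen(
        expression_matrix(both, attr(tumor[[mod]], "modality"),
                          "log2_intensity"),
        metadata, cluster_assignments = hier[[mod]]$assignment,
        alpha_fdr = config$alpha_fdr_srh)
      write_stage_tsv(srh[[mod]]$summary, out_dir,
                      paste0("srh_summary_", mod))
    }
    stage(sprintf("%s: SRH screen done", mod))

    # extreme-expression loss
    ex_loss[[mod]] <- extreme_loss_table(
      tumor[[mod]], normal[[mod]], metadata,
      q_low = config$quantile_bounds[1],
      q_high = config$quantile_bounds[2]) |>
      dplyr::mutate(modality = mod, .before = 1)
    write_stage_tsv(ex_loss[[mod]], out_dir, paste0("extreme_loss_", mod))
    stage(sprintf("%s: extreme-expression loss computed", mod))

    # per-group DE sets and set-difference loss
    de_sets <- purrr::map(de_by_group[[mod]], function(r) {
      if (is.null(r)) character() else r$biomolecule_id[r$selected]
    })
    de_loss[[mod]] <- de_set_difference_loss(de_sets) |>
      dplyr::mutate(modality = mod, .before = 1)
    write_stage_tsv(de_loss[[mod]], out_dir, paste0("de_loss_", mod))
    stage(sprintf("%s: differential-set loss computed", mod))

    # confounder regressions
    conf_records[[mod]] <- confounder_lm(
      restore_expr(unclass(fc[[mod]])[selected, , drop = FALSE], fc[[mod]]),
      covariates)
    conf_summary[[mod]] <- summarize_confounders(
      conf_records[[mod]], p_threshold = config$confounder_p) |>
      dplyr::mutate(modality = mod, .before = 1)
    write_stage_tsv(conf_summary[[mod]], out_dir,
                    paste0("confounders_", mod))
    stage(sprintf("%s: confounder regressions done", mod))
  }

  # --- DPGP + intergroup shifts on the chosen modality -----------------
  mod <- config$dpgp_modality
  dpgp <- NULL; shifts <- NULL
  if (mod %in% modalities && !is.null(de_ref[[mod]])) {
    selected <- de_ref[[mod]]$biomolecule_id[de_ref[[mod]]$selected]
    pats_by_group <- split(pat_groups$patient_id, pat_groups$time_group)
    traj <- vapply(groups, function(grp) {
      cols <- intersect(pats_by_group[[grp]], colnames(fc[[mod]]))
      rowMeans(unclass(fc[[mod]])[selected, cols, drop = FALSE],
               na.rm = TRUE)
    }, numeric(length(selected)))
    traj[is.nan(traj)] <- NA_real_
    if (nrow(traj) >= 2) {
      dcfg <- config$dpgp
      dcfg$seed <- config$seed + 1000L
      dpgp <- dpgp_fit(traj, timepoints = seq_along(groups), config = dcfg)
      write_stage_tsv(dpgp$assignment, out_dir, "clusters_dpgp")
      write_stage_tsv(dpgp$cluster_curves, out_dir, "dpgp_curves")
    }
    glab <- stats::setNames(as.character(pat_groups$time_group),
                            pat_groups$patient_id)
    shifts <- intergroup_shift(
      restore_expr(unclass(fc[[mod]])[selected, , drop = FALSE], fc[[mod]]),
      glab, band = config$shift_band, min_group = config$min_pairs)
    write_stage_tsv(shifts, out_dir, "intergroup_shifts")
  }
  stage("DPGP clustering and intergroup shifts done")

  # --- cut-off recommendation -----------------------------------------
  isch_terms <- paste0("time_group", groups[-1])
  ischemia_coef <- purrr::map_dfr(modalities, function(mod) {
    tibble(modality = mod, group = groups[-1],
           mean_abs_coef = vapply(isch_terms, function(tm) {
             mean_abs_coefficient(conf_records[[mod]], tm,
                                  config$confounder_p)
           }, numeric(1)))
  })
  stage4_coef <- purrr::map_dfr(modalities, function(mod) {
    tibble(modality = mod,
           mean_abs_coef = mean_abs_coefficient(conf_records[[mod]],
                                                "stageIV",
                                                config$confounder_p))
  })
  cutoff <- recommend_cutoff(dplyr::bind_rows(de_loss), ischemia_coef,
                             stage4_coef, scheme,
                             loss_threshold = config$loss_threshold)
  write_stage_tsv(cutoff$table, out_dir, "cutoff_table")
  stage(sprintf("cut-off recommendation: %g min", cutoff$recommendation_min))

  results <- c(results, list(
    fold_changes = fc, de_reference = de_ref, de_by_group = de_by_group,
    hierarchical = hier, srh = srh, extreme_loss = dplyr::bind_rows(ex_loss),
    de_loss = dplyr::bind_rows(de_loss), dpgp = dpgp, shifts = shifts,
    confounder_records = conf_records,
    confounder_summary = dplyr::bind_rows(conf_summary),
    ischemia_coef = ischemia_coef, stage4_coef = stage4_coef,
    cutoff = cutoff, truth = truth))

  if (!is.null(out_dir)) {
    summary <- list(
      package = "ischemiaqc",
      version = as.character(utils::packageVersion("ischemiaqc")),
      schema_version = "1.0",
      seed = config$seed,
      scheme = scheme$name,
      thresholds = list(alpha_fdr_de = config$alpha_fdr_de,
                        alpha_fdr_srh = config$alpha_fdr_srh,
                        confounder_p = config$confounder_p,
                        quantile_bounds = config$quantile_bounds,
                        shift_band = config$shift_band,
                        loss_threshold = config$loss_threshold),
      group_counts = as.data.frame(counts),
      recommendation_min = cutoff$recommendation_min,
      recommended_group = cutoff$recommended_group)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  invisible(results)
}
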