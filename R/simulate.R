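# run code under a fixed RNG state, restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Table of tumor/normal pair counts per refined ischemia group in the
# emulated colorectal cohort (mRNA row), scaled by `size_factor`.
DEFAULT_GROUP_SIZES <- c(T1 = 181, T2 = 223, T3 = 111, T4 = 44, T5 = 18,
                         over = 36)

# integer minute ranges the refined groups cover (overflow capped at 35)
GROUP_MINUTES <- list(T1 = 1:9, T2 = 10:12, T3 = 13:15, T4 = 16:18,
                      T5 = 19:20, over = 21:35)

#' Simulation configuration for a paired multi-omics cohort
#'
#' Defines the cohort the generator emulates: paired tumor/normal samples
#' spread over refined ischemia time groups in the proportions of the
#' emulated colorectal cohort, a true differential set with log2 effects,
#' modality-graded ischemic decay (mRNA least, phosphosites most labile),
#' additive confounder effects on the tumor side, and missingness that
#' increases with ischemia time.
#'
#' @param n_biomolecules Named integer vector: biomolecules per expression
#'   modality.
#' @param size_factor Scales the default per-group pair counts
#'   (181/223/111/44/18/36 for T1..T5/overflow).
#' @param group_sizes Optional named integer vector of pairs per group,
#'   overriding `size_factor`.
#' @param true_de_fraction Fraction of biomolecules with a true
#'   tumor-vs-normal effect.
#' @param de_effect_mean,de_effect_sd Mean and SD of the absolute log2
#'   effect of true differential biomolecules (sign random).
#' @param baseline_mean,baseline_sd Mean and SD of baseline log2 abundance.
#' @param noise_sd Measurement noise SD (log2 units).
#' @param decay_rate Named per-modality per-minute drift coefficient toward
#'   the global mean; default ordered mRNA < protein < phosphosite.
#' @param decay_onset_min Minutes of ischemia before decay begins.
#' @param decaying_fraction Fraction of biomolecules subject to decay.
#' @param confounder_effects Named additive log2 shifts applied to the tumor
#'   side of confounder-affected biomolecules for `grade_high`, `stage_IV`
#'   and `alcohol_active` patients.
#' @param confounder_fraction Fraction of biomolecules carrying the
#'   confounder effects.
#' @param missingness_base,missingness_time_slope Per-cell missingness
#'   probability `base + slope * t`, clipped to `[0, 0.9]`.
#' @param n_loci Loci for the DNA submodality simulator.
#' @param correlate_covariates If `TRUE`, covariates are drawn with a mild
#'   dependence on ischemia time (stress-test mode); by default they are
#'   independent of time group.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_biomolecules = c(mRNA = 500, protein = 500,
                                          phosphosite = 500),
                       size_factor = 1, group_sizes = NULL,
                       true_de_fraction = 0.1,
                       de_effect_mean = 1.5, de_effect_sd = 0.5,
                       baseline_mean = 10, baseline_sd = 2,
                       noise_sd = 0.5,
                       decay_rate = c(mRNA = 0.02, protein = 0.05,
                                      phosphosite = 0.08),
                       decay_onset_min = 10,
                       decaying_fraction = 0.5,
                       confounder_effects = c(grade_high = 0.8,
                                              stage_IV = 0.5,
                                              alcohol_active = 0.4),
                       confounder_fraction = 0.15,
                       missingness_base = 0.02,
                       missingness_time_slope = 0.002,
                       n_loci = 500,
                       correlate_covariates = FALSE,
                       seed = 1L) {
  if (is.null(group_sizes)) {
    group_sizes <- pmax(2L, as.integer(round(DEFAULT_GROUP_SIZES * size_factor)))
    names(group_sizes) <- names(DEFAULT_GROUP_SIZES)
  }
  cfg <- list(n_biomolecules = n_biomolecules, group_sizes = group_sizes,
              true_de_fraction = true_de_fraction,
              de_effect_mean = de_effect_mean, de_effect_sd = de_effect_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, decay_rate = decay_rate,
              decay_onset_min = decay_onset_min,
              decaying_fraction = decaying_fraction,
              confounder_effects = confounder_effects,
              confounder_fraction = confounder_fraction,
              missingness_base = missingness_base,
              missingness_time_slope = missingness_time_slope,
              n_loci = n_loci, correlate_covariates = correlate_covariates,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$true_de_fraction, cfg$decaying_fraction,
          cfg$confounder_fraction, cfg$missingness_base)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (any(c(cfg$de_effect_sd, cfg$baseline_sd, cfg$noise_sd) <= 0)) {
    stop("SDs must be positive", call. = FALSE)
  }
  if (any(cfg$decay_rate < 0)) stop("decay rates must be non-negative",
                                    call. = FALSE)
  if (any(cfg$group_sizes < 2)) {
    stop("every time group needs at least 2 patients (paired tests impossible otherwise)",
         call. = FALSE)
  }
  if (!all(names(cfg$group_sizes) %in% names(GROUP_MINUTES))) {
    stop("group_sizes names must be among ",
         paste(names(GROUP_MINUTES), collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

simulate_metadata <- function(cfg) {
  gs <- cfg$group_sizes
  n_pat <- sum(gs)
  pid <- sprintf("P%04d", seq_len(n_pat))
  grp <- rep(names(gs), gs)
  t_min <- unlist(lapply(names(gs), function(g) {
    mins <- GROUP_MINUTES[[g]]
    sample(mins, gs[[g]], replace = TRUE)
  }), use.names = FALSE)
  stage_p <- c(I = 0.10, II = 0.35, III = 0.35, IV = 0.20)
  if (cfg$correlate_covariates) {
    # mild stress-test confounding: late groups skew toward high grade/stage
    late <- pmin(1, pmax(0, (t_min - 10) / 20))
    grade <- ifelse(stats::runif(n_pat) < 0.4 + 0.3 * late, "high", "low")
    stage <- vapply(late, function(l) {
      sample(names(stage_p), 1, prob = stage_p + c(-0.05, -0.05, 0, 0.1) * l)
    }, character(1))
  } else {
    grade <- sample(c("low", "high"), n_pat, replace = TRUE,
                    prob = c(0.6, 0.4))
    stage <- sample(names(stage_p), n_pat, replace = TRUE, prob = stage_p)
  }
  cov <- tibble(
    patient_id = pid,
    ischemia_min = t_min,
    age = round(stats::runif(n_pat, 40, 85)),
    gender = sample(c("female", "male"), n_pat, replace = TRUE),
    alcohol = sample(c("inactive", "active"), n_pat, replace = TRUE,
                     prob = c(0.7, 0.3)),
    meat = sample(c("low", "high"), n_pat, replace = TRUE),
    grade = grade,
    stage = stage,
    run_label = paste0("run", 1 + (seq_len(n_pat) - 1) %% 2)
  )
  dplyr::bind_rows(
    cov |> dplyr::mutate(sample_id = paste0(pid, "_T"), tissue = "tumor"),
    cov |> dplyr::mutate(sample_id = paste0(pid, "_N"), tissue = "normal")
  ) |>
    dplyr::select("sample_id", "patient_id", "tissue", "ischemia_min",
                  "age", "gender", "alcohol", "meat", "grade", "stage",
                  "run_label")
}

# mean-reversion decay applied in place: for decaying biomolecules and
# samples past onset, values drift toward the global mean by a fraction
# min(1, rate * (t - onset)) and pick up extra noise of the same magnitude
# as the base measurement noise
apply_decay <- function(vals, decaying, t_min, rate, onset, global_mean,
                        noise_sd) {
  past <- which(t_min > onset)
  if (!length(past) || !any(decaying) || rate <= 0) return(vals)
  f <- pmin(1, rate * (t_min[past] - onset))
  sub <- vals[decaying, past, drop = FALSE]
  drift <- sweep(global_mean - sub, 2, f, "*")
  sub <- sub + drift + matrix(stats::rnorm(length(sub), 0, noise_sd),
                              nrow = nrow(sub))
  vals[decaying, past] <- sub
  vals
}

#' Simulate a paired tumor/normal multi-omics cohort with known truth
#'
#' Per biomolecule i and patient p with ischemia time t: the normal value is
#' `b_i + noise`, the tumor value `b_i + d_i + gamma_i * c_p + noise`, with
#' baseline `b_i ~ N(baseline_mean, baseline_sd)`, true differential effect
#' `d_i` (zero for non-differential biomolecules) and confounder shift
#' `gamma_i * c_p` acting on the tumor side of affected biomolecules. For
#' decaying biomolecules with `t` past the onset, both tissues drift toward
#' the global mean by `min(1, decay_rate * (t - onset))` plus extra noise.
#' Cells go missing with probability `missingness_base + slope * t`.
#'
#' @param config A [sim_config()].
#' @return A list of class `ischemia_cohort` with elements `tumor` and
#'   `normal` (named lists of [expression_matrix()] per modality),
#'   `metadata` (sample metadata tibble) and `truth` (ground truth: tibbles
#'   `de`, `decaying`, `confounded`, plus the per-patient covariates).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    md <- simulate_metadata(config)
    pat <- md |> dplyr::filter(.data$tissue == "tumor")
    n_pat <- nrow(pat)
    conf_shift <-
      config$confounder_effects[["grade_high"]] * (pat$grade == "high") +
      config$confounder_effects[["stage_IV"]] * (pat$stage == "IV") +
      config$confounder_effects[["alcohol_active"]] * (pat$alcohol == "active")
    p_miss <- pmin(0.9, pmax(0, config$missingness_base +
                               config$missingness_time_slope * pat$ischemia_min))

    tumor <- list(); normal <- list()
    de_tbl <- list(); decay_tbl <- list(); conf_tbl <- list()
    for (mod in names(config$n_biomolecules)) {
      n_bio <- config$n_biomolecules[[mod]]
      ids <- sprintf("%s_%05d", mod, seq_len(n_bio))
      b <- stats::rnorm(n_bio, config$baseline_mean, config$baseline_sd)
      n_de <- round(config$true_de_fraction * n_bio)
      de_ids <- sample(ids, n_de)
      d <- stats::setNames(numeric(n_bio), ids)
      d[de_ids] <- sample(c(-1, 1), n_de, replace = TRUE) *
        stats::rnorm(n_de, config$de_effect_mean, config$de_effect_sd)
      decaying <- stats::setNames(logical(n_bio), ids)
      decaying[sample(ids, round(config$decaying_fraction * n_bio))] <- TRUE
      confounded <- stats::setNames(logical(n_bio), ids)
      confounded[sample(ids, round(config$confounder_fraction * n_bio))] <- TRUE

      noise <- function() matrix(stats::rnorm(n_bio * n_pat, 0, config$noise_sd),
                                 n_bio, n_pat)
      nrm <- b + noise()
      tum <- b + d + outer(as.numeric(confounded), conf_shift) + noise()
      rate <- config$decay_rate[[mod]]
      nrm <- apply_decay(nrm, decaying, pat$ischemia_min, rate,
                         config$decay_onset_min, config$baseline_mean,
                         config$noise_sd)
      tum <- apply_decay(tum, decaying, pat$ischemia_min, rate,
                         config$decay_onset_min, config$baseline_mean,
                         config$noise_sd)
      mask <- function(m) {
        miss <- matrix(stats::runif(length(m)), nrow(m)) <
          matrix(p_miss, nrow(m), ncol(m), byrow = TRUE)
        m[miss] <- NA_real_
        m
      }
      tum <- mask(tum); nrm <- mask(nrm)
      dimnames(tum) <- list(ids, paste0(pat$patient_id, "_T"))
      dimnames(nrm) <- list(ids, paste0(pat$patient_id, "_N"))
      emod <- if (mod %in% EXPR_MODALITIES) mod else "protein"
      tumor[[mod]] <- expression_matrix(tum, emod, "log2_intensity")
      normal[[mod]] <- expression_matrix(nrm, emod, "log2_intensity")
      de_tbl[[mod]] <- tibble(modality = mod, biomolecule_id = de_ids,
                              effect = unname(d[de_ids]))
      decay_tbl[[mod]] <- tibble(modality = mod,
                                 biomolecule_id = ids[decaying])
      conf_tbl[[mod]] <- tibble(modality = mod,
                                biomolecule_id = ids[confounded])
    }
    structure(list(
      tumor = tumor, normal = normal, metadata = md,
      truth = list(de = dplyr::bind_rows(de_tbl),
                   decaying = dplyr::bind_rows(decay_tbl),
                   confounded = dplyr::bind_rows(conf_tbl),
                   covariates = pat)
    ), class = "ischemia_cohort")
  })
}

#' @export
print.ischemia_cohort <- function(x, ...) {
  cat(sprintf("<ischemia_cohort> %d pairs, modalities: %s\n",
              nrow(x$truth$covariates),
              paste(names(x$tumor), collapse = ", ")))
  invisible(x)
}

#' Simulate DNA submodality matrices under the no-time-effect null
#'
#' Protein-affecting-mutation (PAM) counts are Poisson with a locus-specific
#' rate, and amplification/deletion/truncation indicators are Bernoulli with
#' a locus-specific probability; neither depends on the ischemia time group,
#' reflecting the stability of DNA under ischemia.
#'
#' @param config A [sim_config()].
#' @param metadata Optional tumor metadata to reuse (defaults to a fresh
#'   tumor sample set drawn under the config's group sizes).
#' @param pam_rates,binary_probs Optional per-locus Poisson rates and
#'   Bernoulli probabilities (defaults drawn uniformly).
#' @return A list with `matrices` (named list of [expression_matrix()]:
#'   `PAM`, `CNV_amp`, `CNV_del`, `truncation`) and `metadata` (tumor
#'   samples with ischemia minutes).
#' @export
simulate_dna_submodalities <- function(config, metadata = NULL,
                                       pam_rates = NULL, binary_probs = NULL) {
  validate_sim_config(config)
  with_seed(config$seed + 1L, {
    if (is.null(metadata)) {
      metadata <- simulate_metadata(config) |>
        dplyr::filter(.data$tissue == "tumor")
    }
    n_smp <- nrow(metadata)
    n_loci <- config$n_loci
    ids <- sprintf("locus_%05d", seq_len(n_loci))
    rates <- pam_rates %||% stats::runif(n_loci, 0.05, 3)
    probs <- binary_probs %||% stats::runif(n_loci, 0.01, 0.3)
    pam <- matrix(stats::rpois(n_loci * n_smp, rates), n_loci, n_smp,
                  dimnames = list(ids, metadata$sample_id))
    bin <- function() {
      matrix(as.numeric(stats::runif(n_loci * n_smp) <
                          rep(probs, n_smp)), n_loci, n_smp,
             dimnames = list(ids, metadata$sample_id))
    }
    list(matrices = list(
      PAM = expression_matrix(pam, "PAM", "count"),
      CNV_amp = expression_matrix(bin(), "CNV_amp", "binary"),
      CNV_del = expression_matrix(bin(), "CNV_del", "binary"),
      truncation = expression_matrix(bin(), "truncation", "binary")
    ), metadata = as_tibble(metadata))
  })
}

#' Simulate labelled pseudo-time trajectories
#'
#' Fixture generator for trajectory clustering: cluster mean curves are
#' vertically offset by at least `separation` (with a small smooth wiggle),
#' and each trajectory adds smooth squared-exponential Gaussian-process
#' noise of SD `noise_sd` plus white noise of SD `noise_sd / 2`.
#'
#' @param k_clusters Number of clusters (>= 1).
#' @param n_per_cluster Trajectories per cluster.
#' @param timepoints Number of timepoints (or a numeric vector of times).
#' @param separation Minimum vertical distance between cluster means.
#' @param noise_sd Trajectory noise SD.
#' @param seed Integer seed.
#' @return A list with `trajectories` (matrix, rows = trajectories),
#'   `timepoints` and integer `labels`.
#' @export
simulate_trajectories <- function(k_clusters, n_per_cluster, timepoints,
                                  separation, noise_sd, seed = 1L) {
  stopifnot(k_clusters >= 1, n_per_cluster >= 1)
  tp <- if (length(timepoints) == 1) seq_len(timepoints) else
    as.numeric(timepoints)
  if (length(tp) < 2) stop("need at least 2 timepoints", call. = FALSE)
  with_seed(seed, {
    span <- diff(range(tp))
    means <- vapply(seq_len(k_clusters), function(c) {
      offset <- (c - (k_clusters + 1) / 2) * separation
      offset + (separation / 10) * sin(2 * pi * (tp - tp[1]) / span +
                                         stats::runif(1, 0, 2 * pi))
    }, numeric(length(tp)))
    # smooth GP noise via squared-exponential covariance
    K <- outer(tp, tp, function(a, b) exp(-(a - b)^2 / (2 * (span / 3)^2)))
    L <- chol(K + diag(1e-8, length(tp)))
    n_tot <- k_clusters * n_per_cluster
    labels <- rep(seq_len(k_clusters), each = n_per_cluster)
    traj <- t(vapply(seq_len(n_tot), function(i) {
      means[, labels[i]] +
        noise_sd * as.vector(t(L) %*% stats::rnorm(length(tp))) +
        stats::rnorm(length(tp), 0, noise_sd / 2)
    }, numeric(length(tp))))
    rownames(traj) <- sprintf("traj_%04d", seq_len(n_tot))
    list(trajectories = traj, timepoints = tp, labels = labels)
  })
}
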