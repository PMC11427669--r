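#' Hierarchical clustering of standardized fold-change trajectories
#'
#' Euclidean distances between rows, complete-linkage agglomeration, tree
#' cut into k clusters; the dendrogram leaf order is returned for heatmap
#' export.
#'
#' @param std_fc_matrix Numeric matrix (or `expr_matrix`) of row-standardized
#'   mean log2 fold changes per time group; rows with missing entries are
#'   dropped with a warning.
#' @param k Number of clusters (>= 1, at most the number of rows).
#' @return A `hier_clust` object: `assignment` tibble (`biomolecule_id`,
#'   `cluster`), `leaf_order` (row ids in dendrogram order) and the
#'   underlying `hclust` tree.
#' @export
hierarchical_cluster <- function(std_fc_matrix, k) {
  vals <- unclass(std_fc_matrix)
  keep <- rowSums(is.na(vals)) == 0
  if (!all(keep)) {
    warning(sum(!keep), " row(s) with missing group means dropped",
            call. = FALSE)
    vals <- vals[keep, , drop = FALSE]
  }
  if (k < 1 || k > nrow(vals)) {
    stop("k must lie between 1 and the number of complete rows",
         call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(vals, method = "euclidean"),
                      method = "complete")
  cl <- stats::cutree(hc, k = k)
  structure(list(
    assignment = tibble(biomolecule_id = rownames(vals),
                        cluster = unname(cl)),
    leaf_order = rownames(vals)[hc$order],
    hclust = hc, k = k), class = "hier_clust")
}

#' @export
print.hier_clust <- function(x, ...) {
  cat(sprintf("<hier_clust> %d rows in %d clusters (complete linkage, Euclidean)\n",
              nrow(x$assignment), x$k))
  invisible(x)
}

#' @rdname hierarchical_cluster
#' @param x A `hier_clust` object.
#' @param ... Unused.
#' @export
tidy.hier_clust <- function(x, ...) x$assignment

#' Configuration of the Dirichlet-process Gaussian-process mixture
#'
#' @param alpha Dirichlet-process concentration parameter (default 0.1:
#'   strong prior preference for few clusters).
#' @param m Number of auxiliary empty candidate clusters per Gibbs step.
#' @param noise_shape,noise_scale Shape and scale of the inverse-gamma
#'   prior on the observation noise variance (defaults 4 and 2).
#' @param signal_variance,length_scale Initial squared-exponential kernel
#'   hyperparameters; `NULL` means data-driven (empirical trajectory
#'   variance, half the time span).
#' @param iterations,burn_in Gibbs sweeps and burn-in.
#' @param hyper_refresh_every Refresh kernel hyperparameters by per-cluster
#'   marginal-likelihood maximization every this many sweeps.
#' @param seed Integer seed for the sampler.
#' @return A `dpgp_config` list.
#' @export
dpgp_config <- function(alpha = 0.1, m = 12, noise_shape = 4,
                        noise_scale = 2, signal_variance = NULL,
                        length_scale = NULL, iterations = 500,
                        burn_in = 250, hyper_refresh_every = 20,
                        seed = 1L) {
  stopifnot(alpha > 0, m >= 1, iterations > burn_in)
  structure(list(alpha = alpha, m = m, noise_shape = noise_shape,
                 noise_scale = noise_scale,
                 signal_variance = signal_variance,
                 length_scale = length_scale, iterations = iterations,
                 burn_in = burn_in,
                 hyper_refresh_every = hyper_refresh_every,
                 seed = as.integer(seed)),
            class = "dpgp_config")
}

se_kernel <- function(tp, sf2, ell) {
  sf2 * exp(-outer(tp, tp, "-")^2 / (2 * ell^2))
}

# log density of y ~ N(mu, S) via cholesky
ldmvnorm <- function(y, mu, S_chol) {
  z <- backsolve(S_chol, y - mu, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(S_chol))) -
    0.5 * length(y) * log(2 * pi)
}

# Marginal log likelihood of the n_c trajectories in a cluster:
# y_j = f + eps, f ~ GP(0, K), eps ~ N(0, sn2 I). Decomposes into the mean
# trajectory (cov sn2/n I + K, scaled) and within-cluster residuals.
cluster_marginal_ll <- function(Y, K, sn2) {
  n <- nrow(Y); T <- ncol(Y)
  ybar <- colMeans(Y)
  S <- n * K + diag(sn2, T)
  ch <- chol(S)
  ll_mean <- ldmvnorm(sqrt(n) * ybar, rep(0, T), ch) + (T / 2) * log(n)
  if (n > 1) {
    ss_within <- sum(sweep(Y, 2, ybar)^2)
    ll_res <- -ss_within / (2 * sn2) - ((n - 1) * T / 2) * log(2 * pi * sn2)
  } else ll_res <- 0
  ll_mean + ll_res
}

# Predictive cache for a cluster: posterior mean of f given the members and
# cholesky of the predictive covariance for a new trajectory.
cluster_cache <- function(Y, tp, hyper) {
  K <- se_kernel(tp, hyper["sf2"], hyper["ell"])
  sn2 <- hyper["sn2"]
  T <- length(tp)
  if (is.null(Y) || nrow(Y) == 0) {
    mu <- rep(0, T)
    pred_cov <- K + diag(sn2, T)
  } else {
    n <- nrow(Y)
    ybar <- colMeans(Y)
    A <- K + diag(sn2 / n, T)
    Ainv_ybar <- solve(A, ybar)
    mu <- as.vector(K %*% Ainv_ybar)
    Sigma_f <- K - K %*% solve(A, K)
    pred_cov <- Sigma_f + diag(sn2, T)
  }
  list(mu = mu, chol = chol((pred_cov + t(pred_cov)) / 2), K = K)
}

optimise_hyper <- function(Y, tp, hyper, cfg) {
  obj <- function(par) {
    sf2 <- exp(par[1]); ell <- exp(par[2]); sn2 <- exp(par[3])
    K <- se_kernel(tp, sf2, ell)
    ll <- tryCatch(cluster_marginal_ll(Y, K, sn2), error = function(e) -Inf)
    # inverse-gamma prior on the noise variance (MAP refresh)
    lp <- -(cfg$noise_shape + 1) * log(sn2) - cfg$noise_scale / sn2
    -(ll + lp)
  }
  fit <- tryCatch(
    stats::optim(log(hyper[c("sf2", "ell", "sn2")]), obj,
                 method = "L-BFGS-B",
                 lower = log(c(1e-4, 1e-2, 1e-4)),
                 upper = log(c(1e4, 1e3, 1e4))),
    error = function(e) NULL)
  if (is.null(fit)) return(hyper)
  out <- exp(fit$par)
  names(out) <- c("sf2", "ell", "sn2")
  out
}

#' Dirichlet-process Gaussian-process mixture clustering of trajectories
#'
#' Clusters pseudo-time trajectories with a Dirichlet-process mixture whose
#' components are Gaussian processes with squared-exponential kernels plus
#' observation noise carrying an inverse-gamma prior. Partitions are Gibbs
#' sampled with auxiliary-parameter updates: a trajectory joins an occupied
#' cluster with probability proportional to its size times the GP posterior
#' predictive likelihood, or one of `m` empty candidates with probability
#' proportional to `alpha / m` times the prior marginal likelihood. Kernel
#' hyperparameters are refreshed per cluster by marginal-likelihood
#' maximization at a configurable cadence. The returned partition is the
#' sampled partition with maximum posterior score after burn-in (a
#' posterior-similarity consensus is also available).
#'
#' @param trajectories Numeric matrix, rows = biomolecule trajectories,
#'   columns = timepoints; rows with missing values are dropped with a
#'   warning.
#' @param timepoints Numeric vector of pseudo-time coordinates (defaults to
#'   ordinal indices).
#' @param config A [dpgp_config()].
#' @param partition Partition selection: `"map"` (default) or `"psm"`
#'   (posterior-similarity consensus via average-linkage clustering cut at
#'   the MAP cluster count).
#' @return A `dpgp_fit` object: `assignment` tibble, `cluster_curves`
#'   tibble (posterior mean and mean +/- 2 sigma band per cluster and
#'   timepoint), `k`, `map_log_posterior`, per-cluster hyperparameters and
#'   the config.
#' @export
dpgp_fit <- function(trajectories, timepoints = NULL,
                     config = dpgp_config(), partition = c("map", "psm")) {
  partition <- match.arg(partition)
  Y <- as.matrix(trajectories)
  if (is.null(rownames(Y))) rownames(Y) <- sprintf("traj_%04d", seq_len(nrow(Y)))
  keep <- rowSums(is.na(Y)) == 0
  if (!all(keep)) {
    warning(sum(!keep), " trajectory(ies) with missing values dropped",
            call. = FALSE)
    Y <- Y[keep, , drop = FALSE]
  }
  n <- nrow(Y)
  if (n < 1) stop("no complete trajectories to cluster", call. = FALSE)
  tp <- timepoints %||% seq_len(ncol(Y))
  if (length(tp) < 2) stop("need at least 2 timepoints", call. = FALSE)

  # the prior signal variance must cover the spread of whole trajectories,
  # not just within-trajectory wiggle, or empty clusters cannot attract
  # offset trajectories
  default_hyper <- c(
    sf2 = config$signal_variance %||% max(stats::var(as.vector(Y)), 1e-3),
    ell = config$length_scale %||% (diff(range(tp)) / 2),
    sn2 = config$noise_scale / (config$noise_shape - 1))

  if (n == 1) {
    z <- 1L
    hypers <- list(default_hyper)
    curves <- dpgp_curves(Y, z, tp, hypers)
    return(structure(list(
      assignment = tibble(biomolecule_id = rownames(Y), cluster = z),
      cluster_curves = curves, k = 1L, map_log_posterior = NA_real_,
      hyper = hypers, config = config, n = 1L), class = "dpgp_fit"))
  }

  with_seed(config$seed, {
    z <- rep(1L, n)
    hypers <- list(default_hyper)
    caches <- list(cluster_cache(Y, tp, hypers[[1]]))
    empty_cache <- cluster_cache(NULL, tp, default_hyper)

    rebuild <- function(c_id) {
      idx <- which(z == c_id)
      caches[[c_id]] <<- cluster_cache(Y[idx, , drop = FALSE], tp,
                                       hypers[[c_id]])
    }
    log_alpha_m <- log(config$alpha / config$m)

    best_score <- -Inf; best_z <- z
    samples <- matrix(0L, nrow = 0, ncol = n)

    for (sweep in seq_len(config$iterations)) {
      for (i in seq_len(n)) {
        ci <- z[i]
        z[i] <- 0L
        n_c <- tabulate(z, nbins = length(hypers))
        if (n_c[ci] == 0) {
          # cluster emptied: drop it, relabel
          keep_ids <- which(n_c > 0)
          relab <- integer(length(hypers)); relab[keep_ids] <- seq_along(keep_ids)
          z <- ifelse(z == 0L, 0L, relab[z])
          hypers <- hypers[keep_ids]
          caches <- caches[keep_ids]
          n_c <- n_c[keep_ids]
        } else {
          rebuild(ci)
        }
        k_occ <- length(hypers)
        logw <- numeric(k_occ + config$m)
        for (c_id in seq_len(k_occ)) {
          logw[c_id] <- log(n_c[c_id]) +
            ldmvnorm(Y[i, ], caches[[c_id]]$mu, caches[[c_id]]$chol)
        }
        ll_empty <- ldmvnorm(Y[i, ], empty_cache$mu, empty_cache$chol)
        logw[k_occ + seq_len(config$m)] <- log_alpha_m + ll_empty
        w <- exp(logw - max(logw))
        pick <- sample.int(length(w), 1, prob = w)
        if (pick > k_occ) {
          z[i] <- k_occ + 1L
          hypers[[k_occ + 1L]] <- default_hyper
          caches[[k_occ + 1L]] <- empty_cache
          rebuild(k_occ + 1L)
        } else {
          z[i] <- pick
          rebuild(pick)
        }
      }

      if (sweep %% config$hyper_refresh_every == 0) {
        for (c_id in seq_along(hypers)) {
          idx <- which(z == c_id)
          hypers[[c_id]] <- optimise_hyper(Y[idx, , drop = FALSE], tp,
                                           hypers[[c_id]], config)
          rebuild(c_id)
        }
        empty_cache <- cluster_cache(NULL, tp, default_hyper)
      }

      if (sweep > config$burn_in) {
        score <- partition_log_score(Y, z, tp, hypers, config)
        if (score > best_score) {
          best_score <- score
          best_z <- z
        }
        samples <- rbind(samples, z)
      }
    }

    z_final <- best_z
    if (partition == "psm" && nrow(samples) > 1) {
      sim <- matrix(0, n, n)
      for (s in seq_len(nrow(samples))) {
        sim <- sim + outer(samples[s, ], samples[s, ], "==")
      }
      sim <- sim / nrow(samples)
      hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
      z_final <- stats::cutree(hc, k = length(unique(best_z)))
    }
    # canonical labels in order of first appearance
    z_final <- as.integer(factor(z_final, levels = unique(z_final)))
    k <- length(unique(z_final))
    final_hypers <- lapply(seq_len(k), function(c_id) {
      optimise_hyper(Y[z_final == c_id, , drop = FALSE], tp, default_hyper,
                     config)
    })
    curves <- dpgp_curves(Y, z_final, tp, final_hypers)
    structure(list(
      assignment = tibble(biomolecule_id = rownames(Y), cluster = z_final),
      cluster_curves = curves, k = k, map_log_posterior = best_score,
      hyper = final_hypers, config = config, n = n), class = "dpgp_fit")
  })
}

# CRP prior + GP marginal likelihoods of the current partition
partition_log_score <- function(Y, z, tp, hypers, cfg) {
  n_c <- table(z)
  n <- length(z)
  lprior <- length(n_c) * log(cfg$alpha) + sum(lgamma(as.numeric(n_c))) -
    sum(log(cfg$alpha + seq_len(n) - 1))
  llik <- sum(vapply(seq_along(hypers), function(c_id) {
    idx <- which(z == c_id)
    if (!length(idx)) return(0)
    h <- hypers[[c_id]]
    cluster_marginal_ll(Y[idx, , drop = FALSE],
                        se_kernel(tp, h["sf2"], h["ell"]), h["sn2"])
  }, numeric(1)))
  lprior + llik
}

# posterior mean curve and +/- 2 sigma predictive band per cluster
dpgp_curves <- function(Y, z, tp, hypers) {
  purrr::map_dfr(seq_along(hypers), function(c_id) {
    idx <- which(z == c_id)
    cache <- cluster_cache(Y[idx, , drop = FALSE], tp, hypers[[c_id]])
    sigma <- sqrt(diag(crossprod(cache$chol)))
    tibble(cluster = c_id, time = tp, mean = cache$mu,
           lower = cache$mu - 2 * sigma, upper = cache$mu + 2 * sigma,
           n_members = length(idx))
  })
}

#' @export
print.dpgp_fit <- function(x, ...) {
  cat(sprintf("<dpgp_fit> %d trajectories in %d clusters (alpha = %g, m = %d)\n",
              x$n, x$k, x$config$alpha, x$config$m))
  invisible(x)
}

#' @rdname dpgp_fit
#' @param x A `dpgp_fit` object.
#' @param ... Unused.
#' @export
tidy.dpgp_fit <- function(x, ...) x$assignment

#' @rdname dpgp_fit
#' @export
glance.dpgp_fit <- function(x, ...) {
  tibble(k = x$k, n = x$n, iterations = x$config$iterations,
         burn_in = x$config$burn_in,
         map_log_posterior = x$map_log_posterior)
}

#' Expected number of Dirichlet-process clusters under the prior
#'
#' Closed form `sum_{i=1..n} alpha / (alpha + i - 1)`, which grows as
#' `alpha * log(n)`.
#'
#' @param alpha Concentration parameter.
#' @param n Number of items.
#' @return The expected cluster count.
#' @export
dp_expected_clusters <- function(alpha, n) {
  sum(alpha / (alpha + seq_len(n) - 1))
}
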