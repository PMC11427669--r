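# Independent brute-force oracles used to freeze expected values.

# exact two-sided signed-rank p by enumerating all sign assignments
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Benjamini-Hochberg by definition: min over j >= i of p_(j) * m / j
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-way rank ANOVA sums of squares from group/cell means (balanced case)
srh_oracle <- function(values, a, b) {
  r <- rank(values)
  n <- length(r)
  gm <- mean(r)
  ss_total <- sum((r - gm)^2)
  ss_a <- sum(tapply(r, a, function(x) length(x) * (mean(x) - gm)^2))
  ss_b <- sum(tapply(r, b, function(x) length(x) * (mean(x) - gm)^2))
  cell <- tapply(r, list(a, b), mean)
  cnt <- table(a, b)
  ss_cells <- sum(cnt * (cell - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  tie_tab <- table(r)
  D <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  ms_total <- ss_total / (n - 1)
  list(H = c(tissue = ss_a, time = ss_b, interaction = ss_ab) /
         (ms_total * D),
       ss = c(tissue = ss_a, time = ss_b, interaction = ss_ab,
              total = ss_total))
}

# Kruskal-Wallis H from the textbook rank formula (no ties)
kw_oracle <- function(y, g) {
  n <- length(y)
  r <- rank(y)
  rbar <- tapply(r, g, mean)
  ni <- table(g)
  12 / (n * (n + 1)) * sum(ni * rbar^2) - 3 * (n + 1)
}

# adjusted Rand index via the independent mclust implementation
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# simulate the expected number of Chinese-restaurant-process clusters
crp_expected_k <- function(alpha, n, reps, seed = 1) {
  with_seed <- get("with_seed", asNamespace("ischemiaqc"))
  with_seed(seed, {
    mean(vapply(seq_len(reps), function(r) {
      k <- 1L; sizes <- 1L
      for (i in 2:n) {
        p <- c(sizes, alpha)
        pick <- sample.int(k + 1L, 1L, prob = p)
        if (pick > k) { k <- k + 1L; sizes <- c(sizes, 1L) }
        else sizes[pick] <- sizes[pick] + 1L
      }
      as.numeric(k)
    }, numeric(1)))
  })
}

# small covariate table exercising every confounder level
toy_covariates <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = round(runif(n, 40, 85)),
    gender = sample(c("female", "male"), n, TRUE),
    alcohol = sample(c("inactive", "active"), n, TRUE),
    meat = sample(c("low", "high"), n, TRUE),
    grade = sample(c("low", "high"), n, TRUE),
    stage = sample(c("I", "II", "III", "IV"), n, TRUE),
    time_group = factor(sample(paste0("T", 1:5), n, TRUE),
                        levels = paste0("T", 1:5))
  )
}

toy_expr <- function(vals, modality = "protein", scale = "log2_intensity",
                     ids = NULL, samples = NULL) {
  m <- as.matrix(vals)
  rownames(m) <- ids %||% sprintf("b%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%03d", seq_len(ncol(m)))
  ischemiaqc::expression_matrix(m, modality, scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
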