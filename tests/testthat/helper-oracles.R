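# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately use brute force / enumeration, not the package's
# own code paths.

# AUC by exhaustive pair concordance: P(case score > control score) with
# ties counting one half.
auc_bruteforce <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cs) * length(ct))
}

# Two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n + m, n) group assignments of the pooled values (tie-free input).
wilcox_enumerate <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * length(y) / 2
  # two-sided: assignments at least as extreme (in |W - mean|) as observed
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Trapezoidal area under (x, y) points.
trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# A flat spectrum of constant intensity.
const_spectrum <- function(value, mz = seq(1000, 2000), id = "s1") {
  new_spectrum(mz, rep(value, length(mz)), id, id)
}

# Gaussian peaks + optional exponential baseline on a 1 Da grid.
gauss_spectrum <- function(centers, heights, sds, mz = seq(1000, 10000),
                           baseline_amp = 0, baseline_decay = 3000,
                           noise_sd = 0, id = "s1", label = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- baseline_amp * exp(-(mz - mz[1]) / baseline_decay)
  for (i in seq_along(centers)) {
    y <- y + heights[i] * exp(-(mz - centers[i])^2 / (2 * sds[i]^2))
  }
  if (noise_sd > 0) y <- y + rnorm(length(mz), 0, noise_sd)
  new_spectrum(mz, y, id, id, label = label)
}

# Feature matrix with class-shifted marker columns on Gaussian noise:
# marker j gets mean shift `delta` in the case group.
shifted_fm <- function(n_case, n_control, p, n_marker = 0, delta = 2,
                       seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  x <- matrix(rnorm(n * p), n, p)
  labels <- rep(c("case", "control"), c(n_case, n_control))
  if (n_marker > 0) {
    x[labels == "case", seq_len(n_marker)] <-
      x[labels == "case", seq_len(n_marker)] + delta
  }
  colnames(x) <- paste0("f", seq_len(p))
  new_feature_matrix(x, paste0("s", seq_len(n)), labels, colnames(x))
}

# Small fast simulated cohort for integration-style tests.
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(
    n_cases = 8L, n_controls = 8L, mass_range = c(1000, 4000),
    n_background_peaks = 20L, n_marker_peaks = 2L,
    marker_fold_changes = c(0.6, 1.8), seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
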