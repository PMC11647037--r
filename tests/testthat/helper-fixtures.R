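# Shared fixtures and independent oracles, built in code at test time.

fx_groups <- build_default_groups()
fx_kinetics <- tumor_kinetics_params()

# A free-growth schedule (no radiation, no drug) with configurable
# measurement days.
fx_free_schedule <- function(days = default_measurement_days()) {
  treatment_schedule("free", measurement_days = days)
}

# Small encoded dataset: selected groups x n replicates.
fx_dataset <- function(group_idx = c(1, 3, 4), n = 3L, noise = 0.02,
                       seed = 11L, params = fx_kinetics, vc_scale = 1e-3) {
  sel <- fx_groups[group_idx]
  cohorts <- simulate_cohorts(sel, params, n_replicates = n,
                              noise_level = noise, seed = seed)
  encode_dataset(cohorts, fx_groups, vc_scale = vc_scale)
}

# Brute-force scaled dot-product attention: elementwise loops, no reuse of
# package internals.
naive_attention <- function(Q, K, V, mask = NULL) {
  n <- nrow(Q); m <- nrow(K); dk <- ncol(K)
  W <- matrix(0, n, m)
  for (i in seq_len(n)) {
    s <- numeric(m)
    for (j in seq_len(m)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    allowed <- if (is.null(mask)) rep(TRUE, m) else mask[i, ]
    if (!any(allowed)) next
    e <- exp(s[allowed] - max(s[allowed]))
    W[i, allowed] <- e / sum(e)
  }
  list(context = W %*% V, weights = W)
}

# Random trajectory on a random subset of valid measurement days.
fx_random_trajectory <- function(n_points = 6L) {
  days <- sort(sample(-3:24, n_points))
  trajectory(days, stats::runif(n_points, 20, 1400))
}

# Central finite-difference gradient of the masked loss wrt one parameter
# entry, through the R forward pass.
fx_numeric_grad <- function(params, sample, name, idx, cfg = model_config(),
                            h = 1e-6) {
  p2 <- params
  p2[[name]][idx] <- p2[[name]][idx] + h
  l1 <- masked_l2_loss(forward(sample, p2, cfg)$predictions, sample$target)
  p2[[name]][idx] <- p2[[name]][idx] - 2 * h
  l0 <- masked_l2_loss(forward(sample, p2, cfg)$predictions, sample$target)
  (l1 - l0) / (2 * h)
}

# cross-file cache for expensive fitted objects reused between blocks
acceptance_cache <- new.env(parent = emptyenv())
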