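# Benchmark generators shared across tests: all deterministic under the
# seed they are given, all returning std_panel objects.

# Unidirectionally coupled logistic maps: y (autonomous, chaotic) drives x
# with the given coupling; the classic cross-mapping benchmark.
sim_coupled_logistic <- function(seed, coupling = 0.3, n_steps = 200,
                                 burn = 200, r_x = 3.8, r_y = 3.7) {
  set.seed(seed)
  x <- stats::runif(1, 0.2, 0.8)
  y <- stats::runif(1, 0.2, 0.8)
  xs <- ys <- numeric(n_steps + burn)
  for (t in seq_len(n_steps + burn)) {
    xn <- x * (r_x - r_x * x - coupling * y)
    yn <- y * (r_y - r_y * y)
    x <- min(max(xn, 1e-6), 1 - 1e-6)
    y <- min(max(yn, 1e-6), 1 - 1e-6)
    xs[t] <- x; ys[t] <- y
  }
  as_std_panel(cbind(x = xs[-seq_len(burn)], y = ys[-seq_len(burn)]))
}

# Two independent AR(1) series (a null pair).
sim_ar1_pair <- function(seed, n_steps = 200, phi = 0.5) {
  set.seed(seed)
  as_std_panel(cbind(
    x = as.vector(stats::arima.sim(list(ar = phi), n_steps)),
    y = as.vector(stats::arima.sim(list(ar = phi), n_steps))))
}

# Two uncoupled short-memory Ricker species driven by the same seasonal
# temperature: the common-driver (confounding) scenario. Short memory
# (r near 1) keeps the driver's influence blockable by a finite
# conditioning set.
sim_shared_driver <- function(seed, n_steps = 150, r = 1.05, beta = 0.5,
                              noise = 0.15) {
  params <- make_params(2, connectance = 0, gamma_scale = 0, seed = seed,
                        beta_sd = 0, r_range = c(r, r),
                        process_noise_sd = noise)
  params$beta <- c(beta, beta)
  temp <- simulate_temperature(1, n_steps, noise_sd = 0.3, seed = seed + 500)
  lat <- simulate_abundance(params, temp, seed = seed + 1000)
  as_std_panel(cbind(a = lat$abundance[, 1, 1], b = lat$abundance[, 2, 1],
                     temperature = as.vector(temp)),
               env_vars = "temperature")
}

# Histogram plug-in transfer entropy y -> x on series discretized into
# `n_bins` states: sum p(x', x, y) log[ p(x'|x, y) / p(x'|x) ].
plugin_te <- function(x, y, n_bins = 3) {
  dx <- cut(x, stats::quantile(x, seq(0, 1, length.out = n_bins + 1)),
            include.lowest = TRUE, labels = FALSE)
  dy <- cut(y, stats::quantile(y, seq(0, 1, length.out = n_bins + 1)),
            include.lowest = TRUE, labels = FALSE)
  n <- length(x) - 1L
  xf <- dx[-1]; x0 <- dx[-length(dx)]; y0 <- dy[-length(dy)]
  p3 <- table(xf, x0, y0) / n
  p_x0y0 <- table(x0, y0) / n
  p_xfx0 <- table(xf, x0) / n
  p_x0 <- table(x0) / n
  te <- 0
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) for (k in seq_len(n_bins)) {
    p <- p3[i, j, k]
    if (p > 0) {
      te <- te + p * log((p / p_x0y0[j, k]) / (p_xfx0[i, j] / p_x0[j]))
    }
  }
  te
}

# Brute-force enumeration of valid (delay vector, target) rows for an
# embedding: an independent oracle for the vectorized constructor.
count_embeddings_oracle <- function(site_lengths, E, tau, tp) {
  total <- 0L
  for (len in site_lengths) {
    for (t in seq_len(len)) {
      lags_ok <- all(t - (seq_len(E) - 1L) * tau >= 1)
      tgt <- t + tp
      if (lags_ok && tgt >= 1 && tgt <= len) total <- total + 1L
    }
  }
  total
}
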