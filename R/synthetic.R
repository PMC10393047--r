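# Synthetic multispecies community with temperature-modulated interactions,
# observed through a metabarcoding + internal spike-in sampling model.
# Provides the ground-truth Jacobian oracle used to validate the inference
# stages on data where the interaction structure is known exactly.

#' Draw community parameters for the temperature-modulated Ricker simulator
#'
#' Draws growth rates, a signed sparse interaction matrix, and temperature
#' modulation coefficients for a discrete-time multispecies Ricker community
#' \deqn{x_{i,t+1} = x_{i,t} \exp(r_i + \beta_i \tilde T_t -
#'   \sum_j a_{ij} (1 + \gamma_{ij} \tilde T_t) x_{j,t} + \epsilon_{i,t}),}
#' where \eqn{\tilde T} is standardized water temperature. Diagonal entries
#' \eqn{a_{ii} = r_i} give every species a deterministic equilibrium at 1;
#' growth rates are drawn in the chaotic Ricker regime so that trajectories
#' carry enough dynamical information for state-space reconstruction.
#'
#' Parameter sets whose noise-free trajectory diverges (exceeds 1e6 or turns
#' non-finite during a burn-in plus observation horizon) are rejected and
#' redrawn from the continuing RNG stream; the number of rejections is kept in
#' the `rejections` field.
#'
#' @param n_species Number of species (>= 2, or 1 for single-species checks).
#' @param connectance Probability that an off-diagonal interaction is present.
#' @param gamma_scale Scale of the temperature-modulation slopes
#'   \eqn{\gamma_{ij}} (0 switches temperature modulation of couplings off).
#' @param seed Integer RNG seed.
#' @param r_range Range of intrinsic growth rates (per half-month step).
#' @param a_range Range of absolute off-diagonal interaction magnitudes.
#' @param beta_sd SD of the growth-rate temperature slopes \eqn{\beta_i}.
#' @param process_noise_sd Per-step log-scale process noise SD.
#' @param gamma_sign Optional per-species sign (+1/-1/0) forced on the
#'   temperature modulation of the interactions each species *receives*
#'   (row i of \eqn{\gamma}); `NULL` draws signs at random.
#' @param check_steps,burnin Horizon used for the divergence check.
#' @param max_reject Abort after this many rejected draws.
#' @return An object of class `community_params`.
#' @export
make_params <- function(n_species, connectance, gamma_scale = 0, seed = 1,
                        r_range = c(2.7, 3.3), a_range = c(0.1, 0.35),
                        beta_sd = 0.3, process_noise_sd = 0.05,
                        gamma_sign = NULL, check_steps = 200, burnin = 100,
                        max_reject = 50) {
  stopifnot(n_species >= 1, connectance >= 0, connectance <= 1)
  if (!is.null(gamma_sign)) stopifnot(length(gamma_sign) == n_species)
  set.seed(as.integer(seed) %% 2147483647L)
  rejections <- 0L
  repeat {
    r <- stats::runif(n_species, r_range[1], r_range[2])
    a <- matrix(0, n_species, n_species)
    diag(a) <- r
    n_off <- n_species * (n_species - 1L)
    if (n_off > 0) {
      present <- stats::rbinom(n_off, 1L, connectance) == 1L
      mag <- stats::runif(n_off, a_range[1], a_range[2])
      sgn <- sample(c(-1, 1), n_off, replace = TRUE)
      off <- which(row(a) != col(a))
      a[off] <- present * mag * sgn
    }
    gam <- matrix(0, n_species, n_species)
    if (gamma_scale != 0 && n_off > 0) {
      off_nz <- which(row(a) != col(a) & a != 0)
      if (length(off_nz)) {
        # |gamma| stays below ~1/max|ttilde| so the modulation factor
        # (1 + gamma * ttilde) keeps its sign across the seasonal range
        u <- stats::runif(length(off_nz), 0.7, 1.3)
        s <- if (is.null(gamma_sign)) {
          sample(c(-1, 1), length(off_nz), replace = TRUE)
        } else {
          gamma_sign[row(a)[off_nz]]
        }
        gam[off_nz] <- gamma_scale * u * s
      }
    }
    beta <- stats::rnorm(n_species, 0, beta_sd)
    params <- structure(
      list(n_species = n_species, r = r, a = a, gamma = gam, beta = beta,
           process_noise_sd = process_noise_sd, seed = as.integer(seed),
           connectance = connectance, rejections = rejections),
      class = "community_params")
    if (.params_stable(params, burnin + check_steps)) return(params)
    rejections <- rejections + 1L
    if (rejections > max_reject) {
      stop("make_params: rejected ", rejections,
           " parameter draws (unstable regime); lower connectance or a_range")
    }
  }
}

# Divergence check under representative seasonal forcing: a
# standardized-temperature sinusoid spanning +-1.8 SD (roughly what a
# seasonal cycle standardizes to), so that temperature-modulated couplings
# are probed at both extremes, plus the constant-temperature map, plus one
# noisy replicate at the parameter set's own process-noise level (drawn
# from a stream derived from the base seed, with the caller's RNG state
# restored afterwards).
.params_stable <- function(params, n_steps) {
  n <- params$n_species
  run <- function(amp, eps_mat) {
    x <- rep(1, n)
    for (t in seq_len(n_steps)) {
      tt <- amp * cos(2 * pi * t / 24)
      x <- .ricker_step(params, x, tt, eps_mat[t, ])
      if (any(!is.finite(x)) || any(x > 1e6)) return(FALSE)
    }
    TRUE
  }
  zeros <- matrix(0, n_steps, n)
  for (amp in c(0, 1.8)) if (!run(amp, zeros)) return(FALSE)
  if (params$process_noise_sd > 0) {
    state <- get0(".Random.seed", globalenv())
    set.seed((params$seed * 7919L + 13L) %% 2147483647L)
    ok <- TRUE
    for (rep in 1:6) {
      # margin: noise drawn at twice the nominal level
      eps <- matrix(stats::rnorm(n_steps * n, 0, 2 * params$process_noise_sd),
                    n_steps, n)
      if (!run(1.5, eps)) { ok <- FALSE; break }
    }
    if (!is.null(state)) assign(".Random.seed", state, globalenv())
    if (!ok) return(FALSE)
  }
  TRUE
}

# One Ricker update; ttilde is standardized temperature, eps log-scale noise.
.ricker_step <- function(params, x, ttilde, eps) {
  a_eff <- params$a * (1 + params$gamma * ttilde)
  g <- params$r + params$beta * ttilde - as.vector(a_eff %*% x) + eps
  x * exp(g)
}

#' @export
print.community_params <- function(x, ...) {
  off <- x$a[row(x$a) != col(x$a)]
  cat("Community parameters:", x$n_species, "species,",
      sum(off != 0), "of", length(off), "off-diagonal couplings,\n",
      " gamma range [", round(min(x$gamma), 3), ",", round(max(x$gamma), 3),
      "], process noise sd", x$process_noise_sd,
      ",", x$rejections, "stability rejections\n")
  invisible(x)
}

#' Simulate seasonal water temperature across sites
#'
#' Generates per-site temperature series with sinusoidal seasonality, a
#' between-site mean gradient (emulating a latitudinal gradient along a
#' coastline), and optional observation noise.
#'
#' @param n_sites Number of sites.
#' @param n_steps Steps per site (half-monthly sampling: 24 steps/year).
#' @param mean_temp Across-site mean temperature (degrees C).
#' @param amplitude Seasonal half-range (degrees C); noise-free range is
#'   exactly `2 * amplitude` when `period` divides the horizon.
#' @param period Steps per seasonal cycle (default 24, half-monthly).
#' @param gradient Span of site means (degrees C), ordered along sites.
#' @param noise_sd Observation noise SD (degrees C).
#' @param seed RNG seed.
#' @return `n_steps x n_sites` matrix of temperatures.
#' @export
simulate_temperature <- function(n_sites, n_steps, mean_temp = 19,
                                 amplitude = 6, period = 24, gradient = 2,
                                 noise_sd = 0.5, seed = 1) {
  stopifnot(n_sites >= 1, n_steps >= 1, period >= 2)
  set.seed(as.integer(seed) %% 2147483647L)
  site_means <- if (n_sites == 1) mean_temp else
    mean_temp - gradient / 2 + gradient * (seq_len(n_sites) - 1) / (n_sites - 1)
  seas <- amplitude * cos(2 * pi * seq_len(n_steps) / period)
  temp <- outer(seas, rep(1, n_sites)) +
    outer(rep(1, n_steps), site_means) +
    matrix(stats::rnorm(n_steps * n_sites, 0, noise_sd), n_steps, n_sites)
  colnames(temp) <- paste0("site", sprintf("%02d", seq_len(n_sites)))
  temp
}

# Deterministic per-(site, species) noise sub-seed, so that decoupled
# communities reproduce exactly as collections of single-species runs.
.noise_subseed <- function(seed, site, species_id) {
  (as.integer(seed) + 7919L * as.integer(site) +
     104729L * as.integer(species_id)) %% 2147483647L
}

#' Simulate latent community abundance under temperature forcing
#'
#' Iterates the temperature-modulated Ricker map at each site, with a
#' discarded burn-in so the observed window starts on the attractor.
#' Temperature is standardized across the whole panel (all sites and steps);
#' during burn-in the temperature series is recycled cyclically.
#'
#' Process noise for species i at site s is drawn from a sub-stream seeded by
#' (seed, s, `species_ids[i]`), so runs of decoupled subsets reproduce the
#' full-community trajectories exactly.
#'
#' @param params A `community_params` object.
#' @param temperature `n_steps x n_sites` temperature matrix (degrees C).
#' @param seed RNG seed.
#' @param burnin Discarded initial steps (default 100).
#' @param x0 Optional initial abundance vector (defaults drawn near 1).
#' @param species_ids Integer ids entering the noise sub-seeds.
#' @return A list of class `abundance_panel`: `abundance` (array
#'   `n_steps x n_species x n_sites`), `temperature`, `ttilde` (standardized),
#'   and the scaling used (`temp_mean`, `temp_sd`).
#' @export
simulate_abundance <- function(params, temperature, seed = 1, burnin = 100,
                               x0 = NULL, species_ids = seq_len(params$n_species)) {
  stopifnot(inherits(params, "community_params"))
  temperature <- as.matrix(temperature)
  n_steps <- nrow(temperature)
  n_sites <- ncol(temperature)
  n <- params$n_species
  tmu <- mean(temperature)
  tsd <- stats::sd(as.vector(temperature))
  if (!is.finite(tsd) || tsd == 0) tsd <- 1
  ttilde <- (temperature - tmu) / tsd

  out <- array(NA_real_, c(n_steps, n, n_sites),
               dimnames = list(NULL, paste0("sp", sprintf("%02d", species_ids)),
                               colnames(temperature)))
  for (s in seq_len(n_sites)) {
    # per-species streams: initial state first, then process noise, so a
    # decoupled subset reproduces the full community run exactly
    eps <- matrix(0, burnin + n_steps, n)
    x <- rep_len(if (is.null(x0)) NA_real_ else x0, n)
    for (i in seq_len(n)) {
      set.seed(.noise_subseed(seed, s, species_ids[i]))
      draw <- stats::runif(1, 0.5, 1.5)
      if (is.null(x0)) x[i] <- draw
      if (params$process_noise_sd > 0) {
        eps[, i] <- stats::rnorm(burnin + n_steps, 0, params$process_noise_sd)
      }
    }
    tt_burn <- ttilde[((seq_len(burnin) - 1L) %% n_steps) + 1L, s]
    for (t in seq_len(burnin)) {
      x <- .ricker_step(params, x, tt_burn[t], eps[t, ])
      if (any(!is.finite(x)) || any(x > 1e8)) {
        stop("simulate_abundance: divergence at burn-in step ", t,
             ", site ", s)
      }
    }
    for (t in seq_len(n_steps)) {
      out[t, , s] <- x
      x <- .ricker_step(params, x, ttilde[t, s], eps[burnin + t, ])
      if (any(!is.finite(x)) || any(x > 1e8)) {
        stop("simulate_abundance: divergence at step ", t, ", site ", s)
      }
    }
  }
  structure(list(abundance = out, temperature = temperature, ttilde = ttilde,
                 temp_mean = tmu, temp_sd = tsd),
            class = "abundance_panel")
}

#' Analytic Jacobian of the community update map
#'
#' Closed-form partial derivatives \eqn{\partial x_{i,t+1} / \partial x_{j,t}}
#' of the temperature-modulated Ricker update, evaluated at a state vector and
#' standardized temperature. This is the ground truth against which S-map
#' coefficients (time-varying interaction strengths) are validated.
#'
#' @param params A `community_params` object.
#' @param x State vector (abundances at time t).
#' @param ttilde Standardized temperature at time t.
#' @return `n_species x n_species` Jacobian matrix; entry (i, j) is the effect
#'   of species j's current abundance on species i's next abundance.
#' @export
jacobian_oracle <- function(params, x, ttilde = 0) {
  stopifnot(inherits(params, "community_params"),
            length(x) == params$n_species)
  a_eff <- params$a * (1 + params$gamma * ttilde)
  g <- params$r + params$beta * ttilde - as.vector(a_eff %*% x)
  xn <- x * exp(g)             # x_{t+1}
  jac <- -xn * a_eff           # row i scaled by x_{i,t+1}
  diag(jac) <- exp(g) * (1 - x * diag(a_eff))
  jac
}

#' Observe latent abundances through metabarcoding with a spike-in standard
#'
#' Reads per sample are multinomial with probabilities proportional to latent
#' abundance at or above the detection floor (total reads = sequencing depth);
#' the spike-in species' absolute concentration is additionally measured by
#' qPCR with multiplicative lognormal noise (mean-preserving). Latent
#' abundances below the floor receive zero reads deterministically, and a
#' spike below the floor yields a zero qPCR measurement.
#'
#' @param panel An `abundance_panel` from [simulate_abundance()].
#' @param sequencing_depth Reads per sample.
#' @param spike_species Index of the internal-standard species.
#' @param qpcr_cv Coefficient of variation of the qPCR copy measurement.
#' @param detection_floor Minimum latent abundance registering any signal.
#' @param seed RNG seed.
#' @return Long-format data.frame: site, time_index, species, reads,
#'   spike_copies, temperature. Latent abundance is interpreted as eDNA
#'   copies per microlitre.
#' @export
observe <- function(panel, sequencing_depth = 2e4, spike_species = 1,
                    qpcr_cv = 0.2, detection_floor = 1e-3, seed = 1) {
  stopifnot(inherits(panel, "abundance_panel"), sequencing_depth > 0)
  ab <- panel$abundance
  n_steps <- dim(ab)[1]; n <- dim(ab)[2]; n_sites <- dim(ab)[3]
  stopifnot(spike_species >= 1, spike_species <= n)
  sp_names <- dimnames(ab)[[2]]
  site_names <- dimnames(ab)[[3]]
  if (is.null(site_names)) site_names <- paste0("site", sprintf("%02d", seq_len(n_sites)))
  sdlog <- sqrt(log(1 + qpcr_cv^2))
  set.seed(as.integer(seed) %% 2147483647L)
  rows <- vector("list", n_sites * n_steps)
  k <- 0L
  for (s in seq_len(n_sites)) {
    for (t in seq_len(n_steps)) {
      x <- ab[t, , s]
      p <- ifelse(x >= detection_floor, x, 0)
      reads <- if (sum(p) > 0) {
        as.vector(stats::rmultinom(1, sequencing_depth, p))
      } else rep(0L, n)
      spike_lat <- unname(x[spike_species])
      spike_meas <- if (spike_lat >= detection_floor) {
        spike_lat * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
      } else 0
      k <- k + 1L
      rows[[k]] <- data.frame(
        site = site_names[s], time_index = t, species = sp_names,
        reads = reads, spike_copies = spike_meas,
        temperature = unname(panel$temperature[t, s]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic eDNA survey
#'
#' End-to-end convenience wrapper: community parameters, seasonal multi-site
#' temperature, latent dynamics, inert additional covariates (salinity, wave
#' height, tide level, which do not force the dynamics), and the
#' metabarcoding + spike-in observation layer. Returns both the observed
#' long-format sample panel and the ground truth needed by the oracles.
#'
#' @param n_species,n_sites,n_steps Community and survey dimensions.
#' @param connectance,gamma_scale,seed Passed to [make_params()].
#' @param temperature Optional pre-built temperature matrix.
#' @param sequencing_depth,spike_species,qpcr_cv,detection_floor Observation
#'   model, see [observe()].
#' @param ... Further arguments to [make_params()].
#' @return List: `panel` (long data.frame with reads, spike copies and
#'   environmental covariates), `truth` (`community_params`), `latent`
#'   (`abundance_panel`).
#' @export
simulate_community <- function(n_species = 8, n_sites = 3, n_steps = 50,
                               connectance = 0.2, gamma_scale = 0, seed = 1,
                               temperature = NULL, sequencing_depth = 2e4,
                               spike_species = 1, qpcr_cv = 0.2,
                               detection_floor = 1e-3, ...) {
  params <- make_params(n_species, connectance, gamma_scale, seed = seed, ...)
  if (is.null(temperature)) {
    temperature <- simulate_temperature(n_sites, n_steps, seed = seed + 1L)
  }
  latent <- simulate_abundance(params, temperature, seed = seed + 2L)
  panel <- observe(latent, sequencing_depth = sequencing_depth,
                   spike_species = spike_species, qpcr_cv = qpcr_cv,
                   detection_floor = detection_floor, seed = seed + 3L)
  # inert covariates: realistic ranges, no influence on the dynamics
  set.seed((as.integer(seed) + 4L) %% 2147483647L)
  env <- expand.grid(time_index = seq_len(n_steps),
                     site = colnames(temperature),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  env$salinity <- 33 + stats::rnorm(nrow(env), 0, 0.6)
  env$wave <- stats::rlnorm(nrow(env), log(0.8), 0.4)
  env$tide <- 100 + 40 * sin(2 * pi * env$time_index / 2.2) +
    stats::rnorm(nrow(env), 0, 10)
  panel <- merge(panel, env, by = c("site", "time_index"), sort = FALSE)
  panel <- panel[order(panel$site, panel$time_index, panel$species), ]
  rownames(panel) <- NULL
  list(panel = panel, truth = params, latent = latent)
}
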