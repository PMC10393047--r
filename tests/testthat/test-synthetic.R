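# The community simulator: parameter drawing, temperature forcing, Ricker
# dynamics, the analytic Jacobian, and the observation layer.

test_that("make_params respects connectance and self-limitation", {
  p_full <- make_params(2, connectance = 1, seed = 7)
  off <- p_full$a[row(p_full$a) != col(p_full$a)]
  expect_true(all(off != 0))
  expect_true(all(diag(p_full$a) > 0))

  p_zero <- make_params(5, connectance = 0, seed = 7)
  expect_true(all(p_zero$a[row(p_zero$a) != col(p_zero$a)] == 0))

  p_sparse <- make_params(10, connectance = 0.2, seed = 1)
  n_nz <- sum(p_sparse$a[row(p_sparse$a) != col(p_sparse$a)] != 0)
  # Bernoulli(90, 0.2) count: essentially-sure range
  expect_gte(n_nz, qbinom(1e-5, 90, 0.2))
  expect_lte(n_nz, qbinom(1 - 1e-5, 90, 0.2))

  expect_error(make_params(0, 0.5), "n_species")
})

test_that("gamma modulation honours per-species sign constraints", {
  p <- make_params(6, connectance = 0.5, gamma_scale = 0.5, seed = 3,
                   gamma_sign = c(1, -1, 1, -1, 1, -1))
  for (i in 1:6) {
    gi <- p$gamma[i, -i][p$a[i, -i] != 0]
    if (length(gi)) {
      expect_true(all(sign(gi) == c(1, -1, 1, -1, 1, -1)[i]))
    }
  }
})

test_that("simulate_temperature produces exact seasonal and site structure", {
  t0 <- simulate_temperature(3, 48, amplitude = 0, noise_sd = 0, gradient = 0)
  expect_true(all(apply(t0, 2, function(z) diff(range(z))) == 0))

  t1 <- simulate_temperature(1, 48, amplitude = 5, noise_sd = 0, period = 24)
  expect_equal(diff(range(t1)), 10)

  t2 <- simulate_temperature(11, 48, gradient = 4, noise_sd = 0)
  expect_equal(diff(range(colMeans(t2))), 4)

  expect_identical(simulate_temperature(2, 30, seed = 5),
                   simulate_temperature(2, 30, seed = 5))
})

test_that("Ricker dynamics: equilibrium, decoupling, chaos", {
  # fixed point x* = r / a = 1
  p1 <- make_params(1, 0, seed = 1, process_noise_sd = 0)
  p1$a[1, 1] <- p1$r
  p1$beta <- 0
  temp <- matrix(19, 50, 1)
  lat <- simulate_abundance(p1, temp, x0 = 1, burnin = 0)
  expect_equal(unname(lat$abundance[, 1, 1]), rep(1, 50), tolerance = 1e-12)

  # zero coupling: a joint run equals the single-species runs exactly
  # (noise streams are seeded per species id)
  p2 <- make_params(2, connectance = 0, seed = 11, process_noise_sd = 0.1)
  temp2 <- simulate_temperature(1, 40, seed = 2)
  joint <- simulate_abundance(p2, temp2, seed = 5)
  for (i in 1:2) {
    solo <- p2
    solo$n_species <- 1L
    solo$r <- p2$r[i]; solo$a <- p2$a[i, i, drop = FALSE]
    solo$gamma <- p2$gamma[i, i, drop = FALSE]; solo$beta <- p2$beta[i]
    lat_i <- simulate_abundance(solo, temp2, seed = 5, species_ids = i)
    expect_equal(unname(joint$abundance[, i, 1]),
                 unname(lat_i$abundance[, 1, 1]), tolerance = 1e-12)
  }

  # chaotic single-species Ricker: no period <= 8 over 500 steps
  pc <- make_params(1, 0, seed = 1, process_noise_sd = 0,
                    r_range = c(2.9, 2.9))
  pc$a[1, 1] <- 2.9
  pc$beta <- 0
  latc <- simulate_abundance(pc, matrix(19, 500, 1), x0 = 0.73, burnin = 100)
  xs <- latc$abundance[, 1, 1]
  for (per in 1:8) {
    expect_gt(max(abs(xs[-seq_len(per)] - xs[seq_len(500 - per)])), 1e-3)
  }
})

test_that("jacobian_oracle matches finite differences of the update map", {
  expect_equal(jacobian_oracle(make_params(3, 0, seed = 2), c(1, 2, 0.5))[
    row(diag(3)) != col(diag(3))], rep(0, 6))

  p1 <- make_params(1, 0, seed = 1)
  p1$a[1, 1] <- p1$r
  p1$beta <- 0
  expect_equal(jacobian_oracle(p1, 1, 0)[1, 1], 1 - p1$r, tolerance = 1e-12)

  p3 <- make_params(3, 0.8, gamma_scale = 0.4, seed = 9)
  x <- c(0.8, 1.3, 0.6)
  tt <- 0.7
  jac <- jacobian_oracle(p3, x, tt)
  h <- 1e-6
  for (j in 1:3) {
    xp <- xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    fd <- (ednaflow:::.ricker_step(p3, xp, tt, rep(0, 3)) -
             ednaflow:::.ricker_step(p3, xm, tt, rep(0, 3))) / (2 * h)
    expect_equal(jac[, j], fd, tolerance = 1e-6)
  }
})

test_that("observation layer: multinomial split, floor, depth invariance", {
  p2 <- make_params(2, 0, seed = 1, process_noise_sd = 0)
  lat <- structure(list(
    abundance = array(1, c(5, 2, 1),
                      dimnames = list(NULL, c("sp01", "sp02"), "site01")),
    temperature = matrix(19, 5, 1), ttilde = matrix(0, 5, 1),
    temp_mean = 19, temp_sd = 1), class = "abundance_panel")
  obs <- observe(lat, sequencing_depth = 1e6, spike_species = 1,
                 qpcr_cv = 0, seed = 4)
  reads1 <- obs$reads[obs$species == "sp01"]
  # symmetric multinomial: binomial 99.9% CI around half the depth
  expect_true(all(abs(reads1 - 5e5) < 4 * sqrt(1e6 * 0.25)))
  # noise-free qPCR reports the latent spike concentration exactly
  expect_equal(unique(obs$spike_copies), 1)

  lat$abundance[, 2, ] <- 1e-9   # below the default floor
  obs0 <- observe(lat, sequencing_depth = 1000, seed = 4)
  expect_true(all(obs0$reads[obs0$species == "sp02"] == 0))

  # read proportions converge to abundance proportions at high depth
  set.seed(31)
  ab <- runif(10, 0.2, 3)
  lat10 <- structure(list(
    abundance = array(rep(ab, each = 3), c(3, 10, 1),
                      dimnames = list(NULL, sprintf("sp%02d", 1:10), "site01")),
    temperature = matrix(19, 3, 1), ttilde = matrix(0, 3, 1),
    temp_mean = 19, temp_sd = 1), class = "abundance_panel")
  obs10 <- observe(lat10, sequencing_depth = 1e6, seed = 8)
  prop <- obs10$reads[obs10$time_index == 1] / 1e6
  expect_lt(max(abs(cumsum(prop) - cumsum(ab / sum(ab)))), 0.01)

  expect_identical(observe(lat10, seed = 3), observe(lat10, seed = 3))
})

test_that("simulate_community produces a well-formed sample panel", {
  sim <- simulate_community(n_species = 4, n_sites = 2, n_steps = 20,
                            connectance = 0.3, seed = 2)
  expect_setequal(names(sim$panel),
                  c("site", "time_index", "species", "reads", "spike_copies",
                    "temperature", "salinity", "wave", "tide"))
  expect_equal(nrow(sim$panel), 4 * 2 * 20)
  expect_s3_class(sim$truth, "community_params")
  # one spike measurement per sample
  per_sample <- tapply(sim$panel$spike_copies,
                       paste(sim$panel$site, sim$panel$time_index),
                       function(z) length(unique(z)))
  expect_true(all(per_sample == 1))
})
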