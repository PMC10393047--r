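# Network assembly, strength tables, and the gamma-family additive models
# of interaction strength.

fake_edges <- function(te) {
  n <- length(te)
  data.frame(cause = sprintf("c%d", seq_len(n)),
             effect = sprintf("e%d", seq_len(n)),
             tp = rep(-1L, n), te = te, p_value = rep(0.01, n),
             clear = rep(TRUE, n))
}

test_that("build_network applies the retention quantile", {
  net <- build_network(fake_edges(1:10), q = 0.8)
  expect_equal(sum(net$retained), 2)
  expect_true(all(net$te[net$retained] >= 9))

  expect_equal(sum(build_network(fake_edges(1:10), q = 0)$retained), 10)

  sizes <- sapply(seq(0, 1, 0.1), function(q)
    sum(build_network(fake_edges(rnorm(25)), q)$retained))
  expect_true(all(diff(sizes) <= 0))

  expect_error(build_network(fake_edges(numeric(0))), "no clear edges")
})

make_records <- function(n_t = 30) {
  # one edge A -> B over n_t time points at one site
  data.frame(target = "B", coef = c(rep("A", n_t), rep("B", n_t),
                                    rep("(intercept)", n_t)),
             lag = c(rep(0L, 2 * n_t), rep(NA, n_t)),
             site = "s1", time_index = rep(1:n_t, 3),
             value = c(rnorm(n_t, 0.5, 0.1), rnorm(n_t), rnorm(n_t)),
             skill = 0.8, E = 1)
}

make_obs_panel <- function(n_t = 30) {
  expand.grid(site = "s1", time_index = 1:n_t,
              species = c("A", "B"), KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE) |>
    transform(copies = runif(2 * n_t, 0.5, 2),
              temperature = 19 + 6 * cos(2 * pi * (1:n_t) / 24))
}

test_that("strength_table mirrors each record into one in- and one out-row", {
  set.seed(2)
  rec <- make_records(30)
  pan <- make_obs_panel(30)
  st <- strength_table(rec, pan)
  expect_equal(sum(st$direction == "in" & st$species == "B"), 30)
  expect_equal(sum(st$direction == "out" & st$species == "A"), 30)
  # intercepts and own-lags never appear
  expect_false(any(st$partner == "(intercept)"))
  expect_equal(nrow(st), 60)
  expect_equal(st$strength, abs(st$is_value))
  expect_true(all(st$richness == 2))
  # conservation: every cross-species record appears exactly once per side
  expect_equal(sort(st$time_index[st$direction == "in"]),
               sort(st$time_index[st$direction == "out"]))
})

sim_gamma_obs <- function(seed, slope, n_site = 3, n_spp = 6, n_t = 30) {
  set.seed(seed)
  d <- expand.grid(site = paste0("s", 1:n_site),
                   species = paste0("sp", 1:n_spp), t = 1:n_t,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$partner <- sample(paste0("p", 1:4), nrow(d), replace = TRUE)
  d$temperature <- 19 + 6 * cos(2 * pi * d$t / 24) + rnorm(nrow(d), 0, 0.5)
  re_site <- rnorm(n_site, 0, 0.3)
  re_spp <- rnorm(n_spp, 0, 0.3)
  mu <- exp(-1 + slope * (d$temperature - 19) +
              re_site[match(d$site, paste0("s", 1:n_site))] +
              re_spp[match(d$species, paste0("sp", 1:n_spp))])
  d$strength <- rgamma(nrow(d), shape = 2, scale = mu / 2)
  d$direction <- "in"
  d
}

test_that("fit_strength_model recovers a generative temperature effect", {
  hits <- vapply(1:10, function(s) {
    f <- fit_strength_model(sim_gamma_obs(s, 0.1), "temperature", "in")
    f$clear && f$endpoint_diff > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  f <- fit_strength_model(sim_gamma_obs(1, 0.1), "temperature", "in")
  expect_s3_class(f, "strength_fit")
  expect_equal(nrow(f$curve), 100)
  expect_true(all(f$curve$lower <= f$curve$fit & f$curve$fit <= f$curve$upper))
})

test_that("fit_strength_model guards its degenerate inputs", {
  d <- sim_gamma_obs(2, 0)
  expect_error(fit_strength_model(d[1:40, ], "temperature", "in"), "need > 50")
  d$temperature <- 19
  expect_error(fit_strength_model(d, "temperature", "in"), "unique value")
  d2 <- sim_gamma_obs(2, 0)
  expect_error(fit_strength_model(d2, "depth", "in"), "unknown predictor")
  # zero strengths are floored, not dropped
  d3 <- sim_gamma_obs(3, 0)
  d3$strength[1:10] <- 0
  f <- fit_strength_model(d3, "temperature", "in")
  expect_equal(f$n_floored, 10)
})

test_that("species_temperature_effects classifies per-species trends", {
  d_up <- sim_gamma_obs(4, 0.12)
  d_up$partner <- "p1"
  eff <- species_temperature_effects(d_up, direction = "in", min_rows = 30)
  expect_true(all(eff$clear, na.rm = TRUE))
  expect_true(all(eff$class[eff$clear] == "increasing"))

  d_dn <- sim_gamma_obs(5, -0.12)
  eff_dn <- species_temperature_effects(d_dn, direction = "in")
  expect_true(all(eff_dn$class[eff_dn$clear] == "decreasing"))

  # degenerate highlight threshold: every clear species is highlighted
  eff_hl <- species_temperature_effects(d_up, direction = "in",
                                        alpha_highlight = 1)
  expect_true(all(eff_hl$highlight[eff_hl$clear], na.rm = TRUE))

  # species below the row floor are skipped with a notice
  d_small <- rbind(d_up[d_up$species == "sp1", ],
                   head(d_up[d_up$species == "sp2", ], 10))
  eff_sm <- species_temperature_effects(d_small, direction = "in",
                                        min_rows = 50)
  skipped <- eff_sm[!is.na(eff_sm$error) & grepl("skipped", eff_sm$error), ]
  expect_gt(nrow(skipped), 0)
})
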