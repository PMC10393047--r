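# Embedding construction, nearest-neighbour regression, and embedding
# dimension selection.

test_that("embedding counts match the exhaustive enumeration oracle", {
  one_site <- as_std_panel(matrix(rnorm(5), dimnames = list(NULL, "x")))
  sp <- time_delay_embed(one_site, "x", E = 2, tau = 1, tp = 1)
  expect_equal(nrow(sp$points), 3)

  # identity embedding returns the raw series
  sp1 <- time_delay_embed(one_site, "x", E = 1, tau = 1, tp = 0)
  expect_equal(sp1$points[, 1], one_site$values[, "x"])
  expect_equal(sp1$targets, one_site$values[, "x"])

  two_sites <- as_std_panel(
    matrix(rnorm(50), dimnames = list(NULL, "x")),
    site = rep(c("a", "b"), c(30, 20)))
  sp2 <- time_delay_embed(two_sites, "x", E = 3, tau = 1, tp = 1)
  expect_equal(nrow(sp2$points), 44)
  # no delay vector crosses the boundary: all source rows of a vector
  # belong to the same site as the row itself
  expect_true(all(sp2$time[sp2$site == "a"] <= 29))
  expect_true(all(sp2$time[sp2$site == "b"] >= 33))

  set.seed(4)
  for (rep in 1:10) {
    lens <- sample(8:40, sample(1:3, 1), replace = TRUE)
    E <- sample(1:4, 1); tau <- sample(1:2, 1); tp <- sample(-3:2, 1)
    panel <- as_std_panel(
      matrix(rnorm(sum(lens)), dimnames = list(NULL, "x")),
      site = rep(letters[seq_along(lens)], lens))
    expected <- count_embeddings_oracle(lens, E, tau, tp)
    got <- tryCatch(nrow(time_delay_embed(panel, "x", E = E, tau = tau,
                                          tp = tp)$points),
                    error = function(e) 0L)
    expect_equal(got, expected,
                 info = sprintf("lens=%s E=%d tau=%d tp=%d",
                                paste(lens, collapse = ","), E, tau, tp))
  }
})

test_that("rows touching missing values are dropped, not interpolated", {
  x <- rnorm(20)
  x[7] <- NA
  panel <- as_std_panel(matrix(x, dimnames = list(NULL, "x")))
  sp <- time_delay_embed(panel, "x", E = 2, tau = 1, tp = 1)
  # t = 7 and 8 lose a coordinate, t = 6 loses its target
  expect_false(any(sp$time %in% 6:8))
  expect_true(all(is.finite(sp$points)))
})

test_that("knn_regress behaves at its exact and degenerate limits", {
  set.seed(5)
  panel <- as_std_panel(matrix(rnorm(40), dimnames = list(NULL, "x")))
  sp <- time_delay_embed(panel, "x", E = 2, tau = 1, tp = 1)

  # query equal to a library point with k = 1 returns that point's target
  q <- sp$points[13, , drop = FALSE]
  out <- knn_regress(sp, query = q, k = 1)
  expect_equal(out$predictions, sp$targets[13])

  # constant targets are reproduced for any query (convexity of weights)
  sp_const <- sp
  sp_const$targets <- rep(2.5, length(sp$targets))
  outc <- knn_regress(sp_const, query = matrix(rnorm(6), 3), k = 4)
  expect_equal(outc$predictions, rep(2.5, 3))

  # k = library size with uniform weights equals the library target mean
  outm <- knn_regress(sp_const, query = q, k = nrow(sp$points),
                      weights = "uniform")
  expect_equal(outm$predictions, mean(sp_const$targets))
  sp2 <- sp
  outm2 <- knn_regress(sp2, query = matrix(c(10, -10), 1),
                       k = nrow(sp$points), weights = "uniform")
  expect_equal(outm2$predictions, mean(sp$targets))
})

test_that("simplex forecasting is skilful on smooth and chaotic signals", {
  # noise-free sine wave, E = 2: one-step forecast correlation > 0.99
  s <- sin(2 * pi * (1:150) / 25)
  panel <- as_std_panel(matrix(s, dimnames = list(NULL, "x")))
  sp <- time_delay_embed(panel, "x", E = 2, tau = 1, tp = 1)
  pred <- knn_regress(sp)
  expect_gt(cor(pred, sp$targets), 0.99)

  # chaotic Ricker at its true dimension: skill > 0.9; observation noise
  # degrades the average skill
  pc <- make_params(1, 0, seed = 1, process_noise_sd = 0,
                    r_range = c(2.9, 2.9))
  pc$a[1, 1] <- 2.9; pc$beta <- 0
  xs <- simulate_abundance(pc, matrix(19, 300, 1), x0 = 0.7)$abundance[, 1, 1]
  skill_at <- function(z) {
    pn <- as_std_panel(matrix(z, dimnames = list(NULL, "x")))
    spn <- time_delay_embed(pn, "x", E = 1, tau = 1, tp = 1)
    cor(knn_regress(spn), spn$targets)
  }
  expect_gt(skill_at(xs), 0.9)
  set.seed(8)
  noisy_skill <- mean(replicate(5, skill_at(xs + rnorm(300, 0, 0.5 * sd(xs)))))
  expect_lt(noisy_skill, skill_at(xs))
})

test_that("embedding dimension selection: noise floor and invariances", {
  set.seed(10)
  panel <- as_std_panel(matrix(rnorm(300), dimnames = list(NULL, "x")))
  expect_equal(select_embedding_dimension(panel, "x")$E, 1L)

  # affine rescaling of the raw series leaves the selection unchanged
  p <- sim_coupled_logistic(3)
  raw <- p$values[, "x"] * 3.7 - 11        # arbitrary affine map
  p_resc <- as_std_panel(matrix(raw, dimnames = list(NULL, "x")))
  set.seed(42); e1 <- select_embedding_dimension(p, "x")$E
  set.seed(42); e2 <- select_embedding_dimension(p_resc, "x")$E
  expect_identical(e1, e2)

  # the scan never exceeds E_max
  expect_lte(select_embedding_dimension(p, "x", E_max = 2)$E, 2L)
})

test_that("cross-map dimension resolves the coupled-logistic attractor", {
  # the 2-species system needs 2-3 coordinates; the cross-map dimension
  # (own optimal E + 1) should land there in most runs
  set.seed(77)
  Es <- vapply(1:10, function(s) {
    p <- sim_coupled_logistic(s)
    select_embedding_dimension(p, "x")$E + 1L
  }, integer(1))
  expect_gte(mean(Es %in% 2:3), 0.8)
})
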