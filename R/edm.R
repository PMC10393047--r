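# State-space reconstruction primitives: time-delay embedding with site
# boundaries and missing data, nearest-neighbour (simplex-style) regression,
# and embedding-dimension selection by predictive information gain.

# Lag a merged series within site segments: y[t] = x[t - lag], NA where the
# lagged index falls outside t's segment. Negative lag looks forward.
.shift_within <- function(x, segments, lag) {
  n <- length(x)
  y <- rep(NA_real_, n)
  src <- seq_len(n) - lag
  ok <- src >= 1 & src <= n
  ok[ok] <- segments[src[ok]] == segments[ok]
  y[ok] <- x[src[ok]]
  y
}

# Build a delay-coordinate matrix + target from a std_panel.
# coords: data.frame(var, lag) with lag in steps (>= 0, value at t - lag);
# target_var predicted at t + tp. Rows with any NA are dropped.
.embed_frame <- function(panel, coords, target_var, tp) {
  vals <- panel$values
  seg <- panel$segments
  pts <- matrix(NA_real_, nrow(vals), nrow(coords))
  nm <- character(nrow(coords))
  for (j in seq_len(nrow(coords))) {
    pts[, j] <- .shift_within(vals[, coords$var[j]], seg, coords$lag[j])
    nm[j] <- if (coords$lag[j] == 0) coords$var[j] else
      paste0(coords$var[j], "_lag", coords$lag[j])
  }
  colnames(pts) <- nm
  tgt <- .shift_within(vals[, target_var], seg, -tp)
  valid <- stats::complete.cases(pts) & !is.na(tgt)
  list(points = pts[valid, , drop = FALSE], targets = tgt[valid],
       time = which(valid), site = panel$site[valid],
       segments = seg[valid])
}

#' Time-delay embedding of a standardized panel
#'
#' Builds the reconstructed state space \eqn{\{x_t, x_{t-\tau}, \dots,
#' x_{t-(E-1)\tau}, z_t\}} for an effect variable with optional conditioning
#' coordinates, paired with the target variable at \eqn{t + tp}. Delay
#' vectors never span a site boundary, and rows touching a missing value are
#' dropped rather than interpolated.
#'
#' @param panel A `std_panel` from [standardize_merge()].
#' @param effect Variable whose lags form the embedding.
#' @param target Variable predicted at `t + tp` (defaults to `effect`).
#' @param E Embedding dimension (number of lags of `effect`).
#' @param tau Lag unit in time steps.
#' @param tp Prediction step (negative values look back: a causal lag test).
#' @param conditionals Variables appended as contemporaneous coordinates.
#' @return An object of class `state_space`: `points` (matrix), `targets`,
#'   `time` (row index into the merged panel), `site`, `segments`.
#' @export
time_delay_embed <- function(panel, effect, target = effect, E, tau = 1,
                             tp = 0, conditionals = character()) {
  stopifnot(inherits(panel, "std_panel"), E >= 1, tau >= 1)
  coords <- data.frame(var = c(rep(effect, E), conditionals),
                       lag = c((seq_len(E) - 1L) * tau,
                               rep(0L, length(conditionals))),
                       stringsAsFactors = FALSE)
  out <- .embed_frame(panel, coords, target, tp)
  if (nrow(out$points) == 0) {
    stop("no valid embedding rows: series shorter than (E-1)*tau + |tp| = ",
         (E - 1) * tau + abs(tp), " in every segment, or too many missing values")
  }
  structure(out, class = "state_space")
}

# Leave-one-out simplex predictions over a library.
# Exponential weights w = exp(-d / d1); zero-distance ties get weight 1 and
# the rest decay on an epsilon floor; remaining ties broken by earlier time.
.knn_loo <- function(points, targets, k, time_idx = seq_len(nrow(points)),
                     exclusion_radius = 0, weights = "exponential") {
  n <- nrow(points)
  if (n < 2) stop("library too small for leave-one-out prediction")
  k <- max(1L, min(k, n - 1L))
  D <- as.matrix(stats::dist(points))
  eps_floor <- 1e-12 * mean(D[upper.tri(D)])
  if (!is.finite(eps_floor) || eps_floor == 0) eps_floor <- 1e-300
  pred <- numeric(n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    excl <- abs(time_idx - time_idx[i]) <= exclusion_radius
    excl[i] <- TRUE
    d[excl] <- Inf
    ord <- order(d, time_idx)[seq_len(k)]
    dn <- d[ord]
    if (!is.finite(dn[1])) stop("empty neighbour library after exclusion")
    w <- if (weights == "uniform") rep(1, k) else if (dn[1] > 0)
      exp(-dn / dn[1]) else ifelse(dn == 0, 1, exp(-dn / eps_floor))
    pred[i] <- sum(w * targets[ord]) / sum(w)
  }
  pred
}

#' Nearest-neighbour (simplex) regression in a reconstructed state space
#'
#' Predicts the target as the exponentially weighted mean of the k nearest
#' neighbours' targets, with \eqn{w_i = \exp(-d_i / d_1)} (\eqn{d_1} the
#' nearest distance). With `query = NULL` the prediction is leave-one-out
#' over the library itself, each point excluded from its own neighbourhood
#' (plus any temporal neighbours within `exclusion_radius`).
#'
#' @param space A `state_space` from [time_delay_embed()].
#' @param query Optional matrix of query points (columns as in
#'   `space$points`); `NULL` for leave-one-out prediction of the library.
#' @param k Number of neighbours (default: embedding dimension + 1).
#' @param exclusion_radius Theiler window: library points within this many
#'   time steps of a library query are excluded (0 = self only).
#' @param weights "exponential" (simplex convention) or "uniform" (plain
#'   k-nearest-neighbour average).
#' @return For `query = NULL`, a numeric vector of leave-one-out
#'   predictions; otherwise a list with `predictions`, `neighbors`, and
#'   `weights` per query row.
#' @export
knn_regress <- function(space, query = NULL, k = ncol(space$points) + 1L,
                        exclusion_radius = 0,
                        weights = c("exponential", "uniform")) {
  stopifnot(inherits(space, "state_space"))
  weights <- match.arg(weights)
  pts <- space$points
  tgt <- space$targets
  if (is.null(query)) {
    return(.knn_loo(pts, tgt, k, space$time, exclusion_radius, weights))
  }
  query <- matrix(query, ncol = ncol(pts))
  k <- max(1L, min(k, nrow(pts)))
  preds <- numeric(nrow(query))
  nbs <- ws <- vector("list", nrow(query))
  eps_ref <- mean(stats::dist(pts))
  eps_floor <- max(1e-12 * eps_ref, 1e-300)
  for (q in seq_len(nrow(query))) {
    d <- sqrt(colSums((t(pts) - query[q, ])^2))
    ord <- order(d, space$time)[seq_len(k)]
    dn <- d[ord]
    w <- if (weights == "uniform") rep(1, k) else if (dn[1] > 0)
      exp(-dn / dn[1]) else ifelse(dn == 0, 1, exp(-dn / eps_floor))
    preds[q] <- sum(w * tgt[ord]) / sum(w)
    nbs[[q]] <- ord
    ws[[q]] <- w
  }
  list(predictions = preds, neighbors = nbs, weights = ws)
}

# Column-standardize points/target before neighbour search so that results
# are exactly invariant to affine rescaling of the input series.
.scale_cols <- function(m) {
  for (j in seq_len(ncol(m))) {
    s <- stats::sd(m[, j])
    m[, j] <- if (is.finite(s) && s > 0) (m[, j] - mean(m[, j])) / s else 0
  }
  m
}

# Paired leave-one-out residuals of two models evaluated on the same rows
# of a shared coordinate matrix. full_cols / reduced_cols index columns of
# `points`; an empty reduced set means the leave-one-out mean predictor.
# Each model uses uniform weights over its own simplex neighbourhood
# (k = dimension + 1); the finite-k smoothing inflates an uninformative
# model's residual variance by exactly (1 + 1/k), so the returned
# `correction` term removes that known inflation from the variance ratio.
# Distance weighting is not used here: its effective neighbour count varies
# with dimension, which biases the comparison in a way that has no closed
# form.
.paired_residuals <- function(points, targets, full_cols, reduced_cols,
                              time_idx, exclusion_radius = 0) {
  points <- .scale_cols(points)
  s <- stats::sd(targets)
  targets <- if (is.finite(s) && s > 0) (targets - mean(targets)) / s else targets
  n <- nrow(points)
  k_full <- min(length(full_cols) + 1L, n - 1L)
  pred_full <- .knn_loo(points[, full_cols, drop = FALSE], targets, k_full,
                        time_idx, exclusion_radius, weights = "uniform")
  if (length(reduced_cols) == 0) {
    k_red <- n - 1L
    pred_red <- (sum(targets) - targets) / (n - 1)
  } else {
    k_red <- min(length(reduced_cols) + 1L, n - 1L)
    red <- points[, reduced_cols, drop = FALSE]
    pred_red <- .knn_loo(red, targets, k_red, time_idx, exclusion_radius,
                         weights = "uniform")
  }
  list(e_full = targets - pred_full, e_red = targets - pred_red,
       correction = 0.5 * log((1 + 1 / k_full) / (1 + 1 / k_red)))
}

# Transfer entropy from paired residuals under the Gaussian reduction:
# te = (1/T) sum log[ sigma_red phi(e_full/sigma_full) /
#                     (sigma_full phi(e_red/sigma_red)) ]
#    = 0.5 log(sigma2_red / sigma2_full)  (the quadratic terms cancel),
# plus the finite-k variance correction of .paired_residuals.
.te_from_residuals <- function(e_full, e_red, correction = 0) {
  0.5 * log(mean(e_red^2) / mean(e_full^2)) + correction
}

# Bootstrap the embedded residual pairs with replacement; one-sided p for
# H1: TE > 0 as the fraction of resampled te at or below zero.
.te_bootstrap <- function(e_full, e_red, n_boot, correction = 0) {
  n <- length(e_full)
  te_b <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    te_b[b] <- .te_from_residuals(e_full[idx], e_red[idx], correction)
  }
  te_b
}

#' Select the optimal embedding dimension by predictive information gain
#'
#' Scans E = 1..`E_max`, at each step measuring the transfer entropy of the
#' E-dimensional model over the best accepted lower-dimensional model using
#' one-step-forward (tp = 1) leave-one-out simplex forecasts of the effect
#' variable, with the optional cause and conditioning coordinates present in
#' both models. The scan keeps growing E while the information gain is
#' statistically clear (bootstrap of the embedded residual pairs, one-sided
#' at `alpha`) and returns the smallest E beyond which the gain ceases to be
#' clear.
#'
#' @param panel A `std_panel`.
#' @param effect Variable being embedded (its own forecast defines the
#'   criterion).
#' @param cause Optional causal variable included as a contemporaneous
#'   coordinate in every model.
#' @param conditionals Conditioning variables included in every model.
#' @param E_max Largest dimension scanned.
#' @param tau Lag unit.
#' @param alpha Clarity threshold for the bootstrap test.
#' @param n_boot Bootstrap resamples per step.
#' @return List: `E` (selected dimension), `scan` (data.frame of E, te, p).
#' @export
select_embedding_dimension <- function(panel, effect, cause = NULL,
                                       conditionals = character(),
                                       E_max = 8, tau = 1, alpha = 0.05,
                                       n_boot = 200) {
  stopifnot(E_max >= 1)
  extra <- c(cause, conditionals)
  build <- function(E) {
    coords <- data.frame(var = c(extra, rep(effect, E)),
                         lag = c(rep(0L, length(extra)),
                                 (seq_len(E) - 1L) * tau),
                         stringsAsFactors = FALSE)
    .embed_frame(panel, coords, effect, tp = 1)
  }
  E_opt <- 1L
  scan <- data.frame(E = integer(), te = numeric(), p = numeric())
  if (E_max == 1L) return(list(E = 1L, scan = scan))
  for (E in 2:E_max) {
    emb <- build(E)
    if (nrow(emb$points) < 15) break
    reduced_cols <- c(seq_along(extra), length(extra) + seq_len(E_opt))
    res <- .paired_residuals(emb$points, emb$targets,
                             seq_len(ncol(emb$points)), reduced_cols,
                             emb$time)
    te <- .te_from_residuals(res$e_full, res$e_red, res$correction)
    p <- mean(.te_bootstrap(res$e_full, res$e_red, n_boot,
                            res$correction) <= 0)
    scan <- rbind(scan, data.frame(E = E, te = te, p = p))
    if (te > 0 && p < alpha) E_opt <- E else break
  }
  list(E = E_opt, scan = scan)
}
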