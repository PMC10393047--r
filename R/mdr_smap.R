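# Multiview distance regularized S-map: locally weighted ridge regression
# in a causally informed state space, with neighbourhoods defined by an
# ensemble of low-dimensional embeddings. The local regression coefficients
# are read as time-varying interaction strengths.

#' Multiview distance over an ensemble of low-dimensional embeddings
#'
#' Euclidean distance degrades as a neighbourhood criterion when the state
#' space is high-dimensional. The multiview distance instead averages
#' distances measured in many low-dimensional views (coordinate subsets),
#' keeping only the views that forecast the target well: views of
#' `view_dim` coordinates (each containing at least one lag of the target
#' variable) are ranked by leave-one-out one-step simplex forecast
#' correlation, the top `ceiling(sqrt(n_views))` are retained, each view's
#' distance matrix is normalized by its own mean, and the normalized
#' distances are averaged.
#'
#' @param points Candidate coordinate matrix (rows = reconstructed states).
#' @param targets Forecast target (the target variable one step ahead).
#' @param target_cols Columns of `points` that are lags of the target
#'   variable (every view must contain one).
#' @param view_dim Coordinates per view (default
#'   `ceiling(sqrt(ncol(points)))`).
#' @param n_views_max Evaluate at most this many views (sampled without
#'   replacement when the enumeration is larger).
#' @param time_idx Time indices for neighbour exclusion in the skill
#'   computation.
#' @param seed RNG seed for view sampling.
#' @return List of class `multiview_dist`: `dist` (n x n matrix), `views`
#'   (kept coordinate subsets), `skill` (their forecast correlations).
#' @export
multiview_distance <- function(points, targets, target_cols = 1L,
                               view_dim = NULL, n_views_max = 2000,
                               time_idx = seq_len(nrow(points)), seed = 1) {
  p <- ncol(points)
  stopifnot(p >= 1, length(targets) == nrow(points))
  if (is.character(target_cols)) target_cols <- match(target_cols, colnames(points))
  if (is.null(view_dim)) view_dim <- ceiling(sqrt(p))
  view_dim <- min(view_dim, p)
  all_views <- utils::combn(p, view_dim, simplify = FALSE)
  all_views <- Filter(function(v) any(target_cols %in% v), all_views)
  if (!length(all_views)) stop("no view contains a target lag")
  if (length(all_views) > n_views_max) {
    set.seed(as.integer(seed) %% 2147483647L)
    all_views <- all_views[sample.int(length(all_views), n_views_max)]
  }
  skill <- vapply(all_views, function(v) {
    pred <- .knn_loo(points[, v, drop = FALSE], targets, length(v) + 1L,
                     time_idx)
    suppressWarnings(stats::cor(pred, targets))
  }, numeric(1))
  ok <- is.finite(skill)
  if (!any(ok)) stop("no view achieves finite forecast skill")
  all_views <- all_views[ok]
  skill <- skill[ok]
  n_keep <- min(length(all_views), ceiling(sqrt(length(all_views))))
  keep <- order(-skill)[seq_len(n_keep)]
  n <- nrow(points)
  acc <- matrix(0, n, n)
  for (v in all_views[keep]) {
    dm <- as.matrix(stats::dist(points[, v, drop = FALSE]))
    mu <- mean(dm[upper.tri(dm)])
    if (!is.finite(mu) || mu == 0) mu <- 1
    acc <- acc + dm / mu
  }
  structure(list(dist = acc / n_keep, views = all_views[keep],
                 skill = skill[keep]), class = "multiview_dist")
}

# Weighted ridge solve with unpenalized intercept; returns coefficient
# vector c(intercept, slopes) or NULL if the system is singular.
.ridge_solve <- function(X, y, w, lambda) {
  X1 <- cbind(1, X)
  XtW <- t(X1 * w)
  M <- XtW %*% X1
  diag(M) <- diag(M) + c(0, rep(lambda, ncol(X)))
  b <- XtW %*% y
  out <- tryCatch(solve(M, b), error = function(e) NULL)
  if (!is.null(out) && any(!is.finite(out))) out <- NULL
  out
}

#' Locally weighted ridge S-map with multiview neighbourhoods
#'
#' For each target time point \eqn{t^*} fits the local linear model
#' \deqn{\hat x_{1,t^*+tp} = IS_0 + \sum_j IS_j \, x_{j,t^*}}
#' by ridge regression over all other reconstructed states, weighted by
#' \eqn{w_i = \exp(-\theta \, d_i / \bar d(t^*))} with \eqn{d} the multiview
#' distance and \eqn{\bar d(t^*)} its mean over the library. The
#' coefficients \eqn{IS_j} are the time-varying interaction strengths; the
#' intercept is never penalized. The ridge penalty \eqn{\lambda} (and
#' optionally \eqn{\theta}) is chosen once per target by leave-one-out
#' forecast error: every point's prediction already excludes that point
#' from its own fit.
#'
#' @param points Coordinate matrix (columns: target lags, causes,
#'   conditioners).
#' @param targets Target variable at `t + tp`.
#' @param distances A `multiview_dist`, a distance matrix, or `NULL` for
#'   plain Euclidean distance on `points`.
#' @param theta Local weighting bandwidth, or a grid to search.
#' @param lambda_grid Ridge penalties searched.
#' @param time_idx,site Bookkeeping vectors carried into the result.
#' @return Object of class `mdr_smap_fit`: `coefficients` (one row per
#'   time point; first column the intercept), `predictions`, `skill`
#'   (out-of-sample forecast correlation), chosen `lambda` and `theta`,
#'   `time_idx`, `site`, and `skipped` (points with singular local fits).
#' @export
mdr_smap_fit <- function(points, targets, distances = NULL, theta = 1,
                         lambda_grid = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
                         time_idx = seq_len(nrow(points)), site = NULL) {
  n <- nrow(points)
  p <- ncol(points)
  stopifnot(n > p + 2, length(targets) == n)
  D <- if (is.null(distances)) {
    as.matrix(stats::dist(points))
  } else if (inherits(distances, "multiview_dist")) {
    distances$dist
  } else as.matrix(distances)
  stopifnot(nrow(D) == n, ncol(D) == n)

  fit_all <- function(theta1, lambda1) {
    coefs <- matrix(NA_real_, n, p + 1L)
    preds <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      d <- D[i, -i]
      dbar <- mean(d)
      if (!is.finite(dbar) || dbar == 0) dbar <- 1
      w <- exp(-theta1 * d / dbar)
      beta <- .ridge_solve(points[-i, , drop = FALSE], targets[-i], w, lambda1)
      if (is.null(beta)) next
      coefs[i, ] <- beta
      preds[i] <- sum(c(1, points[i, ]) * beta)
    }
    list(coefs = coefs, preds = preds,
         mse = mean((preds - targets)^2, na.rm = TRUE))
  }

  grid <- expand.grid(theta = theta, lambda = lambda_grid)
  best <- NULL; best_mse <- Inf
  for (g in seq_len(nrow(grid))) {
    f <- fit_all(grid$theta[g], grid$lambda[g])
    if (is.finite(f$mse) && f$mse < best_mse) {
      best_mse <- f$mse
      best <- list(fit = f, theta = grid$theta[g], lambda = grid$lambda[g])
    }
  }
  if (is.null(best)) stop("singular weighted design at every (theta, lambda)")
  coefs <- best$fit$coefs
  colnames(coefs) <- c("(intercept)",
                       colnames(points) %||% paste0("x", seq_len(p)))
  skipped <- which(is.na(coefs[, 1]))
  if (length(skipped)) {
    warning("singular local fit at ", length(skipped),
            " time point(s); skipped")
  }
  ok <- !is.na(best$fit$preds)
  structure(list(coefficients = coefs, predictions = best$fit$preds,
                 skill = suppressWarnings(
                   stats::cor(best$fit$preds[ok], targets[ok])),
                 lambda = best$lambda, theta = best$theta,
                 time_idx = time_idx, site = site, skipped = skipped),
            class = "mdr_smap_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time-varying interaction strengths for detected interactions
#'
#' For each target species, builds the causally informed state space — the
#' target's own optimal-E lags, each statistically clear cause at its
#' retained lag, and the clear environmental conditioners — computes
#' multiview distances, and fits the locally weighted ridge S-map
#' predicting the target one step ahead. Each local regression coefficient
#' is one interaction-strength record, mapped back to its site and time.
#'
#' A cause retained at lag `tp` enters as the coordinate
#' `cause[t - max(0, -tp - 1)]`, so that e.g. a `tp = -1` influence (cause
#' at t-1 affecting the effect at t) appears as the cause's current value
#' in the one-step-ahead forecast.
#'
#' @param panel A `std_panel`.
#' @param interactions An `interaction_set` from [all_pairs()], or a
#'   data.frame with columns cause, effect, tp (all rows treated as clear).
#' @param conditionals Conditioning variables appended to every target's
#'   coordinate set when `interactions` is a plain data.frame (an
#'   `interaction_set` carries its own per-effect conditioners).
#' @param targets Species to fit (default: every species in the panel).
#' @param E Fixed embedding dimension for the targets' own lags, or `NULL`
#'   to select per target.
#' @param theta,lambda_grid,n_views_max Passed to the S-map machinery.
#' @param distance "multiview" (ensemble distance, the default) or
#'   "euclidean" (plain distance on the full coordinate set).
#' @param seed RNG seed (view sampling).
#' @return data.frame of class `is_records`: target, coef (variable name,
#'   `"(intercept)"` for the intercept), lag, site, time_index, value,
#'   skill; one row per coefficient per time point.
#' @export
interaction_strengths <- function(panel, interactions,
                                  conditionals = character(),
                                  targets = panel$species, E = NULL,
                                  theta = c(0.5, 1, 2, 4, 8),
                                  lambda_grid = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
                                  n_views_max = 2000,
                                  distance = c("multiview", "euclidean"),
                                  seed = 1) {
  stopifnot(inherits(panel, "std_panel"))
  distance <- match.arg(distance)
  if (inherits(interactions, "interaction_set")) {
    edges <- clear_edges(interactions)
    cond_list <- interactions$conditionals
  } else {
    edges <- interactions
    if (is.null(edges$clear)) edges$clear <- rep(TRUE, nrow(edges))
    edges <- edges[edges$clear, , drop = FALSE]
    cond_list <- stats::setNames(
      rep(list(as.character(conditionals)), length(targets)), targets)
  }
  out <- NULL
  for (tg in targets) {
    conds <- cond_list[[tg]] %||% character()
    E_tg <- if (is.null(E)) {
      select_embedding_dimension(panel, tg, conditionals = conds)$E
    } else E
    my_edges <- edges[edges$effect == tg & edges$cause %in% panel$species, ,
                      drop = FALSE]
    coords <- data.frame(var = tg, lag = seq_len(E_tg) - 1L,
                         stringsAsFactors = FALSE)
    if (nrow(my_edges)) {
      coords <- rbind(coords, data.frame(
        var = my_edges$cause, lag = pmax(0L, -my_edges$tp - 1L)))
    }
    if (length(conds)) {
      coords <- rbind(coords, data.frame(var = conds, lag = 0L))
    }
    coords <- coords[!duplicated(coords), , drop = FALSE]
    emb <- .embed_frame(panel, coords, tg, tp = 1)
    if (nrow(emb$points) < ncol(emb$points) + 5) {
      warning("too few state-space points for target ", tg, "; skipped")
      next
    }
    target_cols <- which(coords$var == tg)
    mv <- if (distance == "multiview" && ncol(emb$points) > 1) {
      multiview_distance(emb$points, emb$targets, target_cols = target_cols,
                         n_views_max = n_views_max, time_idx = emb$time,
                         seed = seed)
    } else NULL
    fit <- mdr_smap_fit(emb$points, emb$targets, distances = mv,
                        theta = theta, lambda_grid = lambda_grid,
                        time_idx = emb$time, site = emb$site)
    cf <- fit$coefficients
    for (j in seq_len(ncol(cf))) {
      var_j <- if (j == 1L) "(intercept)" else coords$var[j - 1L]
      lag_j <- if (j == 1L) NA_integer_ else coords$lag[j - 1L]
      keep <- !is.na(cf[, j])
      if (!any(keep)) next
      out <- rbind(out, data.frame(
        target = tg, coef = var_j, lag = lag_j,
        site = emb$site[keep],
        time_index = panel$time_index[emb$time[keep]],
        value = cf[keep, j], skill = fit$skill,
        E = E_tg, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("is_records", class(out))
  out
}
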