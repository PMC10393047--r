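# Conditional transfer entropy between standardized eDNA series, estimated
# by nearest-neighbour cross mapping on time-delay embeddings of the effect
# variable, with environmental conditioning and bootstrap clarity tests.

#' Conditional transfer entropy from one series to another
#'
#' Estimates the information flow from a candidate cause `y` to an effect
#' `x` as
#' \deqn{TE = \frac{1}{T} \sum_t \log \frac{p(y_{t+tp} \mid x_t, x_{t-\tau},
#'   \dots, x_{t-(E-1)\tau}, z_t)}{p(y_{t+tp} \mid x_{t-\tau}, \dots,
#'   x_{t-(E-1)\tau}, z_t)}.}
#' Each conditional density is approximated as a Gaussian centred on the
#' leave-one-out nearest-neighbour cross-map prediction of \eqn{y_{t+tp}}
#' from the stated coordinates, with that model's leave-one-out residual
#' variance; the average log ratio then reduces to
#' \eqn{\frac{1}{2}\log(\hat\sigma^2_{reduced} / \hat\sigma^2_{full})}.
#' Positive TE means the effect variable's current state carries predictive
#' information about the cause beyond the effect's own past and the
#' conditioners — the cross-mapping signature of a causal influence.
#'
#' The reduced model is the effect's embedding shifted one lag unit back,
#' \eqn{\{x_{t-\tau}, \dots, x_{t-E\tau}, z_t\}}: the same dimension as
#' the full model, so that under the no-causality null the two models are
#' statistically exchangeable and the estimator is centred at zero, while a
#' genuine influence of y on x leaves extra information in the effect's
#' most recent coordinate only.
#'
#' Conditioning variables enter both models with `cond_lags` delay
#' coordinates (default: as many as the effect, `E`). A dynamic shared
#' driver influences the effect through its recent history, not only its
#' current value, so conditioning on a single contemporaneous coordinate
#' would leave most of a seasonal driver's signal in place.
#'
#' @param panel A `std_panel`.
#' @param effect Effect variable `x` (its lags form the embedding).
#' @param cause Candidate cause `y` (the cross-mapped target).
#' @param conditionals Conditioning variables `z` present in both models.
#' @param E Embedding dimension (selected via
#'   [select_embedding_dimension()] upstream).
#' @param tau Lag unit.
#' @param tp Prediction step; negative tp tests a lagged causal influence.
#' @param cond_lags Delay coordinates per conditioning variable.
#' @param exclusion_radius Theiler window for neighbour search.
#' @param min_T Refuse to estimate below this many state-space points.
#' @param detail Return residuals for bootstrapping.
#' @return TE in nats per point, or (with `detail = TRUE`) a list with `te`,
#'   the paired residuals, and `T`.
#' @export
conditional_te <- function(panel, effect, cause, conditionals = character(),
                           E = 2, tau = 1, tp = 0, cond_lags = E,
                           exclusion_radius = 0, min_T = 20, detail = FALSE) {
  stopifnot(inherits(panel, "std_panel"), E >= 1, cond_lags >= 1)
  # lags 0..E of the effect: the full model uses 0..(E-1)*tau, the reduced
  # model the same window shifted back by tau; conditioners at lags
  # 0..(cond_lags-1)*tau in both models
  z_coords <- if (length(conditionals)) {
    data.frame(var = rep(conditionals, each = cond_lags),
               lag = rep((seq_len(cond_lags) - 1L) * tau,
                         length(conditionals)),
               stringsAsFactors = FALSE)
  } else data.frame(var = character(), lag = integer())
  coords <- rbind(data.frame(var = rep(effect, E + 1L),
                             lag = (seq_len(E + 1L) - 1L) * tau,
                             stringsAsFactors = FALSE),
                  z_coords)
  emb <- .embed_frame(panel, coords, cause, tp)
  T_pts <- nrow(emb$points)
  if (T_pts < min_T) {
    stop("only ", T_pts, " state-space points (< min_T = ", min_T,
         ") for ", cause, " -> ", effect, " at tp = ", tp)
  }
  zc <- if (nrow(z_coords)) E + 1L + seq_len(nrow(z_coords)) else integer()
  full_cols <- c(seq_len(E), zc)
  reduced_cols <- c(seq_len(E) + 1L, zc)
  res <- .paired_residuals(emb$points, emb$targets, full_cols, reduced_cols,
                           emb$time, exclusion_radius)
  te <- .te_from_residuals(res$e_full, res$e_red, res$correction)
  if (!detail) return(te)
  list(te = te, e_full = res$e_full, e_red = res$e_red,
       correction = res$correction, T = T_pts)
}

#' Test a directed interaction over a range of causal lags
#'
#' Computes conditional transfer entropy from `cause` to `effect` at every
#' prediction step in `tp_range` (by convention 0 down to -6: up to a
#' three-month lag at half-monthly sampling), with a one-sided bootstrap
#' test of TE > 0 at each lag (resampling the embedded residual pairs with
#' replacement). The retained lag is the one with the largest TE among the
#' statistically clear lags, or the overall largest-TE lag (with its
#' non-clear p) if none pass.
#'
#' @param panel A `std_panel`.
#' @param effect,cause,conditionals See [conditional_te()].
#' @param tp_range Integer prediction steps to scan.
#' @param cond_lags Delay coordinates per conditioning variable (default:
#'   match `E`).
#' @param E Embedding dimension of the cross-map model; `NULL` selects the
#'   effect's own optimal dimension via [select_embedding_dimension()] and
#'   adds one coordinate, since the cross-map state space must accommodate
#'   the causal variable's dynamics in addition to the effect's own.
#' @param tau Lag unit.
#' @param n_boot Bootstrap resamples (>= 100).
#' @param alpha Clarity threshold.
#' @param min_T Minimum state-space points.
#' @return One-row data.frame: cause, effect, conditionals, tp, E, te,
#'   p_value, T, n_boot, clear; the full per-lag scan is attached as
#'   attribute `"scan"`.
#' @export
uic_test <- function(panel, effect, cause, conditionals = character(),
                     tp_range = 0:-6, E = NULL, tau = 1, cond_lags = NULL,
                     n_boot = 1000, alpha = 0.05, min_T = 20) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (identical(effect, cause)) stop("self-pairs are not tested")
  if (is.null(E)) {
    # The effect's own optimal E (conditioners included, cause excluded:
    # including the cause collapses E to 1 on deterministic systems), plus
    # one coordinate so the cross-map embedding can accommodate the causal
    # variable's dimension on top of the effect's own dynamics.
    E <- select_embedding_dimension(panel, effect,
                                    conditionals = conditionals,
                                    tau = tau, alpha = alpha)$E + 1L
  }
  if (is.null(cond_lags)) cond_lags <- E
  scan <- data.frame(tp = tp_range, te = NA_real_, p_value = NA_real_,
                     T = NA_integer_)
  for (i in seq_along(tp_range)) {
    d <- conditional_te(panel, effect, cause, conditionals, E = E, tau = tau,
                        tp = tp_range[i], cond_lags = cond_lags,
                        min_T = min_T, detail = TRUE)
    scan$te[i] <- d$te
    scan$T[i] <- d$T
    scan$p_value[i] <- mean(.te_bootstrap(d$e_full, d$e_red, n_boot,
                                          d$correction) <= 0)
  }
  clear <- scan$p_value < alpha & scan$te > 0
  pick <- if (any(clear)) which(clear)[which.max(scan$te[clear])] else
    which.max(scan$te)
  out <- data.frame(cause = cause, effect = effect,
                    conditionals = paste(conditionals, collapse = ";"),
                    tp = scan$tp[pick], E = E, te = scan$te[pick],
                    p_value = scan$p_value[pick], T = scan$T[pick],
                    n_boot = n_boot, clear = clear[pick],
                    stringsAsFactors = FALSE)
  attr(out, "scan") <- scan
  out
}

#' Select environmental conditioning variables for one effect species
#'
#' Tests each environmental variable, in the fixed order given, as a cause
#' of the effect series (no conditioning) and returns those with a
#' statistically clear influence; these enter the interaction tests as
#' \eqn{z_t}, removing shared environmental forcing (notably seasonal
#' temperature) from the evidence for species-species interactions.
#' Zero-variance covariates are skipped (a constant series carries no
#' information).
#'
#' @param panel A `std_panel`.
#' @param effect Effect species.
#' @param env_vars Candidate covariates, tested in this order.
#' @param alpha Clarity threshold.
#' @param tp_range Lags scanned per covariate (default -1: the covariate's
#'   value one step back influencing the species now).
#' @param n_boot Bootstrap resamples.
#' @return Character vector of selected covariates (possibly empty), with
#'   the per-covariate test table as attribute `"tests"`.
#' @export
select_conditionals <- function(panel, effect, env_vars = panel$env,
                                alpha = 0.05, tp_range = -1L, n_boot = 200) {
  env_vars <- intersect(env_vars, colnames(panel$values))
  tests <- NULL
  selected <- character()
  for (v in env_vars) {
    if (!is.finite(stats::sd(panel$values[, v])) ||
        stats::sd(panel$values[, v]) == 0) next
    res <- uic_test(panel, effect = effect, cause = v,
                    tp_range = tp_range, n_boot = max(n_boot, 100),
                    alpha = alpha)
    tests <- rbind(tests, res)
    if (res$clear) selected <- c(selected, v)
  }
  attr(selected, "tests") <- tests
  selected
}

#' Test all ordered species pairs for directed interactions
#'
#' For each effect species the environmental conditioners are selected once;
#' then every ordered (cause, effect) pair is tested with [uic_test()]. A
#' statistically clear positive TE is read as a sign of an interspecific
#' interaction.
#'
#' @param panel A `std_panel`.
#' @param species Species to test (default: all in the panel).
#' @param env_vars Candidate conditioning covariates.
#' @param alpha Clarity threshold.
#' @param tp_range Causal lags scanned.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed (bootstraps are deterministic given the seed).
#' @param progress Print one line per effect species.
#' @return An object of class `interaction_set`: `results` (one row per
#'   ordered pair, the retained lag), `conditionals` (named list per effect
#'   species), `alpha`.
#' @export
all_pairs <- function(panel, species = panel$species, env_vars = panel$env,
                      alpha = 0.05, tp_range = 0:-6, n_boot = 1000,
                      seed = 1, progress = FALSE) {
  stopifnot(length(species) >= 2)
  set.seed(as.integer(seed) %% 2147483647L)
  conds <- stats::setNames(vector("list", length(species)), species)
  results <- NULL
  for (eff in species) {
    conds[[eff]] <- as.character(select_conditionals(
      panel, eff, env_vars = env_vars, alpha = alpha, n_boot = n_boot))
    if (progress) {
      message("effect ", eff, ": conditioning on [",
              paste(conds[[eff]], collapse = ", "), "]")
    }
    for (cs in setdiff(species, eff)) {
      res <- uic_test(panel, effect = eff, cause = cs,
                      conditionals = conds[[eff]], tp_range = tp_range,
                      n_boot = n_boot, alpha = alpha)
      results <- rbind(results, res)
    }
  }
  rownames(results) <- NULL
  structure(list(results = results, conditionals = conds, alpha = alpha),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("Interaction set:", nrow(x$results), "ordered pairs tested,",
      sum(x$results$clear), "statistically clear at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Statistically clear directed edges of an interaction set
#'
#' @param x An `interaction_set`.
#' @return data.frame of the clear edges (cause, effect, tp, E, te, p_value).
#' @export
clear_edges <- function(x) {
  stopifnot(inherits(x, "interaction_set"))
  x$results[x$results$clear, , drop = FALSE]
}
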