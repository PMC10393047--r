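# Network assembly and temperature-sensitivity modelling: in-/out-strength
# tables from the S-map coefficients, gamma-family additive mixed models of
# |interaction strength| against temperature and other covariates, and
# per-species temperature-effect classification.

#' Build the directed interaction network from clear edges
#'
#' Returns every statistically clear edge with a `retained` flag marking
#' those at or above the `q`-quantile of clear-edge TE values — the strong
#' interactions kept when the network is visualized.
#'
#' @param interactions An `interaction_set` or a clear-edge data.frame with
#'   a `te` column.
#' @param q Retention quantile (default 0.8).
#' @return data.frame of edges with a logical `retained` column.
#' @export
build_network <- function(interactions, q = 0.8) {
  edges <- if (inherits(interactions, "interaction_set")) {
    clear_edges(interactions)
  } else interactions
  if (!nrow(edges)) stop("no clear edges to build a network from")
  thr <- stats::quantile(edges$te, q, names = FALSE)
  edges$retained <- edges$te >= thr
  rownames(edges) <- NULL
  edges
}

#' Long table of interaction-strength observations
#'
#' Turns cross-species S-map coefficients into one observation per (edge,
#' time point) and direction: each record yields an in-strength row for the
#' target species (the interaction it receives) and an out-strength row for
#' the cause species (the interaction it gives), joined with that sample's
#' water temperature, species richness, and total eDNA concentration.
#' Intercepts and the target's own lags are excluded.
#'
#' @param records `is_records` from [interaction_strengths()].
#' @param panel Long sample data.frame with a `copies` column (for richness
#'   and total copies) and per-sample covariates (temperature, and any of
#'   salinity, wave, tide present).
#' @return data.frame: species, direction ("in"/"out"), partner, site,
#'   time_index, temperature, richness, total_copies, further covariates,
#'   strength (= |IS|), is_value (signed).
#' @export
strength_table <- function(records, panel) {
  cross <- records[records$coef != "(intercept)" &
                     records$coef != records$target, , drop = FALSE]
  env_extra <- intersect(c("salinity", "wave", "tide"), names(panel))
  samp <- unique(panel[, c("site", "time_index", "temperature", env_extra)])
  summ <- sample_summaries(panel)
  samp <- merge(samp, summ, by = c("site", "time_index"))
  base <- data.frame(site = cross$site, time_index = cross$time_index,
                     is_value = cross$value, strength = abs(cross$value))
  rows_in <- cbind(species = cross$target, direction = "in",
                   partner = cross$coef, base)
  rows_out <- cbind(species = cross$coef, direction = "out",
                    partner = cross$target, base)
  out <- rbind(rows_in, rows_out)
  out <- merge(out, samp, by = c("site", "time_index"), sort = FALSE)
  out[order(out$direction, out$species, out$partner, out$site,
            out$time_index), ]
}

# Floor zero strengths at half the smallest positive value (gamma support
# is strictly positive); returns the data and the number floored.
.floor_strengths <- function(strength) {
  pos <- strength[strength > 0]
  if (!length(pos)) stop("all strengths are zero; nothing to model")
  eps <- min(pos) / 2
  n0 <- sum(strength <= 0)
  strength[strength <= 0] <- eps
  list(strength = strength, n_floored = n0)
}

# Shared GAMM fitting core: gamma family, log link, smooth on the
# predictor, random intercepts for the requested groupings. Random
# intercepts are fitted as "re" smooths inside a single REML gam — the
# fully penalized-likelihood equivalent of the mixed model, and far more
# stable for non-Gaussian families than the PQL route. Groupings with a
# single level are dropped.
.fit_gamma_smooth <- function(data, predictor, random_terms) {
  n_unique <- length(unique(data[[predictor]]))
  if (n_unique < 3) {
    stop("predictor '", predictor, "' has ", n_unique,
         " unique value(s); cannot fit a smooth")
  }
  k <- max(3L, min(10L, n_unique - 1L))
  terms <- paste0("s(", predictor, ", k = ", k, ")")
  used <- character()
  for (g in random_terms) {
    if (g %in% names(data) && length(unique(data[[g]])) >= 2) {
      data[[g]] <- factor(data[[g]])
      terms <- c(terms, paste0("s(", g, ", bs = \"re\")"))
      used <- c(used, g)
    }
  }
  fml <- stats::as.formula(paste("strength ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(fml, family = stats::Gamma(link = "log"), data = data,
                   method = "REML")
  list(fit = fit, gam = fit, k = k, random_used = used,
       exclude = if (length(used)) paste0("s(", used, ")") else NULL,
       ref = lapply(stats::setNames(used, used),
                    function(g) factor(levels(data[[g]])[1],
                                       levels = levels(data[[g]]))))
}

# Prediction grid for the population-level smooth: random-intercept terms
# are excluded, with placeholder factor levels supplied for newdata.
.smooth_predict <- function(fitted, grid, type = "response") {
  for (g in fitted$random_used) grid[[g]] <- fitted$ref[[g]]
  mgcv::predict.gam(fitted$gam, newdata = grid, type = type,
                    se.fit = (type == "link"),
                    exclude = fitted$exclude, newdata.guaranteed = TRUE)
}

#' Community-level model of interaction strength against a covariate
#'
#' Fits `abs(IS) ~ s(predictor)` with a gamma error distribution and log
#' link, with random intercepts for study site and species — the biological
#' assumption being that the covariate may influence interaction strengths
#' linearly or nonlinearly while sites and species shift the baseline
#' strength at random. Zero strengths are floored at half the smallest
#' positive value (the gamma distribution has positive support); the count
#' of floored values is reported. The smooth's effect is declared
#' statistically clear at `p < alpha`.
#'
#' @param observations Output of [strength_table()].
#' @param predictor Covariate column modelled (e.g. "temperature",
#'   "richness", "total_copies").
#' @param direction "in" or "out" strength.
#' @param alpha Clarity threshold.
#' @param random_terms Random-intercept groupings (dropped automatically
#'   when a grouping has a single level).
#' @return Object of class `strength_fit`: the fitted model, `p_smooth`,
#'   `clear`, `curve` (predictor grid with fitted response and 95% CI),
#'   `endpoint_diff` (fitted response at the 95th minus the 5th predictor
#'   percentile), `n`, `n_floored`.
#' @export
fit_strength_model <- function(observations, predictor = "temperature",
                               direction = c("in", "out"), alpha = 0.05,
                               random_terms = c("site", "species")) {
  direction <- match.arg(direction)
  obs <- observations[observations$direction == direction, , drop = FALSE]
  if (nrow(obs) <= 50) {
    stop("only ", nrow(obs), " observations for direction '", direction,
         "'; need > 50")
  }
  if (!predictor %in% names(obs)) stop("unknown predictor '", predictor, "'")
  fl <- .floor_strengths(obs$strength)
  obs$strength <- fl$strength
  fitted <- .fit_gamma_smooth(obs, predictor, random_terms)
  sm <- summary(fitted$gam)
  p_smooth <- unname(sm$s.table[1, "p-value"])
  xs <- obs[[predictor]]
  grid <- data.frame(seq(min(xs), max(xs), length.out = 100))
  names(grid) <- predictor
  pr <- .smooth_predict(fitted, grid, type = "link")
  curve <- data.frame(grid,
                      fit = exp(pr$fit),
                      lower = exp(pr$fit - 1.96 * pr$se.fit),
                      upper = exp(pr$fit + 1.96 * pr$se.fit))
  qs <- stats::quantile(xs, c(0.05, 0.95), names = FALSE)
  qgrid <- data.frame(qs); names(qgrid) <- predictor
  fq <- .smooth_predict(fitted, qgrid)
  structure(list(model = fitted$fit, gam = fitted$gam,
                 predictor = predictor, direction = direction,
                 p_smooth = p_smooth, clear = is.finite(p_smooth) &&
                   p_smooth < alpha,
                 curve = curve, endpoint_diff = unname(fq[2] - fq[1]),
                 n = nrow(obs), n_floored = fl$n_floored),
            class = "strength_fit")
}

#' @export
print.strength_fit <- function(x, ...) {
  cat("Gamma GAMM of |IS| (", x$direction, "-strength) ~ s(", x$predictor,
      "): n = ", x$n, ", smooth p = ", signif(x$p_smooth, 3),
      if (x$clear) " (clear)" else " (not clear)",
      ", endpoint difference = ", signif(x$endpoint_diff, 3), "\n", sep = "")
  invisible(x)
}

# Classify a smooth by the global trend of its fitted response evaluated at
# the observed predictor values (Spearman correlation with the predictor):
# reading the curve where the data sit is more robust than its behaviour at
# the sparse extremes. Curves whose fitted values barely co-vary with the
# predictor are "non-monotone".
.classify_smooth <- function(trend_rho) {
  if (!is.finite(trend_rho)) return(NA_character_)
  if (abs(trend_rho) < 0.2) return("non-monotone")
  if (trend_rho > 0) "increasing" else "decreasing"
}

#' Per-species temperature (or covariate) effects on interaction strength
#'
#' Fits the gamma-family smooth separately for every species, with random
#' intercepts for site and for the interaction partner — each received (or
#' given) edge has its own baseline strength, which the log-link partner
#' intercept absorbs so the temperature trend is not distorted by pooling
#' edges of different magnitudes. Classifies each clear smooth as increasing,
#' decreasing, or non-monotone from its fitted response at the 5th vs 95th
#' predictor percentile, and flags strongly affected species at
#' `p < alpha_highlight`.
#'
#' @param observations Output of [strength_table()].
#' @param direction "in" or "out".
#' @param predictor Covariate column (default "temperature").
#' @param alpha Clarity threshold for the `clear` column.
#' @param alpha_highlight Stricter threshold for the `highlight` flag
#'   (default 1e-4).
#' @param min_rows Species with fewer observations are skipped with a
#'   notice.
#' @return data.frame: species, n, p_smooth, clear, highlight,
#'   endpoint_diff (fitted response at the 95th minus 5th predictor
#'   percentile), trend_rho (Spearman correlation of the fitted smooth with
#'   the predictor over the observed values), class
#'   ("increasing"/"decreasing"/"non-monotone", by the sign of trend_rho),
#'   error (message for species whose fit failed).
#' @export
species_temperature_effects <- function(observations,
                                        direction = c("in", "out"),
                                        predictor = "temperature",
                                        alpha = 0.05,
                                        alpha_highlight = 1e-4,
                                        min_rows = 30) {
  direction <- match.arg(direction)
  obs <- observations[observations$direction == direction, , drop = FALSE]
  species <- sort(unique(obs$species))
  out <- NULL
  for (sp in species) {
    d <- obs[obs$species == sp, , drop = FALSE]
    row <- data.frame(species = sp, n = nrow(d), p_smooth = NA_real_,
                      clear = NA, highlight = NA,
                      endpoint_diff = NA_real_, trend_rho = NA_real_,
                      class = NA_character_,
                      error = NA_character_, stringsAsFactors = FALSE)
    if (nrow(d) < min_rows) {
      row$error <- paste0("skipped: ", nrow(d), " rows < min_rows")
      out <- rbind(out, row)
      next
    }
    res <- tryCatch({
      fl <- .floor_strengths(d$strength)
      d$strength <- fl$strength
      fitted <- .fit_gamma_smooth(d, predictor, c("site", "partner"))
      sm <- summary(fitted$gam)
      p <- unname(sm$s.table[1, "p-value"])
      qs <- stats::quantile(d[[predictor]], c(0.05, 0.95), names = FALSE)
      qgrid <- data.frame(qs); names(qgrid) <- predictor
      fq <- .smooth_predict(fitted, qgrid)
      dgrid <- data.frame(d[[predictor]]); names(dgrid) <- predictor
      fd <- .smooth_predict(fitted, dgrid)
      rho <- suppressWarnings(
        stats::cor(as.numeric(fd), d[[predictor]], method = "spearman"))
      list(p = p, diff = unname(fq[2] - fq[1]), rho = rho)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$p_smooth <- res$p
      row$clear <- is.finite(res$p) && res$p < alpha
      row$highlight <- is.finite(res$p) && res$p < alpha_highlight
      row$endpoint_diff <- res$diff
      row$trend_rho <- res$rho
      row$class <- .classify_smooth(res$rho)
    }
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}
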