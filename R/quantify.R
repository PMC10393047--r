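# Spike-in quantification: metabarcoding reads -> estimated eDNA copy
# numbers, dominant-species selection, and merged standardized series.

#' Convert sequence reads to eDNA copy numbers via the internal spike-in
#'
#' Per sample, the conversion factor (reads generated per eDNA copy) is the
#' spike-in species' reads divided by its qPCR-measured copy concentration;
#' every species' reads are divided by that factor. Zero spike measurements
#' are replaced before forming the ratio: a zero qPCR value by
#' `min_spike_copies` and zero spike reads by `min_spike_reads`. When the
#' minima are `NULL` they are recomputed from the panel as the smallest
#' positive observed spike copies / spike reads (the convention used to set
#' the documented defaults of 0.346 copies/uL and 12 reads on the original
#' survey these rules mirror).
#'
#' Non-spike zeros are left at zero: the replacement exists only so the
#' conversion factor is defined in every sample.
#'
#' @param panel Long data.frame with columns site, time_index, species,
#'   reads, spike_copies (per-sample qPCR measurement, repeated across the
#'   sample's rows).
#' @param spike_species Species id of the internal standard.
#' @param min_spike_copies,min_spike_reads Zero-replacement minima; `NULL`
#'   recomputes them as the observed positive minima.
#' @return The panel with a `copies` column (estimated copies per uL).
#' @export
reads_to_copies <- function(panel, spike_species,
                            min_spike_copies = NULL, min_spike_reads = NULL) {
  stopifnot(all(c("site", "time_index", "species", "reads", "spike_copies")
                %in% names(panel)))
  if (!spike_species %in% panel$species) {
    stop("spike species '", spike_species, "' absent from panel")
  }
  spike <- panel[panel$species == spike_species, ]
  key <- function(d) paste(d$site, d$time_index, sep = "\r")
  if (anyDuplicated(key(spike))) stop("duplicated spike rows per sample")
  missing_samples <- setdiff(unique(key(panel)), key(spike))
  if (length(missing_samples)) {
    stop("spike species missing in sample(s): ",
         paste(gsub("\r", "/", utils::head(missing_samples, 3)), collapse = ", "))
  }
  if (is.null(min_spike_copies)) {
    pos <- spike$spike_copies[spike$spike_copies > 0]
    if (!length(pos)) stop("no positive spike copy measurements; supply min_spike_copies")
    min_spike_copies <- min(pos)
  }
  if (is.null(min_spike_reads)) {
    pos <- spike$reads[spike$reads > 0]
    if (!length(pos)) stop("no positive spike read counts; supply min_spike_reads")
    min_spike_reads <- min(pos)
  }
  stopifnot(min_spike_copies > 0, min_spike_reads > 0)
  spike_reads <- ifelse(spike$reads > 0, spike$reads, min_spike_reads)
  spike_copies <- ifelse(spike$spike_copies > 0, spike$spike_copies,
                         min_spike_copies)
  conv <- spike_reads / spike_copies          # reads per copy, per sample
  idx <- match(key(panel), key(spike))
  panel$copies <- panel$reads / conv[idx]
  panel
}

#' Select the most frequently detected species
#'
#' Ranks species by detection frequency (number of samples with reads > 0),
#' breaking ties by total reads and then by species id, and returns the top
#' `n`. Restricting inference to dominant species keeps enough information in
#' each series for state-space reconstruction.
#'
#' @param panel Long data.frame with species and reads columns.
#' @param n Number of species to keep.
#' @return Character vector of `n` species ids, most frequent first.
#' @export
select_top_species <- function(panel, n) {
  det <- tapply(panel$reads > 0, panel$species, sum)
  tot <- tapply(panel$reads, panel$species, sum)
  sp <- names(det)
  if (n > length(sp)) stop("n exceeds the number of species (", length(sp), ")")
  ord <- order(-det, -tot, sp)
  sp[ord][seq_len(n)]
}

#' Merge series across sites and standardize to zero mean, unit variance
#'
#' For each selected variable the per-site series are concatenated in a fixed
#' site order and the merged series is scaled to mean 0 and SD 1. Site
#' boundaries are recorded so that delay embeddings never span two sites.
#' Environmental covariates are carried through and standardized the same
#' way. Missing sampling events stay `NA` and are never imputed.
#'
#' @param panel Long data.frame with a `copies` column (see
#'   [reads_to_copies()]) and per-sample environmental columns.
#' @param species Character vector of species to include (see
#'   [select_top_species()]).
#' @param env_vars Environmental covariate columns to carry (those present
#'   are used).
#' @param per_site Standardize within each site instead of over the merged
#'   series (off by default; the merged convention is the one the inference
#'   stages assume).
#' @return An object of class `std_panel`: `values` (rows = merged time
#'   points, columns = species then covariates), `site`, `time_index`,
#'   `segments` (integer segment id per row), `scaling` (mean/SD used).
#' @export
standardize_merge <- function(panel, species,
                              env_vars = c("temperature", "salinity",
                                           "wave", "tide"),
                              per_site = FALSE) {
  stopifnot(length(species) >= 1, "copies" %in% names(panel))
  env_vars <- intersect(env_vars, names(panel))
  sites <- sort(unique(panel$site))
  # one row per (site, time), sites concatenated in sorted order
  base <- unique(panel[, c("site", "time_index")])
  base <- base[order(match(base$site, sites), base$time_index), ]
  n_row <- nrow(base)
  key <- paste(base$site, base$time_index, sep = "\r")
  vals <- matrix(NA_real_, n_row, length(species) + length(env_vars),
                 dimnames = list(NULL, c(species, env_vars)))
  pkey <- paste(panel$site, panel$time_index, sep = "\r")
  for (sp in species) {
    rows <- panel$species == sp
    vals[match(pkey[rows], key), sp] <- panel$copies[rows]
  }
  for (v in env_vars) {
    first <- !duplicated(pkey)
    vals[match(pkey[first], key), v] <- panel[[v]][first]
  }
  segments <- match(base$site, sites)
  scaling <- data.frame(variable = colnames(vals), mean = NA_real_,
                        sd = NA_real_)
  for (j in seq_len(ncol(vals))) {
    if (per_site) {
      for (s in seq_along(sites)) {
        idx <- segments == s
        m <- mean(vals[idx, j], na.rm = TRUE)
        sdv <- stats::sd(vals[idx, j], na.rm = TRUE)
        if (!is.finite(sdv) || sdv == 0) {
          stop("zero-variance series for '", colnames(vals)[j],
               "' at site ", sites[s], "; cannot standardize")
        }
        vals[idx, j] <- (vals[idx, j] - m) / sdv
      }
      scaling$mean[j] <- 0; scaling$sd[j] <- 1
    } else {
      m <- mean(vals[, j], na.rm = TRUE)
      sdv <- stats::sd(vals[, j], na.rm = TRUE)
      if (!is.finite(sdv) || sdv == 0) {
        if (colnames(vals)[j] %in% species) {
          stop("zero-variance series for species '", colnames(vals)[j],
               "'; cannot standardize")
        }
        # constant covariate: centre to zero, carries no information
        vals[, j] <- vals[, j] - m
        scaling$mean[j] <- m; scaling$sd[j] <- NA_real_
        next
      }
      vals[, j] <- (vals[, j] - m) / sdv
      scaling$mean[j] <- m; scaling$sd[j] <- sdv
    }
  }
  structure(list(values = vals, site = base$site,
                 time_index = base$time_index, segments = segments,
                 species = species, env = env_vars, scaling = scaling),
            class = "std_panel")
}

#' Build a standardized panel directly from aligned series
#'
#' Constructs the `std_panel` container from a matrix of already aligned
#' series (columns = variables, rows = time), standardizing each column to
#' mean 0 and SD 1 within the merged series. Useful when series come from a
#' source other than a read-count panel (simulated latent abundances,
#' benchmark maps).
#'
#' @param values Numeric matrix, one column per variable.
#' @param site Site id per row (defines the segments; defaults to one site).
#' @param env_vars Columns to treat as environmental covariates rather than
#'   species.
#' @param standardize Scale columns to mean 0 / SD 1 (default TRUE).
#' @return A `std_panel`.
#' @export
as_std_panel <- function(values, site = rep("site01", nrow(values)),
                         env_vars = character(), standardize = TRUE) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("v", seq_len(ncol(values)))
  }
  ord <- order(match(site, sort(unique(site))))
  values <- values[ord, , drop = FALSE]
  site <- site[ord]
  segments <- match(site, sort(unique(site)))
  scaling <- data.frame(variable = colnames(values), mean = 0, sd = 1)
  if (standardize) {
    for (j in seq_len(ncol(values))) {
      m <- mean(values[, j], na.rm = TRUE)
      s <- stats::sd(values[, j], na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        values[, j] <- values[, j] - m
        scaling$mean[j] <- m; scaling$sd[j] <- NA_real_
      } else {
        values[, j] <- (values[, j] - m) / s
        scaling$mean[j] <- m; scaling$sd[j] <- s
      }
    }
  }
  time_index <- stats::ave(seq_along(site), site, FUN = seq_along)
  structure(list(values = values, site = site, time_index = time_index,
                 segments = segments,
                 species = setdiff(colnames(values), env_vars),
                 env = intersect(env_vars, colnames(values)),
                 scaling = scaling),
            class = "std_panel")
}

#' @export
print.std_panel <- function(x, ...) {
  cat("Standardized panel:", length(x$species), "species +",
      length(x$env), "covariates,", nrow(x$values), "merged time points over",
      length(unique(x$segments)), "site segment(s)\n")
  invisible(x)
}

#' Per-sample ecological summaries (richness and total eDNA)
#'
#' Computes, for every (site, time) sample, the number of species detected
#' (copies > 0) and the summed eDNA copy concentration, the sample-level
#' covariates used when modelling interaction strengths.
#'
#' @param panel Long data.frame with a `copies` column.
#' @return data.frame: site, time_index, richness, total_copies.
#' @export
sample_summaries <- function(panel) {
  key <- interaction(panel$site, panel$time_index, drop = TRUE)
  agg <- data.frame(
    richness = as.vector(tapply(panel$copies > 0, key, sum)),
    total_copies = as.vector(tapply(panel$copies, key, sum)))
  ids <- do.call(rbind, strsplit(levels(key), ".", fixed = TRUE))
  out <- data.frame(site = ids[, 1],
                    time_index = as.integer(ids[, 2]),
                    agg)
  out[order(out$site, out$time_index), ]
}
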