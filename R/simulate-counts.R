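#' Specification for an overdispersed compositional count table
#'
#' Dirichlet-multinomial generative model for taxon (or KEGG-orthologue)
#' counts over a two-factor design, with planted log2 fold changes on chosen
#' features.  Per sample, the composition is drawn from a Dirichlet with
#' concentration \code{base_proportions / dispersion} (group-modified for
#' planted features), then counts from a multinomial at the sample's library
#' size.  As \code{dispersion} tends to 0 the compositions converge on the
#' base proportions.
#'
#' @param n_taxa number of features.
#' @param n_samples_per_group samples per design cell.
#' @param groups data frame of design cells with columns \code{diet}
#'   (VEH/PREB) and \code{exposure} (Sham/CIH); default the full 2x2.
#' @param base_proportions simplex vector of length \code{n_taxa}; default a
#'   geometric series normalised to 1 (a few dominant taxa, a long tail).
#' @param dispersion overdispersion (> 0; smaller = tighter).
#' @param planted_effects list of \code{list(taxon = index, factor = "diet"
#'   or "exposure", level = affected level, log2fc =)} applied to the base
#'   proportion before renormalisation.
#' @param library_size_range integer range of per-sample totals.
#' @param seed integer seed.
#' @return object of class \code{count_sim_spec}.
#' @export
count_sim_spec <- function(n_taxa = 100, n_samples_per_group = 12,
                           groups = NULL, base_proportions = NULL,
                           dispersion = 0.02, planted_effects = list(),
                           library_size_range = c(20000L, 60000L),
                           seed = 1L) {
  if (is.null(groups))
    groups <- expand.grid(diet = c("VEH", "PREB"),
                          exposure = c("Sham", "CIH"),
                          stringsAsFactors = FALSE)
  if (is.null(base_proportions)) {
    base_proportions <- 0.9^seq_len(n_taxa)
    base_proportions <- base_proportions / sum(base_proportions)
  }
  stop_if_not(length(base_proportions) == n_taxa,
              "base_proportions length must equal n_taxa")
  stop_if_not(abs(sum(base_proportions) - 1) < 1e-8,
              "base_proportions must sum to 1")
  stop_if_not(all(library_size_range > 0), "library sizes must be > 0")
  for (pe in planted_effects)
    stop_if_not(pe$taxon >= 1 && pe$taxon <= n_taxa,
                sprintf("planted taxon index %s out of range", pe$taxon))
  structure(list(n_taxa = n_taxa, n_samples_per_group = n_samples_per_group,
                 groups = groups, base_proportions = base_proportions,
                 dispersion = dispersion, planted_effects = planted_effects,
                 library_size_range = library_size_range,
                 seed = as.integer(seed)),
            class = "count_sim_spec")
}

# Dirichlet draw via gamma normalisation
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a feature-by-sample count table with planted group effects
#'
#' @param spec a \code{\link{count_sim_spec}}.
#' @return list with \code{counts} (a \code{count_table}: integer matrix
#'   features x samples with \code{sample_data} data frame attached) and
#'   \code{truth} (data frame of planted effects: taxon index, feature ID,
#'   factor, level, log2fc).
#' @export
simulate_count_table <- function(spec) {
  stop_if_not(inherits(spec, "count_sim_spec"), "spec must be a count_sim_spec")
  set.seed(spec$seed)
  cells <- spec$groups
  n_cells <- nrow(cells)
  n_samp <- n_cells * spec$n_samples_per_group
  feat_ids <- sprintf("taxon_%03d", seq_len(spec$n_taxa))
  counts <- matrix(0L, spec$n_taxa, n_samp,
                   dimnames = list(feat_ids, NULL))
  sd_list <- list()
  col <- 0L
  for (ci in seq_len(n_cells)) {
    p_cell <- spec$base_proportions
    for (pe in spec$planted_effects) {
      if (cells[[pe$factor]][ci] == pe$level)
        p_cell[pe$taxon] <- p_cell[pe$taxon] * 2^pe$log2fc
    }
    p_cell <- p_cell / sum(p_cell)
    alpha <- p_cell / spec$dispersion
    for (s in seq_len(spec$n_samples_per_group)) {
      col <- col + 1L
      lib <- round(stats::runif(1, spec$library_size_range[1],
                                spec$library_size_range[2]))
      p <- rdirichlet1(alpha)
      counts[, col] <- stats::rmultinom(1, lib, p)[, 1]
      sd_list[[col]] <- data.frame(
        sample_id = sprintf("sample_%02d", col),
        diet = cells$diet[ci], exposure = cells$exposure[ci])
    }
  }
  sample_data <- do.call(rbind, sd_list)
  colnames(counts) <- sample_data$sample_id
  truth <- if (length(spec$planted_effects)) {
    do.call(rbind, lapply(spec$planted_effects, function(pe)
      data.frame(taxon = pe$taxon, feature_id = feat_ids[pe$taxon],
                 factor = pe$factor, level = pe$level, log2fc = pe$log2fc)))
  } else {
    data.frame(taxon = integer(), feature_id = character(),
               factor = character(), level = character(), log2fc = numeric())
  }
  list(counts = count_table(counts, sample_data), truth = truth)
}
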