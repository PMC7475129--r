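#' Construct a feature-by-sample count table
#'
#' @param counts non-negative integer matrix, features x samples, with row
#'   (feature) and column (sample) names.
#' @param sample_data data frame of per-sample metadata (first column
#'   \code{sample_id}; typically also group labels), or NULL.
#' @return object of class \code{count_table} (the matrix, with
#'   \code{sample_data} attached as an attribute).
#' @export
count_table <- function(counts, sample_data = NULL) {
  counts <- as.matrix(counts)
  stop_if_not(all(counts >= 0), "counts must be non-negative")
  stop_if_not(!anyDuplicated(rownames(counts)) && !is.null(rownames(counts)),
              "feature IDs must be present and unique")
  stop_if_not(all(colSums(counts) > 0), "every sample must have > 0 total counts")
  if (!is.null(sample_data))
    stop_if_not(nrow(sample_data) == ncol(counts),
                "sample_data rows must match samples")
  structure(counts, sample_data = sample_data,
            class = c("count_table", "matrix"))
}

#' Prevalence and abundance filtering of a count table
#'
#' Features present (count > 0) in 5\% or fewer of samples are removed.  A
#' second, differential-abundance eligibility mask marks the retained
#' features whose within-sample relative abundance reaches at least 0.5\% in
#' one or more samples; features below that stay in the table (they
#' contribute to the composition) but are not tested.
#'
#' @param counts a \code{count_table}.
#' @param prevalence prevalence threshold (fraction of samples; features at
#'   or below it are removed).
#' @param da_abundance relative-abundance threshold for test eligibility.
#' @return list: \code{counts} (filtered \code{count_table}),
#'   \code{da_eligible} (named logical over retained features).
#' @export
filter_features <- function(counts, prevalence = 0.05, da_abundance = 0.005) {
  stop_if_not(inherits(counts, "count_table"), "counts must be a count_table")
  n_samp <- ncol(counts)
  prev <- rowSums(counts > 0) / n_samp
  keep <- prev > prevalence
  stop_if_not(any(keep), "all features removed by the prevalence filter")
  rel <- sweep(counts, 2, colSums(counts), "/")
  da <- apply(rel >= da_abundance, 1, any)
  filtered <- count_table(unclass(counts)[keep, , drop = FALSE],
                          attr(counts, "sample_data"))
  list(counts = filtered, da_eligible = da[keep])
}

#' Centred log-ratio (CLR) transform
#'
#' Per sample, counts are shifted by a pseudocount and each log-abundance is
#' expressed relative to the sample's geometric mean:
#' clr_i = ln(x_i) - mean_j ln(x_j).  Rows (samples) sum to zero and the
#' transform is invariant to per-sample scaling, the defining properties of
#' compositional coordinates.
#'
#' @param counts a \code{count_table} (typically filtered).
#' @param pseudocount value added to every count before logging.
#' @return object of class \code{clr_matrix}: features x samples real
#'   matrix with the \code{pseudocount} and \code{sample_data} attached.
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  stop_if_not(inherits(counts, "count_table") || is.matrix(counts),
              "counts must be a count_table or matrix")
  x <- unclass(counts) + pseudocount
  lg <- log(x)
  clr <- sweep(lg, 2, colMeans(lg), "-")
  structure(clr, pseudocount = pseudocount,
            sample_data = attr(counts, "sample_data"),
            class = c("clr_matrix", "matrix"))
}

#' Alpha diversity per sample
#'
#' Bias-corrected Chao1 richness S_obs + f1 (f1 - 1) / (2 (f2 + 1)) (f1, f2 =
#' singleton and doubleton counts), Shannon entropy in nats over nonzero
#' proportions, and Gini-Simpson index 1 - sum(p^2).  Computed on raw
#' (unfiltered) counts.
#'
#' @param counts a \code{count_table} of raw counts.
#' @return data frame of class \code{diversity_result}: \code{sample_id},
#'   \code{observed}, \code{chao1}, \code{shannon}, \code{simpson}.
#' @export
alpha_diversity <- function(counts) {
  stop_if_not(inherits(counts, "count_table") || is.matrix(counts),
              "counts must be a count_table or matrix")
  m <- unclass(counts)
  stop_if_not(all(colSums(m) > 0), "empty sample")
  res <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[x > 0]
    p <- x / sum(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    data.frame(sample_id = colnames(m)[j],
               observed = length(x),
               chao1 = length(x) + f1 * (f1 - 1) / (2 * (f2 + 1)),
               shannon = -sum(p * log(p)),
               simpson = 1 - sum(p^2))
  })
  out <- do.call(rbind, res)
  class(out) <- c("diversity_result", "data.frame")
  out
}

#' Principal component analysis of CLR-transformed compositions (Aitchison PCA)
#'
#' Samples are rows; the CLR matrix is centred and decomposed with
#' \code{stats::prcomp}.
#'
#' @param clr a \code{clr_matrix} (features x samples).
#' @param n_components number of components to return.
#' @return list of class \code{pca_result}: \code{scores} (samples x PCs),
#'   \code{loadings}, \code{explained} (variance fractions).
#' @export
pca_clr <- function(clr, n_components = 2L) {
  stop_if_not(ncol(clr) >= 3, "need at least 3 samples")
  x <- t(unclass(clr))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  stop_if_not(sum(pc$sdev > 1e-12) >= 2, "CLR matrix has rank < 2")
  k <- min(n_components, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = expl[seq_len(k)]),
            class = "pca_result")
}

# sum of squared pairwise distances within each group, divided by group size
.ss_within <- function(d2, labels) {
  ss <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    ss <- ss + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss
}

permanova_f <- function(d2, labels) {
  n <- length(labels)
  g <- length(unique(labels))
  ss_tot <- sum(d2) / (2 * n)
  ss_w <- .ss_within(d2, labels)
  ((ss_tot - ss_w) / (g - 1)) / (ss_w / (n - g))
}

#' PERMANOVA on Aitchison distances
#'
#' Permutational multivariate analysis of variance on Euclidean distances
#' between CLR-transformed samples (the Aitchison distance).  The pseudo-F
#' statistic is (SS_between / (g - 1)) / (SS_within / (n - g)); the p-value
#' counts permutations with F at least as large as observed, including the
#' observed labelling: p = (1 + #{F_perm >= F_obs}) / (1 + n_perm), which
#' guarantees p > 0 and exactness.  In pairwise mode each pair of groups is
#' tested separately; a group with fewer than 3 samples is skipped with a
#' warning.
#'
#' @param clr a \code{clr_matrix} (features x samples) or a numeric matrix of
#'   sample coordinates (samples x variables) with \code{coords = TRUE}.
#' @param labels group label per sample.
#' @param n_perm number of permutations.
#' @param pairwise test all group pairs (TRUE) or the overall partition.
#' @param seed integer seed for the permutation stream.
#' @param coords treat \code{clr} as samples x variables coordinates.
#' @param exact for two-group comparisons, enumerate every distinct label
#'   assignment instead of sampling (feasible only for small n); the p-value
#'   is then the exact permutation p including the observed assignment.
#' @return data frame of class \code{permanova_result}: \code{group1},
#'   \code{group2} (NA for the overall test), \code{pseudo_F}, \code{p},
#'   \code{n_perm} (number of distinct assignments when exact).
#' @export
permanova <- function(clr, labels, n_perm = 1000, pairwise = TRUE,
                      seed = 1L, coords = FALSE, exact = FALSE) {
  x <- if (coords) as.matrix(clr) else t(unclass(clr))
  labels <- as.character(labels)
  stop_if_not(nrow(x) == length(labels), "labels must match samples")
  set.seed(seed)
  run_one <- function(xs, ls) {
    d2 <- as.matrix(stats::dist(xs))^2
    f_obs <- permanova_f(d2, ls)
    n <- length(ls)
    if (exact) {
      lv <- unique(ls)
      stop_if_not(length(lv) == 2, "exact enumeration supports two groups")
      n1 <- sum(ls == lv[1])
      assigns <- utils::combn(n, n1, simplify = FALSE)
      fs <- vapply(assigns, function(idx) {
        lp <- rep(lv[2], n)
        lp[idx] <- lv[1]
        permanova_f(d2, lp)
      }, numeric(1))
      return(c(f = f_obs, p = mean(fs >= f_obs - 1e-12),
               nperm = length(assigns)))
    }
    exceed <- 0L
    for (k in seq_len(n_perm)) {
      fp <- permanova_f(d2, ls[sample.int(n)])
      if (fp >= f_obs - 1e-12) exceed <- exceed + 1L
    }
    c(f = f_obs, p = (1 + exceed) / (1 + n_perm), nperm = n_perm)
  }
  groups <- unique(labels)
  small <- groups[table(labels)[groups] < 3]
  if (length(small)) {
    warning(sprintf("group(s) with < 3 samples skipped: %s",
                    paste(small, collapse = ", ")))
    keep <- !(labels %in% small)
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
    groups <- setdiff(groups, small)
  }
  stop_if_not(length(groups) >= 2, "need at least two groups of >= 3 samples")
  if (!pairwise) {
    r <- run_one(x, labels)
    out <- data.frame(group1 = "overall", group2 = NA_character_,
                      pseudo_F = r[["f"]], p = r[["p"]], n_perm = r[["nperm"]])
  } else {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    out <- do.call(rbind, lapply(pairs, function(pr) {
      keep <- labels %in% pr
      r <- run_one(x[keep, , drop = FALSE], labels[keep])
      data.frame(group1 = pr[1], group2 = pr[2],
                 pseudo_F = r[["f"]], p = r[["p"]], n_perm = r[["nperm"]])
    }))
  }
  rownames(out) <- NULL
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' Differential abundance in CLR space with BH FDR
#'
#' For each test-eligible feature, a two-sample comparison of CLR values
#' between the two groups: Welch's t-test when both groups pass Shapiro-Wilk
#' normality at the gate alpha, a Wilcoxon rank-sum test otherwise (the same
#' normality gating the rest of the analysis uses).  This is a single
#' CLR-space test per feature, not a Dirichlet Monte-Carlo average; p-values
#' are Benjamini-Hochberg adjusted and features with q at or below \code{fdr}
#' are called.  Effect size is the difference of group medians divided by the
#' pooled median absolute deviation.
#'
#' @param clr a \code{clr_matrix}.
#' @param labels two-level group label per sample.
#' @param da_mask logical eligibility mask over features (from
#'   \code{\link{filter_features}}); NULL tests all features.
#' @param fdr target false discovery rate.
#' @param gate_alpha Shapiro-Wilk gate level.
#' @return data frame of class \code{differential_result}: \code{feature_id},
#'   \code{mean_1}, \code{mean_2} (CLR group means), \code{test}
#'   ("welch"/"wilcoxon"), \code{statistic}, \code{p}, \code{q},
#'   \code{effect}, \code{significant}.
#' @export
differential_abundance <- function(clr, labels, da_mask = NULL, fdr = 0.10,
                                   gate_alpha = 0.05) {
  labels <- as.character(labels)
  lv <- unique(labels)
  stop_if_not(length(lv) == 2, "exactly two groups required")
  stop_if_not(all(table(labels) >= 3), "each group needs >= 3 samples")
  m <- unclass(clr)
  if (is.null(da_mask)) da_mask <- rep(TRUE, nrow(m))
  feats <- which(da_mask)
  if (!length(feats)) {
    out <- data.frame(feature_id = character(), mean_1 = numeric(),
                      mean_2 = numeric(), test = character(),
                      statistic = numeric(), p = numeric(), q = numeric(),
                      effect = numeric(), significant = logical())
    class(out) <- c("differential_result", "data.frame")
    return(out)
  }
  i1 <- labels == lv[1]
  i2 <- labels == lv[2]
  rows <- lapply(feats, function(f) {
    a <- m[f, i1]
    b <- m[f, i2]
    normal <- function(v) {
      if (stats::sd(v) == 0) return(FALSE)
      stats::shapiro.test(v)$p.value >= gate_alpha
    }
    if (normal(a) && normal(b)) {
      tt <- stats::t.test(a, b)
      test <- "welch"
    } else {
      tt <- suppressWarnings(stats::wilcox.test(a, b))
      test <- "wilcoxon"
    }
    pooled_mad <- sqrt((stats::mad(a)^2 + stats::mad(b)^2) / 2)
    data.frame(feature_id = rownames(m)[f],
               mean_1 = mean(a), mean_2 = mean(b), test = test,
               statistic = unname(tt$statistic), p = tt$p.value,
               effect = if (pooled_mad > 0)
                 (stats::median(a) - stats::median(b)) / pooled_mad else NA_real_)
  })
  out <- do.call(rbind, rows)
  adj <- bh_adjust(out$p, q = fdr)
  out$q <- adj$q_values
  out$significant <- adj$rejected
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Aggregate KEGG-orthologue counts into functional modules
#'
#' Gut-brain and gut-metabolic modules are ordered pathway steps, each step a
#' set of alternative KEGG orthologues (KOs).  Per module and sample: step
#' abundance is the sum of that step's alternative KOs; coverage is the
#' fraction of steps with nonzero abundance; module abundance is the median
#' over steps when coverage reaches \code{coverage_min}, and 0 otherwise.  A
#' module with no KO present simply scores (0, 0).
#'
#' @param ko_counts a \code{count_table} of KO x sample counts (IDs
#'   "K00001"-style).
#' @param defs list of module definitions, each
#'   \code{list(module_id =, name =, steps = list(character vectors of KOs))}
#'   (see \code{\link{read_module_definitions}}).
#' @param coverage_min minimum step coverage for a nonzero module abundance.
#' @return list of class \code{module_table}: \code{abundance} and
#'   \code{coverage} matrices (modules x samples).
#' @export
aggregate_modules <- function(ko_counts, defs, coverage_min = 0.66) {
  m <- unclass(ko_counts)
  ids <- vapply(defs, function(d) d$module_id, character(1))
  nm <- length(defs)
  ab <- matrix(0, nm, ncol(m), dimnames = list(ids, colnames(m)))
  cov <- matrix(0, nm, ncol(m), dimnames = list(ids, colnames(m)))
  for (i in seq_len(nm)) {
    steps <- defs[[i]]$steps
    stop_if_not(length(steps) >= 1, "module must have >= 1 step")
    step_ab <- t(vapply(steps, function(kos) {
      present <- intersect(kos, rownames(m))
      if (!length(present)) return(numeric(ncol(m)))
      colSums(m[present, , drop = FALSE])
    }, numeric(ncol(m))))
    cov[i, ] <- colMeans(step_ab > 0)
    med <- apply(step_ab, 2, stats::median)
    ab[i, ] <- ifelse(cov[i, ] >= coverage_min, med, 0)
  }
  structure(list(abundance = ab, coverage = cov), class = "module_table")
}
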