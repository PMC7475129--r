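#' Choose the parametric or nonparametric analysis path
#'
#' The decision tree applied to every group table: a metric is analysed
#' parametrically iff every group passes Shapiro-Wilk normality and the
#' groups pass Levene's test of variance homogeneity, both at the gate alpha.
#' A degenerate (zero-variance) group fails the gate and forces the
#' nonparametric path.  The decision is a pure function of the data.
#'
#' @param values numeric vector of observations.
#' @param group factor/character of group membership (>= 3 values per group).
#' @param gate_alpha gate level for both tests.
#' @return list of class \code{path_choice}: \code{path}
#'   ("parametric"/"nonparametric"), \code{shapiro_p} (per group),
#'   \code{levene_p}, \code{degenerate} (TRUE when a group had zero
#'   variance).
#' @export
choose_path <- function(values, group, gate_alpha = 0.05) {
  group <- factor(group)
  stop_if_not(all(table(group) >= 3), "every group needs >= 3 values")
  degenerate <- any(tapply(values, group, stats::sd) == 0)
  shapiro_p <- vapply(levels(group), function(g) {
    v <- values[group == g]
    if (stats::sd(v) == 0) return(0)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  levene_p <- if (degenerate) 0 else
    car::leveneTest(values ~ group)[1, "Pr(>F)"]
  path <- if (!degenerate && all(shapiro_p >= gate_alpha) &&
              levene_p >= gate_alpha) "parametric" else "nonparametric"
  structure(list(path = path, shapiro_p = shapiro_p, levene_p = levene_p,
                 degenerate = degenerate),
            class = "path_choice")
}

# the four planned comparisons of the 2x2 exposure-by-diet design
planned_comparisons <- function() {
  list(c("Sham.VEH", "CIH.VEH"), c("CIH.VEH", "CIH.PREB"),
       c("Sham.PREB", "CIH.PREB"), c("Sham.VEH", "Sham.PREB"))
}

#' Group analysis over the 2x2 design
#'
#' Reproduces the decision tree used for the physiology, SCFA, neurochemistry
#' and cytokine tables: gate with \code{\link{choose_path}}; on the
#' parametric path run a two-way ANOVA (diet, exposure, interaction) followed
#' by Fisher's LSD pairwise comparisons (unadjusted pairwise t-tests
#' restricted to the four planned pairs); on the nonparametric path run
#' Kruskal-Wallis over the four cells followed by pairwise Mann-Whitney U
#' tests.  Pairwise significance is assessed against a Bonferroni-adjusted
#' alpha of family_alpha / n_comparisons (0.05 / 4 = 0.0125 for the planned
#' set).  Outliers are reported by the 1.5 IQR box-plot rule but never
#' removed.
#'
#' @param table data frame with columns \code{subject_id}, \code{diet}
#'   (VEH/PREB), \code{exposure} (Sham/CIH), \code{value} for one metric.
#' @param family_alpha family-wise alpha for the planned comparisons.
#' @param gate_alpha gate level for the path choice.
#' @param require_omnibus gate the pairwise tests on omnibus significance at
#'   \code{family_alpha} (FALSE: always report pairwise p-values).
#' @return list of class \code{test_report}: \code{path}, \code{gates},
#'   \code{omnibus} (data frame of terms and p-values), \code{pairwise}
#'   (data frame: comparison, p, significant), \code{adjusted_alpha},
#'   \code{n_outliers}.
#' @export
run_group_analysis <- function(table, family_alpha = 0.05, gate_alpha = 0.05,
                               require_omnibus = FALSE) {
  stop_if_not(all(c("diet", "exposure", "value") %in% names(table)),
              "table needs diet, exposure, value columns")
  table$diet <- factor(table$diet, levels = c("VEH", "PREB"))
  table$exposure <- factor(table$exposure, levels = c("Sham", "CIH"))
  stop_if_not(!any(is.na(table$diet)) && !any(is.na(table$exposure)),
              "diet must be VEH/PREB and exposure Sham/CIH")
  cell <- interaction(table$exposure, table$diet)   # Sham.VEH etc.
  stop_if_not(nlevels(droplevels(cell)) == 4, "2x2 design incomplete")
  gates <- choose_path(table$value, cell, gate_alpha)

  outlier <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75))
    sum(v < q[1] - 1.5 * diff(q) | v > q[2] + 1.5 * diff(q))
  }
  n_out <- sum(tapply(table$value, cell, outlier))

  comparisons <- planned_comparisons()
  adjusted_alpha <- family_alpha / length(comparisons)

  if (gates$path == "parametric") {
    fit <- stats::aov(value ~ diet * exposure, data = table)
    tab <- summary(fit)[[1]]
    omnibus <- data.frame(term = trimws(rownames(tab)[1:3]),
                          statistic = tab[1:3, "F value"],
                          p = tab[1:3, "Pr(>F)"])
    pair_p <- vapply(comparisons, function(cmp) {
      stats::t.test(table$value[cell == cmp[1]],
                    table$value[cell == cmp[2]], var.equal = TRUE)$p.value
    }, numeric(1))
    omnibus_sig <- any(omnibus$p < family_alpha)
  } else {
    kw <- stats::kruskal.test(table$value, cell)
    omnibus <- data.frame(term = "cell", statistic = unname(kw$statistic),
                          p = kw$p.value)
    pair_p <- vapply(comparisons, function(cmp) {
      suppressWarnings(stats::wilcox.test(
        table$value[cell == cmp[1]], table$value[cell == cmp[2]]))$p.value
    }, numeric(1))
    omnibus_sig <- kw$p.value < family_alpha
  }
  report_pairs <- !require_omnibus || omnibus_sig
  pairwise <- data.frame(
    comparison = vapply(comparisons, paste, character(1), collapse = " v "),
    p = if (report_pairs) pair_p else NA_real_,
    significant = if (report_pairs) pair_p < adjusted_alpha else FALSE)
  structure(list(path = gates$path, gates = gates, omnibus = omnibus,
                 pairwise = pairwise, adjusted_alpha = adjusted_alpha,
                 n_outliers = n_out),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> path: %s (adjusted alpha %.4f)\n",
              x$path, x$adjusted_alpha))
  print(x$omnibus, row.names = FALSE)
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: monotonised q-values via \code{stats::p.adjust} and the
#' step-up rejection set at the target FDR (reject all hypotheses with q at
#' or below \code{q}).
#'
#' @param p_values p-values in [0, 1].
#' @param q target false discovery rate.
#' @return list: \code{q_values}, \code{rejected} (logical).
#' @export
bh_adjust <- function(p_values, q = 0.10) {
  stop_if_not(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  qv <- stats::p.adjust(p_values, method = "BH")
  list(q_values = qv, rejected = !is.na(qv) & qv <= q)
}

#' Flat all-against-all Spearman correlation screen
#'
#' Every feature is correlated with every target metric by Spearman's rho;
#' p-values are BH-adjusted across the whole screen and pairs with q below
#' the threshold are reported.  This is a flat (non-hierarchical) screen: no
#' clustering of features is performed, and the output metadata says so.
#' Constant vectors are skipped with a flag.
#'
#' @param features numeric matrix, features x samples (e.g. a
#'   \code{clr_matrix}), or a data frame of per-sample metrics (columns =
#'   features) with \code{samples_in_rows = TRUE}.
#' @param targets numeric matrix/data frame of target metrics, one column per
#'   metric, samples in rows.
#' @param q FDR threshold for reporting.
#' @param samples_in_rows features matrix orientation.
#' @return data frame of class \code{correlation_screen}: \code{feature},
#'   \code{target}, \code{rho}, \code{p}, \code{q}, \code{significant},
#'   \code{skipped_constant}; attribute \code{method} =
#'   "spearman, flat (non-hierarchical) screen".
#' @export
correlation_screen <- function(features, targets, q = 0.10,
                               samples_in_rows = FALSE) {
  f <- if (samples_in_rows) t(as.matrix(features)) else
    as.matrix(unclass(features))
  tg <- as.matrix(targets)
  stop_if_not(ncol(f) == nrow(tg),
              "features samples must match target rows")
  stop_if_not(nrow(tg) >= 5, "need at least 5 paired observations")
  rows <- list()
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(ncol(tg))) {
      x <- f[i, ]
      y <- tg[, j]
      ok <- is.finite(x) & is.finite(y)
      const <- stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0
      if (const || sum(ok) < 5) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = rownames(f)[i], target = colnames(tg)[j],
          rho = NA_real_, p = NA_real_, skipped_constant = TRUE)
      } else {
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman"))
        rows[[length(rows) + 1L]] <- data.frame(
          feature = rownames(f)[i], target = colnames(tg)[j],
          rho = unname(ct$estimate), p = ct$p.value,
          skipped_constant = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  adj <- bh_adjust(out$p, q = q)
  out$q <- adj$q_values
  out$significant <- adj$rejected
  attr(out, "method") <- "spearman, flat (non-hierarchical) screen"
  class(out) <- c("correlation_screen", "data.frame")
  out
}
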