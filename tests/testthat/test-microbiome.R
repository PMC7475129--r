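toy_counts <- function(m, groups = NULL) {
  rownames(m) <- sprintf("t%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  sd_ <- if (!is.null(groups)) data.frame(sample_id = colnames(m),
                                          group = groups) else NULL
  count_table(m, sd_)
}

test_that("prevalence and abundance filters follow the printed thresholds", {
  set.seed(1)
  m <- matrix(rpois(10 * 48, 50), 10, 48)
  m[1, ] <- 0; m[1, 3] <- 5          # 1 of 48 samples ~ 2%: removed
  m[2, ] <- 0                        # absent everywhere: removed
  m[3, ] <- 1                        # rare but prevalent: kept, not eligible
  ct <- toy_counts(m)
  fl <- filter_features(ct)
  expect_false("t01" %in% rownames(fl$counts))
  expect_false("t02" %in% rownames(fl$counts))
  expect_true("t03" %in% rownames(fl$counts))
  # t03 peaks below 0.5% relative abundance: not test-eligible
  rel3 <- max(1 / colSums(ct))
  expect_lt(rel3, 0.005)
  expect_false(fl$da_eligible[["t03"]])
  expect_true(all(fl$da_eligible[c("t04", "t05")]))
  # every feature in exactly 1 of 25 samples (4%): all removed
  expect_error(filter_features(toy_counts(diag(25) * 5L)), "all features")
})

test_that("CLR transform has the compositional properties", {
  # equal counts -> all zeros
  eq <- clr_transform(toy_counts(matrix(7, 5, 3)))
  expect_true(all(abs(eq) < 1e-12))
  # known geometric-mean arithmetic (no pseudocount needed, no zeros)
  v <- clr_transform(toy_counts(matrix(c(1, 10, 100), 3, 1)), pseudocount = 0)
  expect_equal(as.numeric(v), c(-log(10), 0, log(10)), tolerance = 1e-12)
  # rows (samples) sum to zero; scale invariance
  set.seed(2)
  m <- matrix(rpois(60, 30) + 1, 6, 10)
  c1 <- clr_transform(toy_counts(m), pseudocount = 0)
  expect_lt(max(abs(colSums(c1))), 1e-9)
  c2 <- clr_transform(toy_counts(m * 13L), pseudocount = 0)
  expect_equal(unclass(c1), unclass(c2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("alpha diversity matches closed forms and the vegan oracle", {
  u4 <- toy_counts(matrix(c(25, 25, 25, 25), 4, 1))
  d <- alpha_diversity(u4)
  expect_equal(d$shannon, log(4), tolerance = 1e-12)
  expect_equal(d$simpson, 0.75, tolerance = 1e-12)
  # counts (5,3,1,1,2): S = 5, f1 = 2, f2 = 1 -> chao1 = 5.5
  d2 <- alpha_diversity(toy_counts(matrix(c(5, 3, 1, 1, 2), 5, 1)))
  expect_equal(d2$chao1, 5.5)
  d3 <- alpha_diversity(toy_counts(matrix(c(9, 0, 0), 3, 1)))
  expect_equal(d3$shannon, 0)
  expect_equal(d3$simpson, 0)
  expect_equal(d3$chao1, 1)
  skip_if_not_installed("vegan")
  set.seed(3)
  m <- matrix(rpois(80, 8), 8, 10)
  m[m < 0] <- 0
  m <- m + 1L  # avoid empty samples
  ours <- alpha_diversity(toy_counts(m))
  expect_equal(ours$shannon,
               unname(vegan::diversity(t(m), index = "shannon")),
               tolerance = 1e-10)
  expect_equal(ours$simpson,
               unname(vegan::diversity(t(m), index = "simpson")),
               tolerance = 1e-10)
  expect_equal(ours$chao1, unname(vegan::estimateR(t(m))["S.chao1", ]),
               tolerance = 1e-8)
})

test_that("Aitchison PCA separates planted clusters and orders variance", {
  set.seed(4)
  base <- c(rep(0.4 / 5, 5), rep(0.6 / 15, 15))
  shifted <- base * c(2^3, rep(1, 19))
  sim1 <- simulate_count_table(count_sim_spec(
    n_taxa = 20, n_samples_per_group = 5, base_proportions = base,
    dispersion = 0.002,
    planted_effects = list(list(taxon = 1, factor = "exposure",
                                level = "CIH", log2fc = 4)), seed = 5))
  clr <- clr_transform(filter_features(sim1$counts)$counts)
  pc <- pca_clr(clr)
  grp <- attr(clr, "sample_data")$exposure
  # PC1 separates the planted groups (positive silhouette on PC1)
  s1 <- pc$scores[, 1]
  gap <- abs(mean(s1[grp == "CIH"]) - mean(s1[grp == "Sham"]))
  spread <- max(tapply(s1, grp, sd))
  expect_gt(gap / spread, 2)
  expect_true(all(diff(pc$explained) <= 1e-12))
  # duplicated samples get identical scores
  m <- unclass(sim1$counts)[, c(1:5, 1)]
  colnames(m) <- sprintf("d%d", 1:6)
  pc2 <- pca_clr(clr_transform(count_table(m)))
  expect_equal(pc2$scores[1, ], pc2$scores[6, ], tolerance = 1e-9)
})

test_that("PERMANOVA matches exhaustive enumeration and the vegan oracle", {
  set.seed(6)
  x <- matrix(rnorm(6 * 4), 6, 4)
  labs <- rep(c("a", "b"), each = 3)
  mine <- permanova(x, labs, coords = TRUE, pairwise = FALSE, exact = TRUE)
  # brute force over all 6! label permutations
  expect_equal(mine$p, permanova_enum_oracle(x, labs), tolerance = 1e-12)
  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(dist(x) ~ g, data = data.frame(g = labs),
                        permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-9)
})

test_that("PERMANOVA detects a planted multivariate shift", {
  set.seed(7)
  x <- rbind(matrix(rnorm(10 * 5), 10, 5),
             matrix(rnorm(10 * 5, mean = 3), 10, 5))
  labs <- rep(c("a", "b"), each = 10)
  r <- permanova(x, labs, coords = TRUE, pairwise = FALSE, n_perm = 999,
                 seed = 8)
  expect_lte(r$p, 0.005)
  expect_warning(permanova(x, c(rep("a", 9), rep("b", 9), "c", "c"),
                           coords = TRUE, n_perm = 9), "skipped")
})

test_that("pairwise PERMANOVA covers every group pair", {
  set.seed(9)
  x <- matrix(rnorm(12 * 3), 12, 3)
  labs <- rep(c("g1", "g2", "g3"), each = 4)
  r <- permanova(x, labs, coords = TRUE, n_perm = 99, seed = 1)
  expect_equal(nrow(r), 3)
  expect_setequal(paste(r$group1, r$group2),
                  c("g1 g2", "g1 g3", "g2 g3"))
  expect_true(all(r$p > 0 & r$p <= 1))
})

test_that("CLR differential abundance recovers planted features under BH", {
  sim <- simulate_count_table(count_sim_spec(
    n_taxa = 40, n_samples_per_group = 12, dispersion = 0.01,
    planted_effects = list(
      list(taxon = 2, factor = "exposure", level = "CIH", log2fc = 2),
      list(taxon = 7, factor = "exposure", level = "CIH", log2fc = -2)),
    seed = 10))
  sd_ <- attr(sim$counts, "sample_data")
  fl <- filter_features(sim$counts)
  clr <- clr_transform(fl$counts)
  da <- differential_abundance(clr, sd_$exposure, fl$da_eligible)
  hits <- da$feature_id[da$significant]
  expect_true(all(c("taxon_002", "taxon_007") %in% hits))
  # direction: CLR mean difference carries the planted sign
  # (group 1 is Sham by sample order; taxon_002 is up in CIH, taxon_007 down)
  d2 <- da[da$feature_id == "taxon_002", ]
  d7 <- da[da$feature_id == "taxon_007", ]
  expect_lt(d2$mean_1, d2$mean_2)
  expect_gt(d7$mean_1, d7$mean_2)
  expect_true(all(da$q >= da$p - 1e-12))
  # empty eligibility gives an empty result, not an error
  none <- differential_abundance(clr, sd_$exposure,
                                 rep(FALSE, nrow(clr)))
  expect_equal(nrow(none), 0)
})

test_that("module aggregation applies the median-over-steps coverage rule", {
  m <- matrix(c(1, 3, 10, 0, 4,
                2, 0, 10, 0, 0), 5, 2,
              dimnames = list(c("K00001", "K00002", "K00003", "K00004",
                                "K00005"), c("s1", "s2")))
  ct <- count_table(m)
  # module of 2 steps: step sums 4 (K1+K2) and 10 (K3) in s1 -> median 7
  defs <- list(list(module_id = "MGB001", name = "two-step",
                    steps = list(c("K00001", "K00002"), "K00003")))
  ag <- aggregate_modules(ct, defs)
  expect_equal(ag$abundance["MGB001", "s1"], 7)
  expect_equal(ag$coverage["MGB001", "s1"], 1.0)
  # 3 steps with one zero: coverage 2/3 >= 0.66 -> median of the three
  defs3 <- list(list(module_id = "MGB002", name = "three-step",
                     steps = list("K00001", "K00003", "K00004")))
  ag3 <- aggregate_modules(ct, defs3)
  expect_equal(ag3$coverage["MGB002", "s1"], 2 / 3, tolerance = 1e-9)
  expect_equal(ag3$abundance["MGB002", "s1"], median(c(1, 10, 0)))
  # below coverage: zero abundance; absent KOs give (0, 0)
  defs0 <- list(list(module_id = "MGB004", name = "sparse",
                     steps = list("K00002", "K00004", "K00005")))
  ag0 <- aggregate_modules(ct, defs0)
  expect_equal(ag0$coverage["MGB004", "s2"], 0)   # all steps zero in s2
  expect_equal(ag0$abundance["MGB004", "s2"], 0)
  defsx <- list(list(module_id = "MGB003", name = "absent",
                     steps = list("K99999")))
  agx <- aggregate_modules(ct, defsx)
  expect_equal(agx$abundance["MGB003", "s1"], 0)
  expect_equal(agx$coverage["MGB003", "s1"], 0)
})
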