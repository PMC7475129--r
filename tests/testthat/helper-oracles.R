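# independent oracles used across test files

# step-up BH by direct definition: reject the largest k with p_(k) <= k q / m;
# q-values by the textbook min-over-tail formula
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rejected <- rep(FALSE, m)
  if (length(k)) rejected[o[seq_len(max(k))]] <- TRUE
  qv <- numeric(m)
  for (i in seq_len(m)) qv[i] <- min(1, min(ps[i:m] * m / (i:m)))
  q_sorted <- numeric(m)
  q_sorted[o] <- qv
  list(q_values = q_sorted, rejected = rejected)
}

# closed-form lagged-pair Poincare oracle (population variance)
poincare_oracle <- function(x, lag = 1) {
  a <- x[seq_len(length(x) - lag)]
  b <- x[(1 + lag):length(x)]
  pv <- function(v) mean((v - mean(v))^2)
  c(SD1 = sqrt(pv(a - b) / 2), SD2 = sqrt(pv(a + b) / 2))
}

# exhaustive PERMANOVA p by enumerating ALL n! label permutations (small n)
permanova_enum_oracle <- function(x, labels) {
  d2 <- as.matrix(dist(x))^2
  f_of <- function(ls) {
    n <- length(ls)
    g <- length(unique(ls))
    sst <- sum(d2) / (2 * n)
    ssw <- 0
    for (gg in unique(ls)) {
      idx <- which(ls == gg)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((sst - ssw) / (g - 1)) / (ssw / (n - g))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  f_obs <- f_of(labels)
  fs <- vapply(perms(seq_along(labels)),
               function(ix) f_of(labels[ix]), numeric(1))
  mean(fs >= f_obs - 1e-12)
}

# standard planted-event fixture: 10 min trace, known sighs and apnoeas
planted_trace <- function(seed, noise_sd = 0.02, duration_s = 600) {
  sim_protocol(
    duration_s = duration_s, f_R = 80, V_T = 2.1, noise_sd = noise_sd,
    sigh_times = c(100, 250, 480), sigh_gain = 2.5,
    apnoea_specs = list(
      list(onset_s = 150, duration_ttot = 3.5, post_sigh = FALSE),
      list(onset_s = 320, duration_ttot = 4.0, post_sigh = TRUE),
      list(onset_s = 540, duration_ttot = 3.2, post_sigh = FALSE)),
    seed = seed)
}

# match detected events to planted log entries by onset proximity
event_scores <- function(detected_onsets, planted_onsets, tol_s = 0.75) {
  tp <- 0
  used <- rep(FALSE, length(planted_onsets))
  for (o in detected_onsets) {
    d <- abs(planted_onsets - o)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      tp <- tp + 1
      used[j] <- TRUE
    }
  }
  c(precision = if (length(detected_onsets)) tp / length(detected_onsets) else 1,
    recall = if (length(planted_onsets)) tp / length(planted_onsets) else 1)
}
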