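# Independent brute-force oracles used by the unit and acceptance tests.
# These are written from first principles and never call the package code
# paths they check.

# One-way PERMANOVA pseudo-F from the pairwise-distance identity:
# SS_total = sum_{i<j} d_ij^2 / n, SS_within = sum_groups sum_{i<j in g} d^2 / n_g.
oneway_pseudo_f <- function(dmat, groups) {
  n <- nrow(dmat)
  ss_total <- sum(dmat[upper.tri(dmat)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- dmat[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  a <- length(unique(groups))
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# Exact one-way PERMANOVA p-value by enumerating every relabeling.
oneway_exact_p <- function(dmat, groups) {
  f_obs <- oneway_pseudo_f(dmat, groups)
  n <- nrow(dmat)
  g1 <- sum(groups == unique(groups)[1])
  combos <- utils::combn(n, g1)
  f_all <- apply(combos, 2, function(idx) {
    g <- rep("b", n)
    g[idx] <- "a"
    oneway_pseudo_f(dmat, g)
  })
  mean(f_all >= f_obs - 1e-12)
}

# One-way ANOVA F on scalar responses (used for PERMDISP label enumeration).
oneway_anova_f <- function(z, groups) {
  grand <- mean(z)
  ssb <- sum(tapply(z, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(z, groups, function(v) sum((v - mean(v))^2)))
  a <- length(unique(groups))
  (ssb / (a - 1)) / (ssw / (length(z) - a))
}

# Exact Mann-Whitney two-sided p by enumerating group assignments of the
# pooled values (no ties assumed).
mw_exact_p <- function(x, y) {
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(x, y)
  pooled <- c(x, y)
  n <- length(pooled)
  combos <- utils::combn(n, length(x))
  u_all <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- length(x) * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# BH step-up decision rule: reject the k* smallest p-values where k* is the
# largest k with p_(k) <= k * alpha / m.
bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ks <- which(ps <= seq_len(m) * alpha / m)
  reject <- rep(FALSE, m)
  if (length(ks) > 0) reject[ord[seq_len(max(ks))]] <- TRUE
  reject
}

# Efron-corrected Cox partial log-likelihood with delayed entry, one
# covariate vector, written directly from the definition.
efron_loglik <- function(beta, entry, time, event, x) {
  eta <- x * beta
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(entry < t & time >= t)
    d <- length(dead)
    sum_risk <- sum(exp(eta[risk]))
    sum_dead <- sum(exp(eta[dead]))
    ll <- ll + sum(eta[dead])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_risk - (l / d) * sum_dead)
    }
  }
  ll
}

soft_threshold <- function(b, lambda) sign(b) * pmax(abs(b) - lambda, 0)
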