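make_dist <- function(points) {
  stats::dist(points)
}

test_that("PCoA recovers collinear configurations and the Gower identity", {
  pts <- matrix(c(0, 1, 2, 3), ncol = 1)
  ord <- pcoa(make_dist(pts))
  expect_equal(ord$percent_var[1], 100)
  # axis 1 is the line up to sign/translation
  ax <- ord$points$Axis.1
  expect_equal(abs(cor(ax, pts[, 1])), 1)

  # Euclidean-embeddable D: recovered coordinates reproduce D exactly
  set.seed(8)
  pts3 <- matrix(rnorm(18), ncol = 3)
  d <- make_dist(pts3)
  ord3 <- pcoa(d)
  coords <- as.matrix(ord3$points[, -1])
  expect_equal(unname(as.matrix(stats::dist(coords))), unname(as.matrix(d)),
               tolerance = 1e-8)
  expect_lte(sum(ord3$percent_var), 100 + 1e-8)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), "symmetric")
})

test_that("PERMANOVA gives R2 = 1 when groups are perfectly separated", {
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  data <- data.frame(g = c("a", "a", "b", "b"))
  res <- permanova(stats::as.dist(d), data, ~ g, n_perm = 30, seed = 1)
  expect_equal(res$table$r2[res$table$term == "g"], 1)
})

test_that("PERMANOVA F and exact p match full-enumeration oracles", {
  set.seed(12)
  pts <- matrix(rnorm(12), ncol = 2)
  dmat <- as.matrix(make_dist(pts))
  groups <- rep(c("a", "b"), each = 3)
  data <- data.frame(g = groups)

  # all 720 row permutations
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  res <- permanova(stats::as.dist(dmat), data, ~ g, permutations = perms)

  f_oracle <- oneway_pseudo_f(dmat, groups)
  expect_equal(res$table$f[1], f_oracle)
  # (1 + b)/(1 + 720) over all perms equals the exact enumeration fraction
  expect_equal(res$table$p[1], oneway_exact_p(dmat, groups))
})

test_that("PERMANOVA pseudo-F equals classical ANOVA F on Euclidean data", {
  set.seed(13)
  y <- rnorm(18) + rep(c(0, 1, 3), each = 6)
  g <- factor(rep(c("a", "b", "c"), each = 6))
  res <- permanova(stats::dist(y), data.frame(g = g), ~ g, n_perm = 10, seed = 2)
  f_aov <- summary(aov(y ~ g))[[1]]["g", "F value"]
  expect_equal(res$table$f[1], f_aov, tolerance = 1e-10)
})

test_that("sequential decomposition matches vegan::adonis2 term by term", {
  co <- shared_cohort(n_per_cell = 2)
  rel <- relative_abundance(co$counts)
  d <- bray_curtis(rel)
  md <- as.data.frame(co$design)
  res <- permanova(d, md, ~ site + sex + treatment + site:treatment,
                   n_perm = 30, seed = 4)
  ref <- vegan::adonis2(d ~ site + sex + treatment + site:treatment,
                        data = md, permutations = 30, by = "terms")
  terms <- c("site", "sex", "treatment", "site:treatment")
  ours <- res$table[match(terms, res$table$term), ]
  expect_equal(ours$ss, ref[terms, "SumOfSqs"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ours$f, ref[terms, "F"], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(ours$r2, ref[terms, "R2"], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("R2 sums to one, p stays off zero, and seeds reproduce p-values", {
  set.seed(14)
  pts <- matrix(rnorm(40), ncol = 2)
  data <- data.frame(g = rep(c("a", "b"), each = 10),
                     h = rep(c("x", "y"), times = 10))
  d <- make_dist(pts)
  res <- permanova(d, data, ~ g + h, n_perm = 99, seed = 5)
  expect_equal(sum(res$table$r2[res$table$term != "Total"]), 1)
  expect_true(all(res$table$p[1:2] >= 1 / 100))
  res2 <- permanova(d, data, ~ g + h, n_perm = 99, seed = 5)
  expect_identical(res$table$p, res2$table$p)
  expect_error(permanova(d, data.frame(g = rep("a", 20)), ~ g, n_perm = 9),
               "g")
})

test_that("PERMANOVA p-values are uniform under a null of shuffled labels", {
  set.seed(15)
  rejections <- vapply(1:120, function(i) {
    pts <- matrix(rnorm(24), ncol = 2)
    data <- data.frame(g = sample(rep(c("a", "b"), each = 6)))
    res <- permanova(stats::dist(pts), data, ~ g, n_perm = 59, seed = i)
    res$table$p[1] <= 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.0)
  expect_lte(mean(rejections), 0.13)  # 3 binomial SDs around 0.05 at n=120
})

test_that("PERMDISP distances, F, and exact p behave as constructed", {
  # mirror-image groups: identical internal geometry, F exactly 0
  g1 <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  g2 <- g1 + 10
  d <- make_dist(rbind(g1, g2))
  groups <- rep(c("a", "b"), each = 3)
  res <- permdisp(d, groups, n_perm = 30, seed = 1)
  expect_equal(res$f, 0, tolerance = 1e-10)
  expect_equal(res$p, 1)

  # one tight, one dispersed group: detected
  set.seed(16)
  tight <- matrix(rnorm(40, sd = 0.2), ncol = 2)
  loose <- matrix(rnorm(40, sd = 3), ncol = 2)
  d2 <- make_dist(rbind(tight, loose))
  res2 <- permdisp(d2, rep(c("t", "l"), each = 20), n_perm = 199, seed = 2)
  expect_lt(res2$p, 0.01)

  # exact enumeration on 3+3 matches a brute-force label enumeration
  set.seed(17)
  pts <- matrix(rnorm(12), ncol = 2)
  d3 <- make_dist(pts)
  groups3 <- rep(c("a", "b"), each = 3)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  res3 <- permdisp(d3, groups3, permutations = perms)
  z <- res3$distances$distance
  f_obs <- oneway_anova_f(z, groups3)
  combos <- utils::combn(6, 3)
  f_all <- apply(combos, 2, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    oneway_anova_f(z, g)
  })
  expect_equal(res3$f, f_obs)
  expect_equal(res3$p, mean(f_all >= f_obs - 1e-12))

  expect_error(permdisp(d3, c("a", rep("b", 5))), "at least 2")
})

test_that("PERMDISP centroid distances agree with vegan::betadisper", {
  co <- shared_cohort(n_per_cell = 2)
  rel <- relative_abundance(co$counts)
  d <- bray_curtis(rel)
  res <- permdisp(d, co$design$treatment, n_perm = 30, seed = 3)
  ref <- vegan::betadisper(d, co$design$treatment, type = "centroid")
  expect_equal(unname(res$distances$distance), unname(ref$distances),
               tolerance = 1e-8)
})
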