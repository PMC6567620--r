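as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) return(as.matrix(d))
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort("`d` must be a symmetric dissimilarity matrix or `dist` object")
  }
  if (any(abs(diag(m)) > 1e-8)) abort("`d` must have a zero diagonal")
  m
}

gower_center <- function(m) {
  n <- nrow(m)
  a <- -0.5 * m^2
  cc <- diag(n) - matrix(1 / n, n, n)
  cc %*% a %*% cc
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the double-centered (Gower) matrix of squared
#' dissimilarities. Axes are ordered by eigenvalue; the percent variance of
#' each axis is its eigenvalue over the sum of positive eigenvalues. Negative
#' eigenvalues (non-Euclidean dissimilarities) are reported, not corrected.
#'
#' @param d symmetric dissimilarity matrix or `dist` object.
#' @return list of class `mb_pcoa`: `points` (tibble, `sample_id` plus
#'   `Axis.1`, `Axis.2`, ... for positive eigenvalues), `eigenvalues`,
#'   `percent_var`.
#' @export
pcoa <- function(d) {
  m <- as_dist_matrix(d)
  g <- gower_center(m)
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-8
  pos <- eig$values > tol
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]),
                                                      nrow = sum(pos))
  colnames(coords) <- paste0("Axis.", seq_len(ncol(coords)))
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  pts <- dplyr::bind_cols(tibble(sample_id = ids),
                          as_tibble(as.data.frame(coords)))
  structure(list(points = pts, eigenvalues = eig$values,
                 percent_var = 100 * eig$values[pos] / sum(eig$values[pos])),
            class = "mb_pcoa")
}

seq_hats <- function(formula, data) {
  labels <- attr(terms(formula), "term.labels")
  if (length(labels) == 0) abort("the model must contain at least one term")
  n <- nrow(data)
  hats <- list(matrix(1 / n, n, n))  # intercept-only projector
  ranks <- 1L
  for (k in seq_along(labels)) {
    mm <- tryCatch(model.matrix(stats::reformulate(labels[seq_len(k)]), data),
                   error = function(e) {
                     abort(paste0("term `", labels[k],
                                  "` adds no variation to the model"))
                   })
    qq <- qr(mm)
    if (qq$rank <= ranks[length(ranks)]) {
      abort(paste0("term `", labels[k], "` adds no variation to the model"))
    }
    q_mat <- qr.Q(qq)[, seq_len(qq$rank), drop = FALSE]
    hats[[k + 1]] <- tcrossprod(q_mat)
    ranks <- c(ranks, qq$rank)
  }
  list(labels = labels, hats = hats, ranks = ranks)
}

permanova_ss <- function(g, hats) {
  vapply(hats, function(h) sum(h * g), numeric(1))
}

#' PERMANOVA with sequential sums of squares
#'
#' Multivariate analysis of variance on a dissimilarity matrix via the
#' partition of the Gower-centered matrix by the projection (hat) operators
#' of a sequential (Type I) model. For each term the pseudo-F statistic is
#' `(SS_term / df_term) / (SS_residual / df_residual)` and its p-value comes
#' from free permutation of the sample rows of the dissimilarity matrix,
#' using the convention `p = (1 + b) / (1 + m)` where `b` counts permuted
#' statistics at least as extreme, so the observed statistic is always a
#' member of its own null set.
#'
#' @param d dissimilarity `dist` or symmetric matrix; rows in the order of
#'   `data`.
#' @param data data frame of design variables.
#' @param formula right-hand-side formula of sequential terms, e.g.
#'   `~ site + sex + treatment + site:treatment`.
#' @param n_perm number of random permutations (ignored if `permutations`
#'   given).
#' @param seed integer seed for the permutation draw.
#' @param permutations optional integer matrix, one permutation of
#'   `1:n` per row, used instead of random draws (enables exact enumeration).
#' @return object of class `mb_permanova`: tibble with one row per term plus
#'   `Residual` and `Total` rows, with `df`, `ss`, `r2`, `f`, `p`.
#' @export
permanova <- function(d, data, formula, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  if (nrow(data) != n) abort("`data` rows must match the dissimilarity matrix")
  g <- gower_center(m)
  sh <- seq_hats(formula, data)
  nterm <- length(sh$labels)
  ss_cum <- permanova_ss(g, sh$hats)
  ss_total <- sum(diag(g))
  ss_term <- diff(ss_cum)
  df_term <- diff(sh$ranks)
  ss_res <- ss_total - ss_cum[nterm + 1]
  df_res <- n - sh$ranks[nterm + 1]
  if (df_res <= 0) abort("model saturates the data; no residual degrees of freedom")
  f_obs <- (ss_term / df_term) / (ss_res / df_res)

  # With random draws the observed statistic joins its own null set:
  # p = (1 + b) / (1 + m). A user-supplied matrix is treated as the complete
  # null set (exact enumeration), so p is the plain exceedance fraction.
  exact_set <- !is.null(permutations)
  if (!exact_set) {
    permutations <- with_seed(seed, t(replicate(n_perm, sample.int(n))))
  }
  n_used <- nrow(permutations)
  exceed <- numeric(nterm)
  for (b in seq_len(n_used)) {
    p <- permutations[b, ]
    gp <- g[p, p]
    ss_cum_p <- permanova_ss(gp, sh$hats)
    ss_term_p <- diff(ss_cum_p)
    ss_res_p <- ss_total - ss_cum_p[nterm + 1]
    f_p <- (ss_term_p / df_term) / (ss_res_p / df_res)
    exceed <- exceed + (f_p >= f_obs - 1e-12)
  }
  pvals <- if (exact_set) exceed / n_used else (1 + exceed) / (1 + n_used)

  res <- dplyr::bind_rows(
    tibble(term = sh$labels, df = df_term, ss = ss_term,
           r2 = ss_term / ss_total, f = f_obs, p = pvals),
    tibble(term = "Residual", df = df_res, ss = ss_res, r2 = ss_res / ss_total,
           f = NA_real_, p = NA_real_),
    tibble(term = "Total", df = n - 1L, ss = ss_total, r2 = 1,
           f = NA_real_, p = NA_real_))
  structure(list(table = res, n = n, n_perm = n_used, formula = formula),
            class = "mb_permanova")
}

#' @export
print.mb_permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS,", x$n_perm, "permutations)\n")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Distances to group centroids in PCoA space
#'
#' Embeds the dissimilarity matrix by PCoA keeping all axes, and computes
#' each sample's distance to its group centroid as the square root of the
#' positive part of (squared real-axis distance minus squared
#' imaginary-axis distance), the standard correction for non-Euclidean
#' dissimilarities.
#' @noRd
centroid_distances <- function(m, groups) {
  g <- gower_center(m)
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-8
  pos <- eig$values > tol
  neg <- eig$values < -tol
  xr <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]), nrow = sum(pos))
  xi <- eig$vectors[, neg, drop = FALSE] %*% diag(sqrt(-eig$values[neg]), nrow = sum(neg))
  z2 <- numeric(nrow(m))
  for (gr in unique(groups)) {
    idx <- groups == gr
    cr <- colMeans(xr[idx, , drop = FALSE])
    d_r <- rowSums(sweep(xr[idx, , drop = FALSE], 2, cr)^2)
    d_i <- 0
    if (ncol(xi) > 0) {
      ci <- colMeans(xi[idx, , drop = FALSE])
      d_i <- rowSums(sweep(xi[idx, , drop = FALSE], 2, ci)^2)
    }
    z2[idx] <- d_r - d_i
  }
  sqrt(pmax(z2, 0))
}

#' PERMDISP: test of multivariate homogeneity of group dispersions
#'
#' Each sample's distance to its group centroid is computed in the full PCoA
#' embedding (imaginary-axis contribution subtracted); the test statistic is
#' the one-way ANOVA F on those distances, with significance assessed by
#' permuting group labels across the distances. Group centroids (not spatial
#' medians) are used.
#'
#' @param d dissimilarity `dist` or symmetric matrix.
#' @param groups factor-like group labels, one per sample.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param permutations optional permutation matrix (rows are permutations of
#'   `1:n`) for exact enumeration.
#' @return object of class `mb_permdisp` with `distances` tibble, `f`, `p`.
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = NULL, permutations = NULL) {
  m <- as_dist_matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) abort("`groups` must match the dissimilarity matrix")
  tab <- table(groups)
  if (length(tab) < 2) abort("need at least two groups")
  if (any(tab < 2)) {
    abort(paste0("every group needs at least 2 samples; too small: ",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  z <- centroid_distances(m, groups)
  anova_f <- function(z, groups) {
    grand <- mean(z)
    ssb <- sum(tapply(z, groups, function(v) length(v) * (mean(v) - grand)^2))
    ssw <- sum(tapply(z, groups, function(v) sum((v - mean(v))^2)))
    dfb <- length(unique(groups)) - 1
    dfw <- length(z) - length(unique(groups))
    (ssb / dfb) / (ssw / dfw)
  }
  f_obs <- anova_f(z, groups)
  exact_set <- !is.null(permutations)
  if (!exact_set) {
    permutations <- with_seed(seed, t(replicate(n_perm, sample.int(length(z)))))
  }
  f_perm <- apply(permutations, 1, function(p) anova_f(z, groups[p]))
  b <- sum(f_perm >= f_obs - 1e-12)
  p <- if (exact_set) b / length(f_perm) else (1 + b) / (1 + length(f_perm))
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_along(z))
  structure(list(distances = tibble(sample_id = ids, group = groups, distance = z),
                 f = f_obs, p = p, n_perm = nrow(permutations)),
            class = "mb_permdisp")
}

#' @export
print.mb_permdisp <- function(x, ...) {
  cat("PERMDISP: F =", format(x$f, digits = 4), ", p =", format(x$p, digits = 4),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}
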