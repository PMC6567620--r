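#' Spearman rank correlation with Student-t p-value
#'
#' Pearson correlation of mid-ranks, with the two-sided p-value from the
#' Student-t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n at least 4.
#' @return tibble with `rho`, `p`, `n`.
#' @export
spearman_with_t <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: Spearman correlation undefined")
    return(tibble(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, p = p, n = n)
}

#' Adjust a response for design covariates
#'
#' Residuals of an ordinary least-squares fit of the response on the design
#' factors (site, sex, treatment by default); the residuals are orthogonal to
#' every design column.
#'
#' @param y numeric response (e.g. log metabolite concentration).
#' @param data data frame holding the design variables.
#' @param formula right-hand-side design formula.
#' @return numeric residual vector.
#' @export
residualize <- function(y, data, formula = ~ site + sex + treatment) {
  mm <- model.matrix(formula, data)
  fit <- stats::lm.fit(mm, y)
  if (any(is.na(fit$coefficients))) {
    abort(paste0("rank-deficient design; aliased: ",
                 paste(names(fit$coefficients)[is.na(fit$coefficients)], collapse = ", ")))
  }
  unname(fit$residuals)
}

lasso_path_fit <- function(x, y, lambda) {
  glmnet::glmnet(x, y, family = "gaussian", alpha = 1, lambda = lambda,
                 standardize = FALSE, intercept = TRUE, thresh = 1e-10)
}

#' LASSO regression with randomized cross-validation and an out-of-bag gate
#'
#' Standardizes the predictor columns, builds a 100-point log-spaced penalty
#' grid from `lambda_max` (the smallest penalty with an all-zero solution)
#' down to `lambda_max * 1e-4`, assigns samples to `n_folds` random folds,
#' and picks the penalty maximizing the pooled out-of-bag R-squared
#' (1 - SSE/SST over all held-out predictions). The final coefficients come
#' from a refit on all data at the chosen penalty. The model is "validated"
#' when the Spearman rank correlation between observed responses and
#' out-of-bag predictions is positive and significant at p < 0.05 (Student-t
#' approximation); the sign requirement keeps the mechanical anti-correlation
#' of fold-mean predictions from counting as predictive ability.
#'
#' @param x numeric matrix or data frame of predictors (e.g. spike-adjusted
#'   OTU abundances); zero-variance columns are dropped with a warning.
#' @param y numeric response (already design-adjusted).
#' @param n_folds number of cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @return object of class `mb_lasso` with `coefficients` (tibble of the
#'   non-zero terms on the standardized-predictor scale), `lambda`,
#'   `oob_r2`, `oob_rho`, `oob_p`, `validated`, `oob_predictions`.
#' @export
lasso_cv <- function(x, y, n_folds = 10, seed = NULL) {
  x <- as.matrix(as.data.frame(x))
  n <- nrow(x)
  if (n <= n_folds) abort("need more samples than folds")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping ", sum(sds == 0), " zero-variance predictor column(s)"))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(x) < 2) abort("need at least two varying predictors")
  xs <- scale(x)
  lambda_max <- max(abs(crossprod(xs, y - mean(y)))) / n
  grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = 100))
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  oob <- matrix(NA_real_, nrow = n, ncol = length(grid))
  for (f in seq_len(n_folds)) {
    hold <- folds == f
    fit <- lasso_path_fit(xs[!hold, , drop = FALSE], y[!hold], grid)
    oob[hold, ] <- predict(fit, newx = xs[hold, , drop = FALSE])
  }
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - colSums((oob - y)^2) / sst
  best <- which.max(r2)
  final <- lasso_path_fit(xs, y, grid)
  beta <- as.matrix(coef(final))[, best]
  nz <- beta[beta != 0 & names(beta) != "(Intercept)"]
  gate <- if (sd(oob[, best]) == 0) {
    tibble(rho = NA_real_, p = NA_real_, n = n)
  } else {
    spearman_with_t(y, oob[, best])
  }
  # validation requires a *positive* significant rank correlation: held-out
  # predictions of an all-zero model are fold means of the training response,
  # which are mechanically anti-correlated with the held-out values, and that
  # artifact must not count as predictive ability
  structure(list(coefficients = tibble(otu = names(nz), coefficient = unname(nz)),
                 lambda = grid[best], lambda_grid = grid, oob_r2 = r2[best],
                 oob_r2_path = r2, oob_rho = gate$rho, oob_p = gate$p,
                 validated = isTRUE(gate$p < 0.05 && gate$rho > 0),
                 oob_predictions = oob[, best], folds = folds,
                 beta_full = beta, x_center = attr(xs, "scaled:center"),
                 x_scale = attr(xs, "scaled:scale")),
            class = "mb_lasso")
}

#' @export
print.mb_lasso <- function(x, ...) {
  cat("LASSO (10-fold CV): lambda =", format(x$lambda, digits = 4),
      ", OOB R2 =", format(x$oob_r2, digits = 3),
      ", OOB Spearman rho =", format(x$oob_rho, digits = 3),
      ", p =", format(x$oob_p, digits = 3),
      if (x$validated) "[validated]" else "[not validated]", "\n")
  cat(nrow(x$coefficients), "selected predictors\n")
  invisible(x)
}

#' OTU-level LASSO prediction of metabolite concentrations
#'
#' Filters OTUs to those detected in more than `min_incidence` of samples
#' with mean relative abundance above `min_mean_rel`, adjusts the
#' log-transformed metabolite concentration for site, sex, and treatment,
#' and runs [lasso_cv()] on the spike-adjusted abundances of the retained
#' OTUs. Samples whose spike-adjusted abundance is undefined are dropped.
#'
#' @param abund wide spike-adjusted OTU abundance tibble.
#' @param counts wide count tibble (used for the incidence and mean
#'   relative-abundance filters).
#' @param panel metabolite panel (sample id column first).
#' @param metadata design metadata (site, sex, treatment).
#' @param targets metabolites to model.
#' @param n_folds,seed passed to [lasso_cv()].
#' @param min_mean_rel,min_incidence OTU inclusion filters.
#' @return named list of `mb_lasso` objects, one per target metabolite.
#' @export
taxon_metabolite_lasso <- function(abund, counts, panel, metadata,
                                   targets = c("propionate", "butyrate",
                                               "acetate", "lactate"),
                                   n_folds = 10, seed = NULL,
                                   min_mean_rel = 1e-4, min_incidence = 0.05) {
  am <- split_id_matrix(abund, "abund")
  cm <- split_id_matrix(counts, "counts")
  rel <- sweep(cm$mat, 1, rowSums(cm$mat), `/`)
  pass <- colMeans(rel) > min_mean_rel & colMeans(cm$mat >= 1) > min_incidence
  otus <- intersect(names(pass)[pass], colnames(am$mat))
  seeds <- derive_seeds(if (is.null(seed)) 1 else seed, length(targets))
  out <- purrr::map(seq_along(targets), function(i) {
    m <- targets[i]
    common <- Reduce(intersect, list(am$ids, panel[[1]], metadata[[am$id_name]]))
    xmat <- am$mat[match(common, am$ids), otus, drop = FALSE]
    keep <- stats::complete.cases(xmat)
    common <- common[keep]
    xmat <- xmat[keep, , drop = FALSE]
    conc <- panel[[m]][match(common, panel[[1]])]
    md <- metadata[match(common, metadata[[am$id_name]]), ]
    yadj <- residualize(zero_replace_log(conc), md)
    lasso_cv(xmat, yadj, n_folds = n_folds, seed = seeds[i])
  })
  names(out) <- targets
  out
}

#' Family-level Spearman correlations with metabolites, within strata
#'
#' Spearman rho (Student-t p) for every family x metabolite pair, computed
#' separately inside each stratum (by default the treatment groups), so that
#' correlations induced purely by between-stratum offsets vanish.
#'
#' @param family_abund wide family-level abundance tibble.
#' @param panel metabolite panel (sample id column first).
#' @param metadata data frame with the stratum columns.
#' @param strata character vector of metadata columns defining strata.
#' @param min_n strata smaller than this are skipped with a warning.
#' @return tibble with `stratum`, `family`, `metabolite`, `rho`, `p`, `n`.
#' @export
family_metabolite_correlations <- function(family_abund, panel, metadata,
                                           strata = "treatment", min_n = 4) {
  fm <- split_id_matrix(family_abund, "family_abund")
  common <- Reduce(intersect, list(fm$ids, panel[[1]], metadata[[fm$id_name]]))
  fmat <- fm$mat[match(common, fm$ids), , drop = FALSE]
  pan <- panel[match(common, panel[[1]]), ]
  md <- metadata[match(common, metadata[[fm$id_name]]), ]
  stratum <- do.call(paste, c(as.list(md[strata]), sep = "/"))
  metabs <- setdiff(names(pan), names(pan)[1])
  rows <- list()
  for (s in unique(stratum)) {
    idx <- which(stratum == s & stats::complete.cases(fmat))
    if (length(idx) < min_n) {
      warn(paste0("stratum ", s, " has fewer than ", min_n, " samples; skipped"))
      next
    }
    for (fam in colnames(fmat)) {
      for (m in metabs) {
        r <- suppressWarnings(spearman_with_t(fmat[idx, fam], pan[[m]][idx]))
        rows[[length(rows) + 1]] <- tibble(stratum = s, family = fam,
                                           metabolite = m, rho = r$rho,
                                           p = r$p, n = r$n)
      }
    }
  }
  dplyr::bind_rows(rows)
}
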