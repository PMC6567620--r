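#' Mann-Whitney U test
#'
#' `U = #{(i, j): x_i > y_j} + 0.5 #{ties}`. The two-sided p-value is exact
#' (by enumeration of all group assignments) when the combined sample size is
#' at most 12 and there are no ties; otherwise the normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return tibble with `u`, `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(u = unname(wt$statistic), p = wt$p.value,
         method = if (exact) "exact" else "normal approximation")
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's size factor is the median across
#' reference OTUs of the ratio of its count to the geometric mean of that
#' OTU's counts. Reference OTUs are those with strictly positive counts in
#' every sample; if none exist, geometric means over positive counts only are
#' used, with a notice.
#'
#' @param mat sample x OTU count matrix.
#' @return numeric vector of size factors (geometric mean 1 scaling is not
#'   imposed; medians of ratios are used directly).
#' @export
size_factors <- function(mat) {
  all_pos <- colSums(mat > 0) == nrow(mat)
  if (any(all_pos)) {
    ref <- mat[, all_pos, drop = FALSE]
    log_gm <- colMeans(log(ref))
    sf <- apply(ref, 1, function(r) exp(median(log(r) - log_gm)))
  } else {
    inform("no OTU is positive in every sample; using positive-count geometric means")
    log_gm <- apply(mat, 2, function(col) {
      pos <- col > 0
      if (!any(pos)) return(NA_real_)
      mean(log(col[pos]))
    })
    usable <- !is.na(log_gm)
    if (!any(usable)) abort("no OTU usable for size factors")
    sf <- apply(mat, 1, function(r) {
      idx <- usable & r > 0
      if (!any(idx)) return(NA_real_)
      exp(median(log(r[idx]) - log_gm[idx]))
    })
    if (anyNA(sf)) abort("some samples share no positive OTU with the reference")
  }
  sf
}

#' Per-OTU negative-binomial Wald tests
#'
#' For every OTU detected in at least two samples, fits a negative-binomial
#' log-linear model of counts on the design (default
#' `~ site + sex + treatment + sex:treatment`) with log size-factor offsets.
#' The per-OTU dispersion is a method-of-moments estimate with a small floor
#' (no empirical-Bayes shrinkage), and each coefficient's Wald z statistic is
#' its estimate over its standard error.
#'
#' @param counts wide count tibble (sample id column first).
#' @param metadata data frame aligned by the sample id column, carrying the
#'   design variables.
#' @param formula design formula (right-hand side).
#' @param dispersion_floor lower bound on the method-of-moments dispersion.
#' @return tibble of class `mb_otu_tests`, one row per OTU per non-intercept
#'   coefficient: `otu`, `term`, `log2fc`, `stat`, `p`, plus per-OTU
#'   `mean_rel_abund` and `incidence`.
#' @export
nb_wald_test <- function(counts, metadata,
                         formula = ~ site + sex + treatment + sex:treatment,
                         dispersion_floor = 1e-8) {
  cm <- split_id_matrix(counts, "counts")
  md <- metadata[match(cm$ids, metadata[[cm$id_name]]), ]
  if (any(is.na(md[[cm$id_name]]))) abort("samples in `counts` missing from `metadata`")
  for (v in all.vars(formula)) {
    if (is.character(md[[v]]) || is.factor(md[[v]])) md[[v]] <- design_factor(md[[v]])
  }
  cell <- do.call(interaction, as.list(md[all.vars(formula)]))
  if (min(table(cell)) < 2) abort("need at least 2 samples per design cell")
  sf <- size_factors(cm$mat)
  rel <- sweep(cm$mat, 1, rowSums(cm$mat), `/`)
  mean_rel <- colMeans(rel)
  incidence <- colMeans(cm$mat >= 1)
  usable <- colSums(cm$mat > 0) >= 2
  mm <- model.matrix(formula, md)
  res <- purrr::map(colnames(cm$mat)[usable], function(o) {
    k <- cm$mat[, o]
    y <- k / sf
    m <- mean(y)
    v <- var(y)
    alpha <- max((v - m * mean(1 / sf)) / m^2, dispersion_floor)
    fit <- tryCatch(
      suppressWarnings(
        stats::glm(k ~ 0 + mm + offset(log(sf)),
                   family = MASS::negative.binomial(theta = 1 / alpha))),
      error = function(e) NULL)
    if (is.null(fit)) {
      keep <- colnames(mm) != "(Intercept)"
      return(tibble(otu = o, term = colnames(mm)[keep], log2fc = NA_real_,
                    stat = NA_real_, p = NA_real_,
                    mean_rel_abund = mean_rel[[o]], incidence = incidence[[o]]))
    }
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    keep <- colnames(mm) != "(Intercept)"
    z <- est[keep] / se[keep]
    tibble(otu = o, term = colnames(mm)[keep],
           log2fc = unname(est[keep]) / log(2), stat = unname(z),
           p = 2 * pnorm(-abs(unname(z))),
           mean_rel_abund = mean_rel[[o]], incidence = incidence[[o]])
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("mb_otu_tests", class(out))
  out
}

#' Benjamini-Hochberg correction with independent filtering
#'
#' Applies the BH step-up procedure only to OTUs passing two filters that are
#' computed from abundance, never from the p-values: mean relative abundance
#' at least `min_mean_rel` and detection in at least `min_incidence` of
#' samples. Filtered-out ("rare") OTUs keep their raw p-value but get no
#' adjusted q, so the number of tests m is reduced without biasing the FDR.
#' When a `term` column is present the correction is applied within each
#' term.
#'
#' @param results tibble with columns `p`, `mean_rel_abund`, `incidence`
#'   (e.g. from [nb_wald_test()]).
#' @param min_mean_rel mean relative-abundance threshold (default 0.01%).
#' @param min_incidence incidence threshold (default 5% of samples).
#' @return the input with logical `tested` and numeric `q` columns added
#'   (`q` is `NA` for rare OTUs).
#' @export
filtered_bh <- function(results, min_mean_rel = 1e-4, min_incidence = 0.05) {
  if (anyNA(results$p)) abort("raw p-values must be present for every row")
  results$tested <- results$mean_rel_abund >= min_mean_rel &
    results$incidence >= min_incidence
  adjust_group <- function(df) {
    df$q <- NA_real_
    df$q[df$tested] <- p.adjust(df$p[df$tested], method = "BH")
    df
  }
  if ("term" %in% names(results)) {
    results <- results |>
      dplyr::group_by(.data$term) |>
      dplyr::group_modify(~ adjust_group(.x)) |>
      dplyr::ungroup() |>
      dplyr::relocate(dplyr::any_of(c("otu")), .before = 1)
  } else {
    results <- adjust_group(results)
  }
  results
}

#' Survey OTUs for treatment, sex, and interaction effects
#'
#' Convenience wrapper: runs the negative-binomial Wald stage and then the
#' independent-filtering BH correction.
#'
#' @inheritParams nb_wald_test
#' @inheritParams filtered_bh
#' @return tibble as from [filtered_bh()].
#' @export
otu_survey <- function(counts, metadata,
                       formula = ~ site + sex + treatment + sex:treatment,
                       min_mean_rel = 1e-4, min_incidence = 0.05) {
  res <- nb_wald_test(counts, metadata, formula)
  bad <- is.na(res$p)
  if (any(bad)) {
    warn(paste0(sum(bad), " OTU/term fits failed and were dropped"))
    res <- res[!bad, ]
  }
  filtered_bh(res, min_mean_rel = min_mean_rel, min_incidence = min_incidence)
}
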