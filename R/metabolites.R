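#' Fit an HPLC standard curve by weighted regression
#'
#' Weighted least squares of peak area on concentration with weights
#' `1 / concentration^2`, fitted without an intercept except where requested
#' (propionate). Without an intercept the weighted slope has the closed form
#' `mean(area_i / concentration_i)`.
#'
#' @param points data frame with columns `concentration` (mM, strictly
#'   positive) and `area`.
#' @param with_intercept fit an intercept (use `TRUE` for propionate).
#' @param compound optional compound label carried in the result.
#' @return object of class `mb_stdcurve` with `slope`, `intercept` (0 when
#'   not fitted), `compound`, `n`, `points`.
#' @export
fit_standard_curve <- function(points, with_intercept = FALSE, compound = NULL) {
  if (!all(c("concentration", "area") %in% names(points))) {
    abort("`points` needs `concentration` and `area` columns")
  }
  if (any(points$concentration <= 0)) {
    abort("standard concentrations must be strictly positive (weights are 1/c^2)")
  }
  n_min <- if (with_intercept) 2 else 1
  if (nrow(points) < n_min) abort("not enough standard points to fit the curve")
  w <- 1 / points$concentration^2
  fit <- if (with_intercept) {
    lm(area ~ concentration, data = points, weights = w)
  } else {
    lm(area ~ 0 + concentration, data = points, weights = w)
  }
  slope <- unname(coef(fit)[["concentration"]])
  intercept <- if (with_intercept) unname(coef(fit)[["(Intercept)"]]) else 0
  structure(list(compound = compound, slope = slope, intercept = intercept,
                 n = nrow(points), points = as_tibble(points),
                 with_intercept = with_intercept),
            class = "mb_stdcurve")
}

#' @export
print.mb_stdcurve <- function(x, ...) {
  cat("Standard curve", if (!is.null(x$compound)) paste0("(", x$compound, ")"),
      ": area =", format(x$slope, digits = 5), "x mM",
      if (x$with_intercept) paste("+", format(x$intercept, digits = 5)), "\n")
  invisible(x)
}

#' Concentration in feces from a peak area
#'
#' Converts a peak area to extract concentration via the standard curve
#' (`mM = (area - intercept) / slope`), then to micromoles per gram wet
#' feces using the extraction volume. The volume is either fixed
#' (`homogenization_volume_mL`, the 200 uL protocol variant) or proportional
#' to pellet weight (`weight_g * extraction_ratio` mL, the 1:10
#' weight:volume protocol). Areas below the intercept give negative nominal
#' concentrations, which are clamped to zero and flagged.
#'
#' @param area peak area(s), arbitrary units.
#' @param curve an `mb_stdcurve`.
#' @param pellet_weight_g pellet wet weight(s) in grams.
#' @param extraction_ratio volume:weight ratio in mL per g (default 10).
#' @param homogenization_volume_mL fixed extract volume in mL, overriding the
#'   ratio when given.
#' @return tibble with `mM` (extract), `umol_per_g`, and logical `clamped`.
#' @export
quantify <- function(area, curve, pellet_weight_g, extraction_ratio = 10,
                     homogenization_volume_mL = NULL) {
  if (!inherits(curve, "mb_stdcurve")) abort("`curve` must come from fit_standard_curve()")
  if (any(pellet_weight_g <= 0)) abort("`pellet_weight_g` must be strictly positive")
  mM <- (area - curve$intercept) / curve$slope
  clamped <- mM < 0
  if (any(clamped)) {
    warn(paste0(sum(clamped), " peak area(s) below the curve intercept; ",
                "concentration clamped to 0"))
    mM[clamped] <- 0
  }
  volume_mL <- if (is.null(homogenization_volume_mL)) {
    pellet_weight_g * extraction_ratio
  } else {
    rep(homogenization_volume_mL, length.out = length(mM))
  }
  tibble(mM = mM, umol_per_g = mM * volume_mL / pellet_weight_g,
         clamped = clamped)
}

#' Half-minimum zero replacement and log transform
#'
#' Replaces zeros with half the lowest detected (positive) value, then takes
#' the natural log. Errors if nothing was detected.
#'
#' @param x non-negative concentrations.
#' @return log-scale values.
#' @export
zero_replace_log <- function(x) {
  if (any(x < 0)) abort("concentrations must be non-negative")
  pos <- x[x > 0]
  if (length(pos) == 0) abort("all values are zero; nothing was detected")
  x[x == 0] <- min(pos) / 2
  log(x)
}

#' Total SCFA
#'
#' Adds a `total_scfa` column defined exactly as acetate + butyrate +
#' propionate.
#'
#' @param panel data frame with `acetate`, `butyrate`, `propionate` columns.
#' @return the panel with `total_scfa` appended.
#' @export
add_total_scfa <- function(panel) {
  need <- setdiff(c("acetate", "butyrate", "propionate"), names(panel))
  if (length(need) > 0) abort(paste0("panel lacks: ", paste(need, collapse = ", ")))
  dplyr::mutate(panel, total_scfa = .data$acetate + .data$butyrate + .data$propionate)
}

#' Interaction tests on log metabolite concentrations
#'
#' For each metabolite: (a) the treatment-by-site interaction F-test from an
#' ANOVA of log concentration on `site + sex + treatment + treatment:site`;
#' (b) a Gaussian likelihood-ratio test (chi-squared, 1 df, statistic
#' `n log(RSS_null / RSS_full)`) between nested linear models with and
#' without the `sex:treatment` interaction, with all other two-way
#' interactions retained in both models. Zeros are replaced with half the
#' minimum detected value before the log transform.
#'
#' @param panel data frame, sample id column first, metabolite concentration
#'   columns named in `metabolites`.
#' @param metadata data frame aligned by the sample id column with `site`,
#'   `sex`, `treatment`.
#' @param metabolites metabolite columns to test (default: every non-id
#'   column of `panel`).
#' @return tibble with `metabolite`, `treatment_site_F`, `treatment_site_p`,
#'   `sex_treatment_lrt`, `sex_treatment_p`.
#' @export
interaction_tests <- function(panel, metadata, metabolites = NULL) {
  id_name <- names(panel)[1]
  if (is.null(metabolites)) metabolites <- setdiff(names(panel), id_name)
  md <- metadata[match(panel[[id_name]], metadata[[id_name]]), ]
  for (v in c("site", "sex", "treatment")) {
    if (length(unique(md[[v]])) < 2) {
      abort(paste0("design variable `", v, "` has no variation"))
    }
  }
  purrr::map(metabolites, function(m) {
    df <- data.frame(y = zero_replace_log(panel[[m]]),
                     site = design_factor(md$site), sex = design_factor(md$sex),
                     treatment = design_factor(md$treatment))
    fit_a <- lm(y ~ site + sex + treatment + treatment:site, data = df)
    if (any(is.na(coef(fit_a)))) {
      abort(paste0("rank-deficient design for ", m, "; aliased: ",
                   paste(names(coef(fit_a))[is.na(coef(fit_a))], collapse = ", ")))
    }
    an <- anova(fit_a)
    irow <- grep(":", rownames(an))
    full <- lm(y ~ site + sex + treatment + site:treatment + site:sex + sex:treatment,
               data = df)
    null <- lm(y ~ site + sex + treatment + site:treatment + site:sex, data = df)
    n <- nrow(df)
    lrt <- n * log(sum(resid(null)^2) / sum(resid(full)^2))
    tibble(metabolite = m,
           treatment_site_F = an[irow, "F value"],
           treatment_site_p = an[irow, "Pr(>F)"],
           sex_treatment_lrt = lrt,
           sex_treatment_p = pchisq(lrt, df = 1, lower.tail = FALSE))
  }) |> dplyr::bind_rows()
}
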