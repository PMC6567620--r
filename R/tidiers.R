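#' @importFrom broom tidy glance
NULL

#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PERMANOVA result
#' @param x an `mb_permanova` object.
#' @param ... unused.
#' @return tibble with one row per model term plus residual and total rows.
#' @export
tidy.mb_permanova <- function(x, ...) x$table

#' @rdname tidy.mb_permanova
#' @export
glance.mb_permanova <- function(x, ...) {
  tibble(n = x$n, n_perm = x$n_perm,
         r2_model = sum(x$table$r2[!x$table$term %in% c("Residual", "Total")]))
}

#' Tidy a PERMDISP result
#' @param x an `mb_permdisp` object.
#' @param ... unused.
#' @export
tidy.mb_permdisp <- function(x, ...) {
  x$distances |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_distance = mean(.data$distance),
                     .groups = "drop")
}

#' @rdname tidy.mb_permdisp
#' @export
glance.mb_permdisp <- function(x, ...) {
  tibble(statistic = x$f, p.value = x$p, n_perm = x$n_perm)
}

#' Tidy a LASSO association model
#' @param x an `mb_lasso` object.
#' @param ... unused.
#' @return tibble of selected predictors and their standardized-scale
#'   coefficients.
#' @export
tidy.mb_lasso <- function(x, ...) x$coefficients

#' @rdname tidy.mb_lasso
#' @export
glance.mb_lasso <- function(x, ...) {
  tibble(lambda = x$lambda, oob_r2 = x$oob_r2, oob_rho = x$oob_rho,
         oob_p = x$oob_p, validated = x$validated,
         n_selected = nrow(x$coefficients))
}

#' Tidy the SCFA-longevity model set
#' @param x an `mb_scfa_cox` object.
#' @param ... unused.
#' @return tibble with a `model` column (`single` or `joint`) and per-SCFA
#'   standardized hazard ratios.
#' @export
tidy.mb_scfa_cox <- function(x, ...) {
  dplyr::bind_rows(dplyr::mutate(x$single, model = "single"),
                   dplyr::mutate(x$joint, model = "joint")) |>
    dplyr::relocate("model")
}

#' @rdname tidy.mb_scfa_cox
#' @export
glance.mb_scfa_cox <- function(x, ...) {
  tibble(n = x$n, lrt_statistic = x$lrt$statistic, lrt_df = x$lrt$df,
         lrt_p = x$lrt$p)
}

#' Tidy a standard curve
#' @param x an `mb_stdcurve` object.
#' @param ... unused.
#' @export
tidy.mb_stdcurve <- function(x, ...) {
  tibble(compound = x$compound %||% NA_character_, slope = x$slope,
         intercept = x$intercept, n = x$n)
}

#' Tidy Kaplan-Meier group medians
#' @param x an `mb_km` object.
#' @param ... unused.
#' @export
tidy.mb_km <- function(x, ...) x$medians

#' @rdname tidy.mb_km
#' @export
glance.mb_km <- function(x, ...) {
  tibble(logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
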