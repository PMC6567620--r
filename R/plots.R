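#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_step geom_boxplot
#'   geom_col facet_wrap labs theme_minimal autoplot scale_y_log10
NULL

#' Ordination plot
#'
#' Scatter of the first two principal coordinates, with the percent variance
#' explained on the axis labels. Pass per-sample metadata to map colour and
#' shape aesthetics.
#'
#' @param object an `mb_pcoa` object.
#' @param metadata optional data frame joined to the points by `sample_id`
#'   (its first column is used as the key if not named `sample_id`).
#' @param colour,shape metadata column names to map.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mb_pcoa <- function(object, metadata = NULL, colour = NULL,
                             shape = NULL, ...) {
  pts <- object$points
  if (!is.null(metadata)) {
    md <- metadata
    names(md)[1] <- "sample_id"
    pts <- dplyr::left_join(pts, md, by = "sample_id")
  }
  p <- ggplot(pts, aes(x = .data$Axis.1, y = .data$Axis.2))
  mapping <- aes()
  if (!is.null(colour)) mapping$colour <- rlang::sym(colour)
  if (!is.null(shape)) mapping$shape <- rlang::sym(shape)
  p + geom_point(mapping, size = 2) +
    labs(x = sprintf("PCo1 (%.1f%%)", object$percent_var[1]),
         y = sprintf("PCo2 (%.1f%%)", object$percent_var[2])) +
    theme_minimal()
}

#' Family abundance by treatment
#'
#' Box plots of family-level abundance split by treatment and facetted by
#' family, on a log scale.
#'
#' @param family_abund wide family-level abundance tibble.
#' @param metadata data frame with the sample id column and `treatment`.
#' @param families which families to show (default: all).
#' @return a ggplot.
#' @export
plot_family_abundance <- function(family_abund, metadata, families = NULL) {
  id_name <- names(family_abund)[1]
  long <- tidyr::pivot_longer(family_abund, -dplyr::all_of(id_name),
                              names_to = "family", values_to = "abundance")
  if (!is.null(families)) long <- dplyr::filter(long, .data$family %in% families)
  long <- dplyr::left_join(long, metadata, by = id_name)
  ggplot(long, aes(x = .data$treatment, y = .data$abundance + 1e-6)) +
    geom_boxplot(aes(fill = .data$treatment), outlier.size = 0.5) +
    facet_wrap(~family, scales = "free_y") +
    scale_y_log10() +
    labs(y = "abundance", x = NULL) +
    theme_minimal()
}

#' Metabolite concentrations by site and treatment
#'
#' @param panel metabolite panel tibble (sample id first).
#' @param metadata data frame with `site` and `treatment`.
#' @param metabolites which metabolites to show (default: all).
#' @return a ggplot.
#' @export
plot_metabolites <- function(panel, metadata, metabolites = NULL) {
  id_name <- names(panel)[1]
  long <- tidyr::pivot_longer(panel, -dplyr::all_of(id_name),
                              names_to = "metabolite", values_to = "umol_per_g")
  if (!is.null(metabolites)) {
    long <- dplyr::filter(long, .data$metabolite %in% metabolites)
  }
  long <- dplyr::left_join(long, metadata, by = id_name)
  ggplot(long, aes(x = .data$site, y = .data$umol_per_g,
                   colour = .data$treatment)) +
    geom_boxplot(outlier.size = 0.5) +
    facet_wrap(~metabolite, scales = "free_y") +
    labs(y = "concentration (umol/g wet feces)", x = NULL) +
    theme_minimal()
}

#' Kaplan-Meier survival curves by group
#'
#' @param data data frame with a time column and group column; all subjects
#'   are events.
#' @param time,group column names.
#' @return a ggplot of the step survivor functions.
#' @export
plot_survival <- function(data, time = "death_age", group = "treatment") {
  df <- tibble(time = data[[time]], group = as.factor(data[[group]]))
  curves <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::mutate(surv = 1 - dplyr::row_number() / dplyr::n()) |>
    dplyr::ungroup()
  ggplot(curves, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    labs(x = "age (days)", y = "fraction surviving") +
    theme_minimal()
}

#' Cross-validation curve of a LASSO model
#'
#' Out-of-bag R-squared along the penalty grid, with the selected penalty
#' marked.
#'
#' @param object an `mb_lasso` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mb_lasso <- function(object, ...) {
  df <- tibble(lambda = object$lambda_grid, oob_r2 = object$oob_r2_path)
  ggplot(df, aes(x = .data$lambda, y = .data$oob_r2)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    labs(x = "penalty (lambda)", y = "out-of-bag R squared") +
    theme_minimal()
}
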