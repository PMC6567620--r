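#' @importFrom rlang .data abort warn inform
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats anova aov coef cor fitted lm median model.matrix p.adjust
#'   pchisq pnorm pt quantile resid rexp rlnorm rmultinom rnorm runif sd
#'   setNames terms var vcov formula as.formula predict
#' @importFrom utils head
NULL

# First column of a wide table is taken as the sample identifier; the rest
# must be numeric.
split_id_matrix <- function(tbl, what = "table") {
  if (!is.data.frame(tbl) || ncol(tbl) < 2) {
    abort(paste0("`", what, "` must be a data frame with an id column plus value columns"))
  }
  ids <- as.character(tbl[[1]])
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    abort(paste0("all non-id columns of `", what, "` must be numeric"))
  }
  rownames(mat) <- ids
  list(ids = ids, mat = mat, id_name = names(tbl)[1])
}

rebuild_id_matrix <- function(mat, ids, id_name) {
  out <- as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- dplyr::bind_cols(tibble(!!id_name := ids), out)
  out
}

# Design variables are modeled as factors with "control" as the reference
# level when present, so treatment coefficients read as treated-vs-control.
design_factor <- function(x) {
  x <- as.character(x)
  lv <- sort(unique(x))
  if ("control" %in% lv) lv <- c("control", setdiff(lv, "control"))
  factor(x, levels = lv)
}

abund_units <- function(x) attr(x, "mb_units")

set_abund_units <- function(x, units, level = NULL) {
  attr(x, "mb_units") <- units
  if (!is.null(level)) attr(x, "mb_level") <- level
  x
}

# Deterministic stream of sub-seeds from one cohort seed (values < 2^31).
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
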