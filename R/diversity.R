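#' Rarefy a count vector to a fixed depth
#'
#' Draws `depth` reads without replacement from the sample's read multiset
#' (multivariate hypergeometric), so subsampled totals are exactly `depth`.
#'
#' @param x non-negative integer vector of per-OTU counts.
#' @param depth number of reads to retain; must not exceed `sum(x)`.
#' @param seed optional integer seed for the single realization.
#' @param sample_id used in error messages.
#' @return integer vector of the same length and names as `x`.
#' @export
subsample_counts <- function(x, depth, seed = NULL, sample_id = NULL) {
  x <- as.integer(round(x))
  if (any(x < 0)) abort("counts must be non-negative")
  total <- sum(x)
  if (depth > total) {
    abort(paste0("requested depth ", depth, " exceeds total reads (", total, ")",
                 if (!is.null(sample_id)) paste0(" in sample ", sample_id) else ""))
  }
  if (depth == total) return(x)
  with_seed(seed, {
    reads <- rep.int(seq_along(x), x)
    keep <- sample(reads, depth)
    out <- tabulate(keep, nbins = length(x))
    names(out) <- names(x)
    as.integer(out)
  })
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where `F1` and `F2` are the numbers
#' of singleton and doubleton OTUs. The bias-corrected form stays finite when
#' no doubletons are present, and equals the observed richness when there is
#' at most one singleton.
#'
#' @param x non-negative integer vector of per-OTU counts.
#' @return estimated richness (never below observed richness).
#' @export
chao1 <- function(x) {
  if (all(x == 0)) abort("cannot estimate richness from an all-zero sample")
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Simpson's evenness
#'
#' Inverse Simpson diversity divided by observed richness:
#' `(1 / sum(p_i^2)) / S_obs`, in (0, 1], reaching 1 on perfectly even
#' profiles.
#'
#' @param x non-negative numeric vector of per-OTU counts or abundances.
#' @return evenness in (0, 1].
#' @export
simpson_evenness <- function(x) {
  if (all(x == 0)) abort("cannot compute evenness of an all-zero sample")
  p <- x / sum(x)
  (1 / sum(p^2)) / sum(x > 0)
}

#' Rarefied alpha-diversity for a cohort
#'
#' Each sample is independently subsampled once to the given depth (by
#' default the cohort minimum endemic read count), then Chao1 and Simpson's
#' evenness are computed on the rarefied profile.
#'
#' @param counts wide count tibble (sample id column first; spike reads must
#'   already be excluded).
#' @param depth rarefaction depth; `NULL` uses the cohort minimum.
#' @param seed integer seed for the rarefaction realization.
#' @return tibble with `sample_id`, `rarefaction_depth`, `observed`, `chao1`,
#'   `evenness`.
#' @export
alpha_diversity <- function(counts, depth = NULL, seed = NULL) {
  cm <- split_id_matrix(counts, "counts")
  totals <- rowSums(cm$mat)
  if (is.null(depth)) depth <- min(totals)
  sub_seeds <- if (is.null(seed)) rep(list(NULL), nrow(cm$mat)) else
    as.list(derive_seeds(seed, nrow(cm$mat)))
  rows <- purrr::map(seq_len(nrow(cm$mat)), function(i) {
    xs <- subsample_counts(cm$mat[i, ], depth, seed = sub_seeds[[i]],
                           sample_id = cm$ids[i])
    tibble(sample_id = cm$ids[i], rarefaction_depth = depth,
           observed = sum(xs > 0), chao1 = chao1(xs),
           evenness = simpson_evenness(xs))
  })
  dplyr::bind_rows(rows)
}

#' Partition-then-rarefy alpha-diversity
#'
#' Removes the excluded OTUs' counts first, then subsamples every remaining
#' sample to the cohort-minimum remaining total, then computes Chao1 and
#' evenness. The order matters: subsampling *after* partitioning equalizes
#' the retained read totals across samples, which subsampling before
#' partitioning would not. Samples left empty by the exclusion are dropped
#' with a warning.
#'
#' @param counts wide count tibble.
#' @param exclude character vector of OTU column names to remove before
#'   rarefying (possibly empty).
#' @param seed integer seed.
#' @return tibble as from [alpha_diversity()], plus an `excluded_otus`
#'   attribute.
#' @export
partitioned_diversity <- function(counts, exclude = character(), seed = NULL) {
  cm <- split_id_matrix(counts, "counts")
  keep_cols <- setdiff(colnames(cm$mat), exclude)
  mat <- cm$mat[, keep_cols, drop = FALSE]
  totals <- rowSums(mat)
  empty <- totals == 0
  if (any(empty)) {
    warn(paste0("dropping ", sum(empty), " sample(s) left empty by the partition: ",
                paste(cm$ids[empty], collapse = ", ")))
    mat <- mat[!empty, , drop = FALSE]
    cm$ids <- cm$ids[!empty]
  }
  out <- alpha_diversity(rebuild_id_matrix(mat, cm$ids, cm$id_name),
                         depth = min(rowSums(mat)), seed = seed)
  attr(out, "excluded_otus") <- exclude
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, in \[0, 1\], symmetric with
#' zero diagonal. A pair of all-zero samples has no defined dissimilarity and
#' is returned as `NA` with a warning.
#'
#' @param x wide abundance tibble (sample id column first), counts or any
#'   non-negative abundances.
#' @return a `dist` object with sample ids as labels.
#' @export
bray_curtis <- function(x) {
  xm <- split_id_matrix(x, "x")
  if (any(xm$mat < 0)) abort("Bray-Curtis requires non-negative abundances")
  n <- nrow(xm$mat)
  d <- matrix(0, n, n, dimnames = list(xm$ids, xm$ids))
  for (i in seq_len(n - 1)) {
    xi <- xm$mat[i, ]
    for (j in (i + 1):n) {
      denom <- sum(xi + xm$mat[j, ])
      d[i, j] <- d[j, i] <- if (denom == 0) NA_real_ else
        sum(abs(xi - xm$mat[j, ])) / denom
    }
  }
  if (anyNA(d)) warn("some sample pairs are both all-zero; their dissimilarity is NA")
  stats::as.dist(d)
}
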