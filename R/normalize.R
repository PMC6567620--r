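#' Relative abundance from an OTU count table
#'
#' Divides each sample's endemic OTU counts by its endemic read total. Spike
#' reads must already have been separated from the table. Samples with no
#' endemic reads cannot be normalized and are dropped with a warning.
#'
#' @param counts wide tibble: sample id column first, then integer OTU counts.
#' @return wide tibble of proportions (rows sum to 1) with unit attribute
#'   `relative`.
#' @export
relative_abundance <- function(counts) {
  cm <- split_id_matrix(counts, "counts")
  if (any(cm$mat < 0)) abort("counts must be non-negative")
  totals <- rowSums(cm$mat)
  empty <- totals == 0
  if (any(empty)) {
    warn(paste0("dropping ", sum(empty), " sample(s) with zero endemic reads: ",
                paste(cm$ids[empty], collapse = ", ")))
    cm$mat <- cm$mat[!empty, , drop = FALSE]
    cm$ids <- cm$ids[!empty]
    totals <- totals[!empty]
  }
  rel <- sweep(cm$mat, 1, totals, `/`)
  set_abund_units(rebuild_id_matrix(rel, cm$ids, cm$id_name), "relative", "otu")
}

#' Spike-adjusted absolute abundance (vector form)
#'
#' The per-taxon density statistic in microliter-spike-equivalents per gram:
#' `rel * (total_endemic * spike_volume) / (total_spike * weight)`. Summed
#' over all taxa of a sample it equals
#' `(total_endemic * spike_volume) / (total_spike * weight)`.
#'
#' @param rel relative abundance (proportion), vectorized over taxa.
#' @param total_endemic total endemic reads in the sample.
#' @param total_spike reads recovered from the spike-in standard (must be
#'   at least 1; the statistic is undefined at 0).
#' @param spike_volume microliters of spike added.
#' @param weight sample wet weight in grams.
#' @return numeric vector, uL spike equivalents per gram.
#' @export
spike_equivalents <- function(rel, total_endemic, total_spike, spike_volume, weight) {
  if (any(weight <= 0)) abort("`weight` must be strictly positive")
  if (any(total_spike < 1)) {
    abort("`total_spike` must be at least 1; the statistic is undefined without spike reads")
  }
  rel * (total_endemic * spike_volume) / (total_spike * weight)
}

#' Spike-adjusted abundance table for a cohort
#'
#' Combines a count table with per-sample spike recovery, spike volume, and
#' sample weight. Samples with zero spike reads have an undefined statistic
#' and are returned as missing values with a warning; no pseudo-count is
#' substituted.
#'
#' @param counts wide count tibble (sample id column first).
#' @param metadata data frame with the sample id column (same name as in
#'   `counts`), `spike_reads`, `spike_uL`, and `weight_g`.
#' @return wide tibble in uL-spike-equivalents per gram, unit attribute
#'   `spike_equiv`.
#' @export
spike_adjusted_abundance <- function(counts, metadata) {
  cm <- split_id_matrix(counts, "counts")
  need <- c(cm$id_name, "spike_reads", "spike_uL", "weight_g")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) {
    abort(paste0("`metadata` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  md <- metadata[match(cm$ids, metadata[[cm$id_name]]), ]
  if (any(is.na(md[[cm$id_name]]))) abort("some samples in `counts` missing from `metadata`")
  total_endemic <- rowSums(cm$mat)
  rel <- sweep(cm$mat, 1, pmax(total_endemic, 1), `/`)
  zero_spike <- md$spike_reads == 0
  out <- matrix(NA_real_, nrow = nrow(cm$mat), ncol = ncol(cm$mat),
                dimnames = dimnames(cm$mat))
  ok <- !zero_spike
  if (any(ok)) {
    out[ok, ] <- rel[ok, , drop = FALSE] *
      (total_endemic[ok] * md$spike_uL[ok]) / (md$spike_reads[ok] * md$weight_g[ok])
  }
  if (any(zero_spike)) {
    warn(paste0(sum(zero_spike), " sample(s) had zero spike reads; spike-adjusted ",
                "abundance is undefined and reported as NA: ",
                paste(cm$ids[zero_spike], collapse = ", ")))
  }
  set_abund_units(rebuild_id_matrix(out, cm$ids, cm$id_name), "spike_equiv", "otu")
}

#' Aggregate an OTU-level abundance table to family level
#'
#' Family abundance is the summed abundance of all member OTUs; total
#' abundance is conserved. OTUs without a taxonomy entry are pooled into an
#' `unclassified` family. Works on either relative or spike-adjusted tables;
#' the unit attribute propagates.
#'
#' @param abund wide OTU-level abundance tibble.
#' @param taxonomy data frame with columns `otu`, `family`.
#' @return wide family-level tibble.
#' @export
aggregate_family <- function(abund, taxonomy) {
  am <- split_id_matrix(abund, "abund")
  units <- abund_units(abund)
  fam <- taxonomy$family[match(colnames(am$mat), taxonomy$otu)]
  fam[is.na(fam)] <- "unclassified"
  fams <- unique(fam)
  out <- vapply(fams, function(f) rowSums(am$mat[, fam == f, drop = FALSE]),
                numeric(nrow(am$mat)))
  if (nrow(am$mat) == 1) out <- matrix(out, nrow = 1, dimnames = list(am$ids, fams))
  set_abund_units(rebuild_id_matrix(out, am$ids, am$id_name), units, "family")
}

#' Read a mothur shared-format OTU count table
#'
#' Tolerates and drops the mothur bookkeeping columns `label` and `numOtus`;
#' the `Group` column becomes the sample id. Generic sample x OTU TSVs with
#' the sample id in the first column are also accepted.
#'
#' @param path path to a TSV file.
#' @param spike_taxon optional string; columns whose name contains it are
#'   summed into a `spike_reads` attribute and removed from the table.
#' @return wide count tibble; if `spike_taxon` was found, the per-sample
#'   spike totals are attached as attribute `spike_reads`.
#' @export
read_shared <- function(path, spike_taxon = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  drop <- intersect(c("label", "numOtus"), names(tbl))
  tbl <- tbl[, setdiff(names(tbl), drop)]
  if ("Group" %in% names(tbl)) {
    tbl <- dplyr::relocate(tbl, "Group")
    names(tbl)[1] <- "sample_id"
  }
  if (!is.null(spike_taxon)) {
    hit <- stringr::str_detect(names(tbl)[-1], stringr::fixed(spike_taxon))
    if (any(hit)) {
      spike <- rowSums(as.matrix(tbl[, -1][, hit, drop = FALSE]))
      tbl <- tbl[, c(names(tbl)[1], names(tbl)[-1][!hit])]
      attr(tbl, "spike_reads") <- as.integer(spike)
    } else {
      attr(tbl, "spike_reads") <- rep(0L, nrow(tbl))
    }
  }
  tbl
}

#' Read a mothur cons.taxonomy-style table
#'
#' Expects columns `OTU` and `Taxonomy` (a semicolon-delimited lineage with
#' optional bootstrap confidence suffixes such as `(100)`), and extracts the
#' family as the fifth rank (domain; phylum; class; order; family; ...).
#' Unresolved or `unclassified` ranks map to family `unclassified`.
#'
#' @param path path to a TSV file.
#' @param family_rank 1-based index of the family rank in the lineage.
#' @return tibble with `otu`, `family`, `lineage`.
#' @export
read_taxonomy <- function(path, family_rank = 5) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl) <- tolower(names(tbl))
  if (!all(c("otu", "taxonomy") %in% names(tbl))) {
    abort("taxonomy file must have OTU and Taxonomy columns")
  }
  lineage <- stringr::str_remove_all(tbl$taxonomy, "\\(\\d+\\)")
  lineage <- stringr::str_remove(lineage, ";\\s*$")
  ranks <- stringr::str_split(lineage, ";")
  family <- vapply(ranks, function(r) {
    f <- if (length(r) >= family_rank) stringr::str_trim(r[[family_rank]]) else ""
    if (f == "" || stringr::str_detect(f, "^unclassified")) "unclassified" else f
  }, character(1))
  tibble(otu = tbl$otu, family = family, lineage = lineage)
}
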