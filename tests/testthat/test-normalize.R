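test_that("relative abundance is row-normalized and symmetric in columns", {
  counts <- tibble::tibble(sample_id = c("s1", "s2"), A = c(9L, 5L), B = c(1L, 0L))
  rel <- relative_abundance(counts)
  expect_equal(rel$A, c(0.9, 1))
  expect_equal(rel$B, c(0.1, 0))
  expect_equal(rowSums(as.matrix(rel[, -1])), c(1, 1), ignore_attr = TRUE)

  perm <- counts[, c("sample_id", "B", "A")]
  rel_perm <- relative_abundance(perm)
  expect_equal(rel_perm$A, rel$A)
  expect_equal(rel_perm$B, rel$B)

  counts0 <- tibble::tibble(sample_id = c("s1", "s2"), A = c(0L, 3L), B = c(0L, 1L))
  expect_warning(out <- relative_abundance(counts0), "zero endemic")
  expect_equal(out$sample_id, "s2")
})

test_that("the spike-equivalents formula matches hand computation", {
  expect_equal(spike_equivalents(1, 900, 100, 10, 0.1), 900)
  expect_equal(spike_equivalents(0, 900, 100, 10, 0.1), 0)
  expect_equal(spike_equivalents(0.25, 2000, 500, 10, 0.05), 200)
  expect_error(spike_equivalents(1, 10, 0, 10, 0.1), "undefined")
  expect_error(spike_equivalents(1, 10, 10, 10, 0), "positive")
})

test_that("spike-adjusted values sum to the sample-level identity", {
  set.seed(31)
  for (i in 1:10) {
    rel <- runif(8); rel <- rel / sum(rel)
    te <- sample(500:5000, 1); ts <- sample(50:800, 1)
    vol <- runif(1, 5, 20); w <- runif(1, 0.02, 0.2)
    vals <- spike_equivalents(rel, te, ts, vol, w)
    expect_equal(sum(vals), te * vol / (ts * w))
  }
})

test_that("samples without spike reads become NA, never imputed", {
  counts <- tibble::tibble(mouse_id = c("m1", "m2"), A = c(90L, 80L), B = c(10L, 20L))
  md <- tibble::tibble(mouse_id = c("m1", "m2"), spike_reads = c(0L, 50L),
                       spike_uL = 10, weight_g = 0.1)
  expect_warning(ab <- spike_adjusted_abundance(counts, md), "zero spike")
  expect_true(all(is.na(ab[1, -1])))
  expect_equal(ab$A[2], 0.8 * (100 * 10) / (50 * 0.1))
})

test_that("scaling endemic counts scales spike-adjusted values linearly", {
  counts <- tibble::tibble(mouse_id = "m1", A = 30L, B = 70L)
  md <- tibble::tibble(mouse_id = "m1", spike_reads = 20L, spike_uL = 10,
                       weight_g = 0.05)
  a1 <- spike_adjusted_abundance(counts, md)
  counts3 <- dplyr::mutate(counts, A = A * 3L, B = B * 3L)
  a3 <- spike_adjusted_abundance(counts3, md)
  expect_equal(as.numeric(a3[1, -1]), 3 * as.numeric(a1[1, -1]))
})

test_that("family aggregation conserves totals and pools unmapped OTUs", {
  ab <- tibble::tibble(mouse_id = c("m1", "m2"),
                       OTU_a = c(3, 1), OTU_b = c(4, 2), OTU_c = c(5, 7))
  tax <- tibble::tibble(otu = c("OTU_a", "OTU_b"), family = c("F1", "F1"))
  fam <- aggregate_family(ab, tax)
  expect_equal(fam$F1, c(7, 3))
  expect_equal(fam$unclassified, c(5, 7))
  expect_equal(rowSums(as.matrix(fam[, -1])), rowSums(as.matrix(ab[, -1])),
               ignore_attr = TRUE)

  rel <- relative_abundance(tibble::tibble(mouse_id = "m", A = 2L, B = 8L))
  fam_rel <- aggregate_family(rel, tibble::tibble(otu = c("A", "B"),
                                                  family = c("F1", "F2")))
  expect_equal(sum(fam_rel[1, -1]), 1)
  expect_equal(attr(fam_rel, "mb_units"), "relative")
})

test_that("expected spike-adjusted values are depth-invariant", {
  dens <- c(A = 2e5, B = 6e5, C = 2e5)
  w <- 0.05; vol <- 10; cp <- 2000
  mean_adj <- function(depth) {
    rowMeans(vapply(1:250, function(i) {
      s <- sequence_sample(dens, w, vol, depth, cp, seed = 5000 + i)
      te <- sum(s$counts)
      spike_equivalents(s$counts / te, te, s$spike_reads, vol, w)
    }, numeric(3)))
  }
  m1 <- mean_adj(1000)
  m2 <- mean_adj(2000)
  expect_equal(unname(m2 / m1), rep(1, 3), tolerance = 0.05)
  # and they estimate density in spike-equivalent units: dens / cp
  expect_equal(unname(m1), unname(dens / cp), tolerance = 0.05)
})

test_that("raising one taxon leaves others' spike-adjusted values unchanged", {
  base <- c(A = 2e5, B = 2e5, C = 2e5)
  up <- c(A = 2e6, B = 2e5, C = 2e5)
  w <- 0.05; vol <- 10; cp <- 2000
  stats_for <- function(dens) {
    out <- vapply(1:300, function(i) {
      s <- sequence_sample(dens, w, vol, 2000, cp, seed = 7000 + i)
      te <- sum(s$counts)
      c(spike_equivalents(s$counts / te, te, s$spike_reads, vol, w)["B"],
        rel_b = unname(s$counts["B"] / te))
    }, numeric(2))
    rowMeans(out)
  }
  s_base <- stats_for(base); s_up <- stats_for(up)
  expect_equal(unname(s_up[1] / s_base[1]), 1, tolerance = 0.06)  # density stat
  expect_lt(s_up[2], 0.5 * s_base[2])                             # composition
})

test_that("mothur-style shared and taxonomy files round-trip", {
  shared <- paste(
    "label\tGroup\tnumOtus\tOTU_1\tOTU_2\tSphingopyxis_spike",
    "0.03\tm1\t3\t10\t30\t5",
    "0.03\tm2\t3\t20\t20\t8", sep = "\n")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(shared, f)
  tbl <- read_shared(f, spike_taxon = "Sphingopyxis")
  expect_equal(names(tbl), c("sample_id", "OTU_1", "OTU_2"))
  expect_equal(attr(tbl, "spike_reads"), c(5L, 8L))
  expect_equal(tbl$OTU_1, c(10, 20))

  taxf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(
    "OTU\tSize\tTaxonomy",
    "OTU_1\t100\tBacteria(100);Bacteroidetes(100);Bacteroidia(100);Bacteroidales(100);Muribaculaceae(97);",
    "OTU_2\t50\tBacteria(100);Firmicutes(100);Bacilli(99);Lactobacillales(99);unclassified;",
    sep = "\n"), taxf)
  tax <- read_taxonomy(taxf)
  expect_equal(tax$family, c("Muribaculaceae", "unclassified"))
})
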