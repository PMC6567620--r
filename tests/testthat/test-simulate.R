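test_that("the factorial design has the right shape, cages, and ages", {
  des <- generate_design(12, seed = 1)
  expect_equal(nrow(des), 144)
  expect_equal(unname(as.vector(table(des$site, des$sex, des$treatment))),
               rep(12L, 12))
  expect_equal(anyDuplicated(des$cage_id), 0L)
  expect_true(all(des$sampling_age >= 762 & des$sampling_age <= 973))

  one <- generate_design(1, seed = 2)
  expect_equal(nrow(one), 12)
  expect_equal(nrow(dplyr::distinct(one, site, sex, treatment)), 12)

  expect_error(generate_design(0), "positive")
})

test_that("design generation is seed-deterministic", {
  expect_identical(generate_design(4, seed = 7), generate_design(4, seed = 7))
  a <- generate_design(4, seed = 7)
  b <- generate_design(4, seed = 8)
  expect_false(identical(a$cage_id, b$cage_id))
})

test_that("planted community folds are recovered from latent densities", {
  params <- cohort_params()
  ratios <- sapply(1:6, function(s) {
    des <- generate_design(12, seed = s)
    dens <- generate_community(des, params, seed = s + 100)
    tr <- des$treatment == "ACA"
    tjl <- des$site == "TJL"
    bloom <- dens$OTU_1
    r_bloom <- median(bloom[tr & tjl]) / median(bloom[!tr & tjl])
    other <- rowSums(as.matrix(dens[, paste0("OTU_", 6:40)]))
    r_other <- median(other[tr]) / median(other[!tr])
    c(r_bloom, r_other)
  })
  # latent medians scale exactly by the planted folds; noise is only from
  # the lognormal sampling of the medians themselves
  expect_equal(mean(ratios[1, ]), 4.3, tolerance = 0.15)
  expect_equal(mean(ratios[2, ]), 0.5, tolerance = 0.05)
})

test_that("site-restricted OTUs are essentially absent off-site", {
  des <- generate_design(4, seed = 3)
  dens <- generate_community(des, cohort_params(), seed = 4)
  off <- des$site != "UT"
  expect_true(max(dens$OTU_4[off]) < 1e-2 * min(dens$OTU_4[!off]))
})

test_that("null-mode communities show no treatment effect", {
  params <- null_params(small_params())
  des <- generate_design(12, seed = 5)
  dens <- generate_community(des, params, seed = 6)
  tr <- des$treatment == "ACA"
  r <- median(dens$OTU_1[tr]) / median(dens$OTU_1[!tr])
  expect_gt(r, 0.6)
  expect_lt(r, 1.6)
})

test_that("unknown sites in the bloom map are rejected", {
  des <- generate_design(1, seed = 1)
  des$site[1] <- "ELSEWHERE"
  expect_error(generate_community(des, cohort_params()), "ELSEWHERE")
})

test_that("sequencing draws behave like the multinomial they are", {
  # all density on the spike: every read is spike
  s <- sequence_sample(c(a = 0, b = 0), weight = 0.05, spike_volume = 10,
                       depth = 500, spike_copies_per_uL = 1000, seed = 1)
  expect_equal(s$spike_reads, 500)
  expect_equal(unname(s$counts), c(0L, 0L))

  # expected spike fraction matches the closed form
  dens <- c(a = 4000, b = 8000)
  w <- 0.05; vol <- 10; cp <- 20
  expected_frac <- (cp * vol) / (cp * vol + sum(dens) * w)
  fracs <- vapply(1:300, function(i) {
    s <- sequence_sample(dens, w, vol, depth = 1000, spike_copies_per_uL = cp,
                         seed = i)
    s$spike_reads / 1000
  }, numeric(1))
  expect_equal(mean(fracs), expected_frac, tolerance = 0.01)

  # doubling depth doubles expected counts, proportions fixed
  mean_counts <- function(depth) {
    rowMeans(vapply(1:200, function(i) {
      sequence_sample(dens, w, vol, depth, cp, seed = 1000 + i)$counts
    }, numeric(2)))
  }
  m1 <- mean_counts(500); m2 <- mean_counts(1000)
  expect_equal(unname(m2 / m1), c(2, 2), tolerance = 0.06)

  expect_error(sequence_sample(c(a = 0), weight = 1, spike_volume = 0 * 10,
                               depth = 10, spike_copies_per_uL = 0),
               "degenerate")
})

test_that("metabolite couplings are planted with the right signs", {
  co <- shared_cohort()
  d <- co$design
  # acetate-butyrate latent factor
  expect_gt(cor(rank(co$metabolites$acetate), rank(co$metabolites$butyrate)), 0.2)
  # Muribaculaceae -> propionate, positive within treatment arms
  ab <- suppressWarnings(spike_adjusted_abundance(co$counts, d))
  fam <- aggregate_family(ab, co$taxonomy)
  for (arm in c("control", "ACA")) {
    idx <- d$treatment == arm
    r <- spearman_with_t(fam$Muribaculaceae[idx], co$metabolites$propionate[idx])
    expect_gt(r$rho, 0)
  }
})

test_that("null-mode metabolites are decoupled from the community", {
  des <- generate_design(24, seed = 11)
  params <- null_params(small_params())
  dens <- generate_community(des, params, seed = 12)
  met <- generate_metabolites(dens, des, params, seed = 13)
  r <- spearman_with_t(dens$OTU_1, met$propionate)
  expect_lt(abs(r$rho), 0.15)
  expect_lt(abs(cor(rank(met$acetate), rank(met$butyrate))), 0.15)
})

test_that("survival respects truncation and the planted hazards", {
  co <- shared_cohort()
  expect_true(all(co$design$death_age > co$design$sampling_age))

  # independence under zero betas
  params <- null_params(cohort_params())
  des <- generate_design(24, seed = 21)
  z <- scale(matrix(rnorm(nrow(des) * 3), ncol = 3))
  colnames(z) <- c("acetate", "butyrate", "propionate")
  sv <- generate_survival(des, z, params, seed = 22)
  expect_lt(abs(cor(z[, "propionate"], sv$time)), 0.12)

  # planted betas recovered at n = 2004 within Monte-Carlo tolerance
  params <- cohort_params()
  des <- generate_design(167, seed = 23)
  z <- scale(matrix(rnorm(nrow(des) * 3), ncol = 3))
  colnames(z) <- c("acetate", "butyrate", "propionate")
  sv <- generate_survival(des, z, params, seed = 24)
  df <- data.frame(entry = sv$entry, time = sv$time, event = 1L,
                   treatment = des$treatment, sex = des$sex, site = des$site, z)
  fit <- survival::coxph(survival::Surv(entry, time, event) ~
                           treatment:sex + acetate + butyrate + propionate,
                         data = df, ties = "efron")
  for (s in names(params$hazard_betas)) {
    expect_equal(unname(coef(fit)[s]), unname(params$hazard_betas[s]),
                 tolerance = 0.25)
  }

  expect_error(cohort_params(weibull_shape = -1), "positive")
  expect_error(cohort_params(metabolite_noise_sd = -0.1), "non-negative")
})

test_that("identical seeds reproduce cohorts bit-for-bit", {
  a <- simulate_cohort(n_per_cell = 2, params = small_params(), seed = 99)
  b <- simulate_cohort(n_per_cell = 2, params = small_params(), seed = 99)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$design, b$design)
  c2 <- simulate_cohort(n_per_cell = 2, params = small_params(), seed = 100)
  expect_false(identical(a$counts, c2$counts))
})
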