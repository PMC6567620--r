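#' Generator settings for synthetic cohorts
#'
#' Bundles every knob of the synthetic cohort generator. The defaults encode
#' the planted-effect condition: a treatment-responsive bloom OTU whose
#' identity differs by site (`OTU_1` at TJL and UM, `OTU_4` at UT, the latter
#' essentially absent elsewhere), a 4.3-fold density increase of the bloom
#' taxon under treatment, a 0.5-fold decrease of the remaining
#' *Muribaculaceae*, taxon-coupled metabolite concentrations, and per-SD
#' log-hazard coefficients for the three SCFAs of log(1.576), log(0.586) and
#' log(0.674) for acetate, butyrate and propionate respectively.
#'
#' @param n_otus number of endemic OTUs.
#' @param log_mean,otu_log_sd,sample_log_sd,site_log_sd log-normal community
#'   baseline: grand mean of log density (log 16S copies per gram), spread of
#'   per-OTU means, within-OTU across-sample spread, and spread of per-site
#'   offsets.
#' @param baseline_boost named additions to the log-mean of selected OTUs,
#'   used to make the focal taxa dominant as in real fecal communities.
#' @param bloom_otu_by_site named character vector mapping each site to the
#'   OTU that blooms under treatment there.
#' @param site_restricted named character vector; each entry names an OTU and
#'   gives the only site where it occurs (density is negligible elsewhere).
#' @param bloom_fold multiplicative density effect of treatment on the site's
#'   bloom OTU.
#' @param muribaculaceae_other_fold multiplicative treatment effect on
#'   *Muribaculaceae* OTUs other than the bloom pair.
#' @param sequencing_depth target reads per sample; realized depth is uniform
#'   on `depth_range * sequencing_depth`.
#' @param depth_range relative range of realized sequencing depth.
#' @param spike_copies_per_uL 16S copies per microliter of the spike-in
#'   standard suspension.
#' @param spike_volume microliters of spike added to every sample.
#' @param sample_weight_range range (grams) of fecal sample wet weights.
#' @param metabolite_coefficients list mapping metabolite name to a named
#'   numeric vector of per-OTU log-linear coefficients applied to the
#'   standardized log1p OTU density. `NULL` uses
#'   [default_metabolite_coefficients()].
#' @param metabolite_base named log medians (log umol/g) per metabolite.
#' @param metabolite_treatment_effects named additive treatment effects on
#'   log concentration (direct, not community-mediated).
#' @param metabolite_noise_sd SD of the Gaussian noise on log concentration.
#' @param acetate_butyrate_loading loading of a shared latent factor added to
#'   log acetate and log butyrate, making them positively correlated by
#'   construction.
#' @param hazard_betas named per-SD log-hazard coefficients for standardized
#'   acetate, butyrate and propionate.
#' @param weibull_shape,weibull_scale baseline Weibull hazard of the lifespan
#'   model (scale in days).
#' @param treatment_loghr named log hazard ratios of treatment by sex
#'   (`M`, `F`); the default reproduces a stronger male longevity benefit.
#' @param cage_sd SD of an optional cage-level random effect added to every
#'   OTU's log density (off by default).
#' @return a list of class `mb_params`.
#' @export
cohort_params <- function(n_otus = 200,
                          log_mean = 11,
                          otu_log_sd = 1.5,
                          sample_log_sd = 0.8,
                          site_log_sd = 0.3,
                          baseline_boost = c(OTU_1 = 4.2, OTU_2 = 3.9, OTU_3 = 3.8,
                                             OTU_4 = 4.0, OTU_5 = 2.5),
                          bloom_otu_by_site = c(TJL = "OTU_1", UM = "OTU_1", UT = "OTU_4"),
                          site_restricted = c(OTU_4 = "UT"),
                          bloom_fold = 4.3,
                          muribaculaceae_other_fold = 0.5,
                          sequencing_depth = 10000,
                          depth_range = c(0.7, 1.3),
                          spike_copies_per_uL = 20000,
                          spike_volume = 10,
                          sample_weight_range = c(0.03, 0.09),
                          metabolite_coefficients = NULL,
                          metabolite_base = c(acetate = log(13), butyrate = log(4),
                                              propionate = log(1.4), succinate = log(2.8),
                                              lactate = log(5), glucose = log(6)),
                          metabolite_treatment_effects = c(glucose = 0.6, succinate = -0.5),
                          metabolite_noise_sd = 0.4,
                          acetate_butyrate_loading = 0.4,
                          hazard_betas = c(acetate = log(1.576), butyrate = log(0.586),
                                           propionate = log(0.674)),
                          weibull_shape = 6,
                          weibull_scale = 920,
                          treatment_loghr = c(M = -0.65, F = -0.2),
                          cage_sd = 0) {
  if (n_otus < 6) abort("`n_otus` must be at least 6 so the focal OTUs exist")
  if (bloom_fold <= 0 || muribaculaceae_other_fold <= 0) {
    abort("fold changes must be strictly positive")
  }
  if (metabolite_noise_sd < 0) abort("`metabolite_noise_sd` must be non-negative")
  if (weibull_shape <= 0 || weibull_scale <= 0) {
    abort("Weibull shape and scale must be strictly positive")
  }
  if (spike_copies_per_uL <= 0 || spike_volume <= 0) {
    abort("spike copies and volume must be strictly positive")
  }
  p <- list(n_otus = as.integer(n_otus), log_mean = log_mean, otu_log_sd = otu_log_sd,
            sample_log_sd = sample_log_sd, site_log_sd = site_log_sd,
            baseline_boost = baseline_boost, bloom_otu_by_site = bloom_otu_by_site,
            site_restricted = site_restricted, bloom_fold = bloom_fold,
            muribaculaceae_other_fold = muribaculaceae_other_fold,
            sequencing_depth = sequencing_depth, depth_range = depth_range,
            spike_copies_per_uL = spike_copies_per_uL, spike_volume = spike_volume,
            sample_weight_range = sample_weight_range,
            metabolite_coefficients = metabolite_coefficients,
            metabolite_base = metabolite_base,
            metabolite_treatment_effects = metabolite_treatment_effects,
            metabolite_noise_sd = metabolite_noise_sd,
            acetate_butyrate_loading = acetate_butyrate_loading,
            hazard_betas = hazard_betas, weibull_shape = weibull_shape,
            weibull_scale = weibull_scale, treatment_loghr = treatment_loghr,
            cage_sd = cage_sd)
  structure(p, class = "mb_params")
}

#' Null-mode generator settings
#'
#' Takes planted-effect settings and removes every planted effect: unit fold
#' changes, zero taxon-metabolite coefficients, zero direct treatment effects
#' on metabolites, no shared acetate/butyrate factor, zero SCFA hazard
#' coefficients, and no treatment effect on survival. Under these settings
#' every downstream test should reject at its nominal level.
#'
#' @param params an `mb_params` object to neutralize.
#' @return an `mb_params` object.
#' @export
null_params <- function(params = cohort_params()) {
  params$bloom_fold <- 1
  params$muribaculaceae_other_fold <- 1
  params$metabolite_coefficients <- list()
  params$metabolite_treatment_effects <- numeric(0)
  params$acetate_butyrate_loading <- 0
  params$hazard_betas <- c(acetate = 0, butyrate = 0, propionate = 0)
  params$treatment_loghr <- c(M = 0, F = 0)
  params
}

#' Default OTU taxonomy for synthetic cohorts
#'
#' Assigns OTUs to the five dominant families of the mouse fecal community.
#' The focal bloom OTUs (`OTU_1`, `OTU_4`) and `OTU_5` are *Muribaculaceae*;
#' `OTU_2` is the dominant *Lactobacillaceae*; `OTU_3` a dominant
#' *Lachnospiraceae*.
#'
#' @param n_otus number of OTUs.
#' @return tibble with columns `otu`, `family`.
#' @export
default_taxonomy <- function(n_otus = 200) {
  fam <- rep("unclassified", n_otus)
  assign_fam <- function(fam, idx, name) {
    idx <- idx[idx <= n_otus]
    fam[idx] <- name
    fam
  }
  fam <- assign_fam(fam, c(1, 4, 5, 6:40), "Muribaculaceae")
  fam <- assign_fam(fam, c(2, 41:60), "Lactobacillaceae")
  fam <- assign_fam(fam, c(3, 61:120), "Lachnospiraceae")
  fam <- assign_fam(fam, 121:160, "Ruminococcaceae")
  fam <- assign_fam(fam, 161:180, "Erysipelotrichaceae")
  tibble(otu = paste0("OTU_", seq_len(n_otus)), family = fam)
}

#' Default taxon-to-metabolite coupling coefficients
#'
#' Per-OTU log-linear coefficients on standardized log1p densities. Propionate
#' is driven by the three planted *Muribaculaceae* OTUs (`OTU_1`, `OTU_4`,
#' `OTU_5`); butyrate and acetate by *Lachnospiraceae* OTUs; lactate
#' positively by the *Lactobacillaceae* `OTU_2` and negatively by two butyrate
#' producers (lactate cross-feeding).
#'
#' @return named list of named numeric vectors.
#' @export
default_metabolite_coefficients <- function() {
  list(propionate = c(OTU_1 = 0.45, OTU_4 = 0.45, OTU_5 = 0.30),
       butyrate   = c(OTU_3 = 0.40, OTU_61 = 0.25, OTU_62 = 0.25),
       acetate    = c(OTU_3 = 0.25, OTU_63 = 0.25),
       lactate    = c(OTU_2 = 0.60, OTU_61 = -0.15, OTU_62 = -0.15),
       succinate  = numeric(0),
       glucose    = numeric(0))
}

#' Generate the factorial cohort design
#'
#' Full factorial over 3 sites (TJL, UM, UT), 2 sexes and 2 treatments with
#' `n_per_cell` mice per cell. Each sampled mouse comes from its own cage and
#' is sampled at an age uniform on 762 to 973 days.
#'
#' @param n_per_cell mice per design cell (12 gives the canonical 144).
#' @param seed integer seed; identical seeds give identical designs.
#' @return tibble with `mouse_id`, `site`, `sex`, `treatment`, `cage_id`,
#'   `sampling_age` (days).
#' @export
generate_design <- function(n_per_cell = 12, seed = NULL) {
  if (length(n_per_cell) != 1 || is.na(n_per_cell) || n_per_cell < 1) {
    abort("`n_per_cell` must be a positive integer")
  }
  n_per_cell <- as.integer(n_per_cell)
  with_seed(seed, {
    grid <- tidyr::expand_grid(site = c("TJL", "UM", "UT"),
                               sex = c("M", "F"),
                               treatment = c("control", "ACA"),
                               rep = seq_len(n_per_cell))
    n <- nrow(grid)
    grid |>
      dplyr::mutate(mouse_id = sprintf("mouse_%03d", seq_len(n)),
                    cage_id = sprintf("cage_%03d", sample.int(10L * n, n)),
                    sampling_age = round(runif(n, 762, 973))) |>
      dplyr::select("mouse_id", "site", "sex", "treatment", "cage_id", "sampling_age")
  })
}

#' Generate latent absolute OTU densities
#'
#' Log-normal per-OTU baseline densities (16S copies per gram) with
#' site-specific offsets. Under treatment the site's bloom OTU is multiplied
#' by `bloom_fold` and the other *Muribaculaceae* OTUs by
#' `muribaculaceae_other_fold`. Site-restricted OTUs are essentially absent
#' outside their resident site.
#'
#' @param design design tibble from [generate_design()].
#' @param params an `mb_params` object.
#' @param seed integer seed.
#' @return wide tibble, `mouse_id` plus one numeric column per OTU, with unit
#'   attribute `copies_per_g`.
#' @export
generate_community <- function(design, params = cohort_params(), seed = NULL) {
  sites <- unique(design$site)
  missing_sites <- setdiff(sites, names(params$bloom_otu_by_site))
  if (length(missing_sites) > 0) {
    abort(paste0("`bloom_otu_by_site` has no entry for site(s): ",
                 paste(missing_sites, collapse = ", ")))
  }
  otus <- paste0("OTU_", seq_len(params$n_otus))
  fam <- default_taxonomy(params$n_otus)
  with_seed(seed, {
    base <- params$log_mean + rnorm(params$n_otus, 0, params$otu_log_sd)
    names(base) <- otus
    # focal taxa get fixed (not drawn) baselines so their dominance matches
    # the real community structure regardless of the seed
    boost <- params$baseline_boost[names(params$baseline_boost) %in% otus]
    base[names(boost)] <- params$log_mean + boost
    site_off <- matrix(rnorm(length(sites) * params$n_otus, 0, params$site_log_sd),
                       nrow = length(sites), dimnames = list(sites, otus))
    n <- nrow(design)
    logd <- matrix(rnorm(n * params$n_otus, 0, params$sample_log_sd),
                   nrow = n, dimnames = list(design$mouse_id, otus))
    logd <- sweep(logd, 2, base, `+`) + site_off[design$site, , drop = FALSE]
    if (params$cage_sd > 0) {
      cage_eff <- rnorm(length(unique(design$cage_id)), 0, params$cage_sd)
      names(cage_eff) <- unique(design$cage_id)
      logd <- logd + cage_eff[design$cage_id]
    }
    dens <- exp(logd)
    for (o in names(params$site_restricted)) {
      if (o %in% otus) {
        off_site <- design$site != params$site_restricted[[o]]
        dens[off_site, o] <- dens[off_site, o] * 1e-6
      }
    }
    treated <- design$treatment == "ACA"
    for (s in sites) {
      b <- params$bloom_otu_by_site[[s]]
      if (!b %in% otus) abort(paste0("bloom OTU ", b, " not among generated OTUs"))
      rows <- treated & design$site == s
      dens[rows, b] <- dens[rows, b] * params$bloom_fold
    }
    murib_other <- setdiff(fam$otu[fam$family == "Muribaculaceae"],
                           unique(unname(params$bloom_otu_by_site)))
    dens[treated, murib_other] <- dens[treated, murib_other] * params$muribaculaceae_other_fold
    set_abund_units(rebuild_id_matrix(dens, design$mouse_id, "mouse_id"),
                    "copies_per_g", "otu")
  })
}

#' Sequence one sample: multinomial reads over endemic taxa plus spike
#'
#' Reads are a single multinomial draw of size `depth` with probabilities
#' proportional to (per-OTU copies/g x sample weight, spike copies/uL x spike
#' volume).
#'
#' @param densities named numeric vector of per-OTU copies per gram.
#' @param weight sample wet weight in grams.
#' @param spike_volume microliters of spike added.
#' @param depth total reads to draw.
#' @param spike_copies_per_uL spike density.
#' @param seed optional integer seed.
#' @return list with `counts` (named integer vector) and `spike_reads`.
#' @export
sequence_sample <- function(densities, weight, spike_volume, depth,
                            spike_copies_per_uL, seed = NULL) {
  if (depth < 1) abort("`depth` must be at least 1")
  if (weight <= 0) abort("`weight` must be strictly positive")
  mass <- c(densities * weight, .spike = spike_copies_per_uL * spike_volume)
  if (all(mass == 0)) {
    abort("degenerate input: all endemic densities zero and no spike material")
  }
  with_seed(seed, {
    reads <- as.integer(rmultinom(1, size = depth, prob = mass))
    names(reads) <- names(mass)
    list(counts = reads[names(densities)], spike_reads = unname(reads[".spike"]))
  })
}

#' Sequence a whole cohort
#'
#' Applies [sequence_sample()] to every row of a latent density table, with
#' per-sample weights and realized depths.
#'
#' @param densities wide density tibble from [generate_community()].
#' @param design design tibble including `weight_g` and `spike_uL` columns.
#' @param params an `mb_params` object.
#' @param seed integer seed.
#' @return list with `counts` (wide tibble of integer reads) and
#'   `spike_reads` (integer vector aligned with design rows).
#' @export
generate_reads <- function(densities, design, params = cohort_params(), seed = NULL) {
  dm <- split_id_matrix(densities, "densities")
  with_seed(seed, {
    n <- nrow(design)
    depth <- round(runif(n, params$depth_range[1], params$depth_range[2]) *
                     params$sequencing_depth)
    counts <- matrix(0L, nrow = n, ncol = ncol(dm$mat),
                     dimnames = dimnames(dm$mat))
    spike_reads <- integer(n)
    for (i in seq_len(n)) {
      s <- sequence_sample(dm$mat[i, ], weight = design$weight_g[i],
                           spike_volume = design$spike_uL[i], depth = depth[i],
                           spike_copies_per_uL = params$spike_copies_per_uL)
      counts[i, ] <- s$counts
      spike_reads[i] <- s$spike_reads
    }
    list(counts = rebuild_id_matrix(counts, dm$ids, "mouse_id"),
         spike_reads = spike_reads, depth = depth)
  })
}

#' Generate taxon-coupled metabolite concentrations
#'
#' Log concentration of each metabolite is a baseline plus optional direct
#' treatment effects, plus the sum of per-OTU coefficients applied to
#' standardized log1p densities, plus a latent factor shared by acetate and
#' butyrate, plus Gaussian noise. Concentrations are exponentiated and hence
#' strictly positive.
#'
#' @param densities wide latent density tibble.
#' @param design design tibble (`treatment` column used).
#' @param params an `mb_params` object.
#' @param seed integer seed.
#' @return tibble `mouse_id` plus one column per metabolite (umol/g).
#' @export
generate_metabolites <- function(densities, design, params = cohort_params(),
                                 seed = NULL) {
  if (params$metabolite_noise_sd < 0) abort("`metabolite_noise_sd` must be non-negative")
  dm <- split_id_matrix(densities, "densities")
  coefs <- params$metabolite_coefficients
  if (is.null(coefs)) coefs <- default_metabolite_coefficients()
  metabolites <- names(params$metabolite_base)
  need <- setdiff(c("acetate", "butyrate", "propionate", "succinate", "lactate", "glucose"),
                  metabolites)
  if (length(need) > 0) {
    abort(paste0("`metabolite_base` must cover: ", paste(need, collapse = ", ")))
  }
  logz <- log1p(dm$mat)
  # standardize within site: couplings reflect local abundance variation, so
  # site-restricted taxa still drive metabolites at their resident site and
  # the planted correlations hold within every site, not just across sites
  z <- matrix(0, nrow = nrow(logz), ncol = ncol(logz), dimnames = dimnames(logz))
  for (s in unique(design$site)) {
    rows <- design$site == s
    zs <- scale(logz[rows, , drop = FALSE])
    zs[, attr(zs, "scaled:scale") == 0] <- 0
    zs[is.na(zs)] <- 0
    z[rows, ] <- zs
  }
  # a site-restricted taxon cannot drive metabolites where it is absent;
  # without this its (unobservable) latent noise would dilute the couplings
  for (o in names(params$site_restricted)) {
    if (o %in% colnames(z)) {
      z[design$site != params$site_restricted[[o]], o] <- 0
    }
  }
  with_seed(seed, {
    n <- nrow(dm$mat)
    shared <- rnorm(n)
    treated <- as.numeric(design$treatment == "ACA")
    out <- matrix(NA_real_, nrow = n, ncol = length(metabolites),
                  dimnames = list(dm$ids, metabolites))
    for (m in metabolites) {
      lc <- rep(params$metabolite_base[[m]], n)
      if (m %in% names(params$metabolite_treatment_effects)) {
        lc <- lc + params$metabolite_treatment_effects[[m]] * treated
      }
      cf <- coefs[[m]]
      cf <- cf[names(cf) %in% colnames(z)]
      if (length(cf) > 0) lc <- lc + as.vector(z[, names(cf), drop = FALSE] %*% cf)
      if (m %in% c("acetate", "butyrate")) {
        lc <- lc + params$acetate_butyrate_loading * shared
      }
      out[, m] <- exp(lc + rnorm(n, 0, params$metabolite_noise_sd))
    }
    rebuild_id_matrix(out, dm$ids, "mouse_id")
  })
}

#' Generate left-truncated survival times
#'
#' Death ages follow a Weibull proportional-hazards model whose linear
#' predictor is the sex-specific treatment effect plus the SCFA hazard
#' coefficients applied to standardized concentrations, conditioned on
#' survival past each mouse's sampling age by inverse-transform sampling on
#' the conditional survivor function. Every mouse is dead (event = 1).
#'
#' @param design design tibble (`sex`, `treatment`, `sampling_age`).
#' @param scfa data frame or matrix of standardized (mean 0, sd 1) acetate,
#'   butyrate and propionate columns, aligned with design rows.
#' @param params an `mb_params` object.
#' @param seed integer seed.
#' @return tibble `mouse_id`, `entry`, `time`, `event`.
#' @export
generate_survival <- function(design, scfa, params = cohort_params(), seed = NULL) {
  if (params$weibull_shape <= 0 || params$weibull_scale <= 0) {
    abort("Weibull shape and scale must be strictly positive")
  }
  scfa <- as.matrix(as.data.frame(scfa)[, names(params$hazard_betas), drop = FALSE])
  ms <- apply(scfa, 2, mean)
  ss <- apply(scfa, 2, sd)
  if (any(abs(ms) > 0.2) || any(abs(ss - 1) > 0.2)) {
    warn("`scfa` columns do not look standardized (mean 0, sd 1)")
  }
  lp <- as.vector(scfa %*% params$hazard_betas) +
    params$treatment_loghr[design$sex] * (design$treatment == "ACA")
  with_seed(seed, {
    n <- nrow(design)
    e <- rexp(n)
    entry <- design$sampling_age
    # H(t) = (t/scale)^shape * exp(lp); solve H(t) = H(entry) + E
    t_death <- params$weibull_scale *
      ((entry / params$weibull_scale)^params$weibull_shape + e / exp(lp))^(1 / params$weibull_shape)
    tibble(mouse_id = design$mouse_id, entry = entry,
           time = as.numeric(t_death), event = 1L)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generator: factorial design, latent community, multinomial
#' sequencing with spike-in, taxon-coupled metabolites, and left-truncated
#' survival. A single seed drives one RNG stream from which each stage's
#' sub-seed is derived deterministically, so identical seeds give
#' bit-identical cohorts.
#'
#' @param n_per_cell mice per site x sex x treatment cell.
#' @param params an `mb_params` object.
#' @param seed integer seed.
#' @param mode `"planted"` keeps the effects encoded in `params`; `"null"`
#'   neutralizes them via [null_params()].
#' @return list of class `mb_cohort` with elements `design` (including
#'   `weight_g`, `spike_uL`, `spike_reads`, `death_age`), `counts`,
#'   `taxonomy`, `metabolites`, `params`, `seed`.
#' @export
simulate_cohort <- function(n_per_cell = 12, params = cohort_params(), seed = 1,
                            mode = c("planted", "null")) {
  mode <- match.arg(mode)
  if (mode == "null") params <- null_params(params)
  seeds <- derive_seeds(seed, 6)
  design <- generate_design(n_per_cell, seed = seeds[1])
  design <- with_seed(seeds[2], {
    design |>
      dplyr::mutate(weight_g = runif(dplyr::n(), params$sample_weight_range[1],
                                     params$sample_weight_range[2]),
                    spike_uL = params$spike_volume)
  })
  dens <- generate_community(design, params, seed = seeds[3])
  reads <- generate_reads(dens, design, params, seed = seeds[4])
  metab <- generate_metabolites(dens, design, params, seed = seeds[5])
  scfa_z <- scale(log(as.matrix(metab[, c("acetate", "butyrate", "propionate")])))
  surv <- generate_survival(design, scfa_z, params, seed = seeds[6])
  design$spike_reads <- reads$spike_reads
  design$death_age <- surv$time
  structure(list(design = design, counts = reads$counts,
                 taxonomy = default_taxonomy(params$n_otus),
                 metabolites = metab, params = params, seed = seed),
            class = "mb_cohort")
}

#' @export
print.mb_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$design), "mice,", ncol(x$counts) - 1, "OTUs\n")
  cat("  sites x sex x treatment:",
      paste(dim(table(x$design$site, x$design$sex, x$design$treatment)), collapse = " x "), "\n")
  invisible(x)
}
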