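# Shared synthetic cohorts, generated once per test run and cached.
.cohort_cache <- new.env(parent = emptyenv())

shared_cohort <- function(seed = 42, n_per_cell = 12, mode = "planted") {
  key <- paste(seed, n_per_cell, mode, sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(n_per_cell = n_per_cell,
                                            seed = seed, mode = mode)
  }
  .cohort_cache[[key]]
}

# Smaller, faster settings for replicated null-mode studies.
small_params <- function(...) {
  cohort_params(n_otus = 50, sequencing_depth = 2000, ...)
}

cohort_survival_frame <- function(cohort) {
  d <- cohort$design
  data.frame(entry = d$sampling_age, time = d$death_age, event = 1L,
             treatment = d$treatment, sex = d$sex, site = d$site,
             acetate = cohort$metabolites$acetate,
             butyrate = cohort$metabolites$butyrate,
             propionate = cohort$metabolites$propionate)
}
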