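# Shared fixtures, built in code at load time (fast: ~1s total).

# Default seeded cohort plus the calibrated / RT-aligned feature table.
default_pipeline <- local({
  cache <- NULL
  function(seed = 101L) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    cohort <- generate_cohort(cohort_design(seed = seed))
    cal <- calibrate_cohort(cohort$features, reference_ccs_table(cohort))
    ali <- align_rt(cal$features)
    cache <<- list(seed = seed, cohort = cohort, cal = cal,
                   features = ali$features, alignments = ali$alignments)
    cache
  }
})

# Zero-noise, identity-distortion cohort: observed values equal the
# structural model exactly, so effects are recoverable without tolerance.
noiseless_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cohort <- generate_cohort(cohort_design(seed = 1L), noiseless())
    cal <- calibrate_cohort(cohort$features, reference_ccs_table(cohort))
    ali <- align_rt(cal$features)
    cache <<- list(cohort = cohort, features = ali$features)
    cache
  }
})

all_transformations <- c("plus2CH2", "plusDB_downstream", "plusDB_delta1",
                         "alkenyl_vs_alkyl_isobar")

enumerate_all_pairs <- function(species) {
  do.call(rbind, lapply(all_transformations, function(tr) {
    enumerate_pairs(species, tr)
  }))
}
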