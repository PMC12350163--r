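# Default synthetic cohort (generator defaults, fixed seed) run through the
# full pipeline once per session; shared by the end-to-end checks.
default_cohort_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config()
    cohort <- simulate_cohort(cfg)
    d <- file.path(tempdir(), "dualmark-default-fixture")
    if (!dir.exists(d)) write_fixture(cohort, d)
    out <- file.path(tempdir(), "dualmark-default-out")
    res <- run_pipeline(d, analysis_config(mappability_n = 26L), outdir = out)
    cache <<- list(cfg = cfg, cohort = cohort, dir = d, out = out, res = res)
    cache
  }
})

# Truth-derived expectations on the retained bin set of a pipeline run.
retained_truth <- function(run) {
  tt <- run$cohort$truth
  tt[match(run$res$retained$bin_id, tt$bin_id), ]
}
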