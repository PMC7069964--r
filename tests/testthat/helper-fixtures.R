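# Shared fixtures. Cohorts are small so the unit suite stays fast; the
# acceptance tests use the study-scale configurations directly.

quick_config <- function(seed = 1L, ...) {
  sim_config(n_samples = 200L, n_genes = 40L, n_interactome_edges = 120L,
             seed = seed, ...)
}

# Memoised default pipeline run shared by several tests.
.run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.run_cache$run)) {
    .run_cache$run <- suppressMessages(
      suppressWarnings(run_pipeline(pipeline_config(seed = 1L)))
    )
  }
  .run_cache$run
}

# A small survival data set with a known group effect.
toy_survival <- function(n = 120, hr = 2, seed = 42) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    g <- rbinom(n, 1, 0.5)
    t_event <- rexp(n, rate = 0.02 * hr^g)
    t_cens <- rexp(n, rate = 0.005)
    data.frame(group = g, time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  })
}
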