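# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a desk-scale cohort for unit tests: 120 samples x 2,000 probes
small_config <- function(seed = 1, ...) {
  simulation_config(n_probes = 2000, n_informative = 120,
                    samples_per_entity = 40, n_entity_probes = 60,
                    lump_panel_size = 20, seed = seed, ...)
}

small_cohort <- function(seed = 1) {
  cached(paste0("small_cohort_", seed),
         function() simulate_cohort(small_config(seed = seed)))
}

small_model <- function(seed = 1) {
  cached(paste0("small_model_", seed), function() {
    co <- small_cohort(seed)
    train_purity_model(co$betas, co$truth, purity_config(seed = seed))
  })
}

# a minimal valid beta matrix from a plain vector spec
toy_beta <- function(values, n_probes, n_samples,
                     probe_ids = sprintf("cg%03d", seq_len(n_probes)),
                     sample_ids = sprintf("S%02d", seq_len(n_samples))) {
  matrix(values, nrow = n_probes, ncol = n_samples,
         dimnames = list(probe_ids, sample_ids))
}

toy_purity <- function(purity, source = "SYNTHETIC_TRUTH", group = NULL,
                       sample_ids = sprintf("S%02d", seq_along(purity))) {
  out <- tibble::tibble(sample_id = sample_ids, purity = purity,
                        source = source)
  if (!is.null(group)) out$group <- group
  out
}

# random-sample generator used by the dip property tests: a mix of
# continuous unimodal, bimodal, boundary-heavy and heavily tied shapes
random_dip_sample <- function(n) {
  switch(sample(1:5, 1),
         stats::runif(n),
         stats::rnorm(n),
         c(stats::rnorm(ceiling(n / 2), -2, 0.3),
           stats::rnorm(floor(n / 2), 2, 0.3)),
         stats::rbeta(n, 0.3, 0.3),
         round(stats::runif(n), 1))
}
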