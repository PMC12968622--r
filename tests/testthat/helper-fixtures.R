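# Shared fixtures and caches for the test suite.

ref_fixture <- function() make_reference_parameters()

# random-but-reproducible valid parameter sets around the fixture scale
random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pk_params(cl_f = runif(1, 4, 20), vc_f = runif(1, 25, 90),
              vp_f = runif(1, 15, 80), q_f = runif(1, 3, 25),
              ka = runif(1, 1, 4), d1 = runif(1, 0.2, 2),
              alag1 = runif(1, 0, 0.5))
  })
}

# expensive SSE runs shared between test files (computed once per session)
.sse_cache <- new.env(parent = emptyenv())
shared_sse <- function(id, n_replicates = 100L, base_seed = 101L) {
  key <- paste(id, n_replicates, base_seed, sep = "|")
  if (is.null(.sse_cache[[key]])) {
    .sse_cache[[key]] <- run_sse(load_scenario(id), ref_fixture(),
                                 n_replicates = n_replicates,
                                 base_seed = base_seed)
  }
  .sse_cache[[key]]
}

fim_model <- function(fx = ref_fixture()) {
  list(params = fx$params, omega = fx$omega, sigma = fx$sigma,
       allometry = fx$allometry)
}
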