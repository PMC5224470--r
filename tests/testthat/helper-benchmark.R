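# The default synthetic benchmark (50 hosts of 100 kb, one 20 kb virus per
# host) is expensive enough to build once and share across acceptance tests.
# Seeds are fixed up front; nothing here depends on test outcomes.

.bench_cache <- new.env(parent = emptyenv())

default_benchmark <- function(alpha = 1) {
  key <- paste0("alpha_", alpha)
  if (!exists(key, envir = .bench_cache)) {
    cfg <- simulation_config(alpha = alpha, seed = 20160915 %% 2^31)
    assign(key, simulate_benchmark(cfg), envir = .bench_cache)
  }
  get(key, envir = .bench_cache)
}

default_host_features <- function(alpha = 1) {
  key <- paste0("hf_", alpha)
  if (!exists(key, envir = .bench_cache)) {
    b <- default_benchmark(alpha)
    assign(key, lapply(b$hosts, genome_features, k = 6L, order = 2L),
           envir = .bench_cache)
  }
  get(key, envir = .bench_cache)
}
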