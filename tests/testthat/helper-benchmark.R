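# Desk-scale benchmark runs are expensive (minutes), so the trained
# pipelines are computed once per test session and shared across the
# test files that probe them.

.bench_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.bench_cache[[key]])) .bench_cache[[key]] <- force(expr)
  .bench_cache[[key]]
}

benchmark_run <- function() {
  cached("regular", run_open_set_benchmark(seed = 1))
}

benchmark_oe_run <- function() {
  cached("outlier_exposed", {
    cfg <- benchmark_config(seed = 1, outlier_exposure = TRUE)
    run_open_set_benchmark(seed = 1, config = cfg)
  })
}

benchmark_quality_run <- function() {
  cached("quality", run_quality_benchmark(benchmark_run()$model, seed = 1))
}
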