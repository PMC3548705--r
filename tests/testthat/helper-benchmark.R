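# Shared benchmark fixtures, computed once per test session: the large
# mixture sample and its best-of-500 reference partition are expensive, and
# several acceptance checks reuse them.

.bench_cache <- new.env(parent = emptyenv())

bench_big_sample <- function() {
  if (is.null(.bench_cache$big)) {
    .bench_cache$big <- sampleMixture(benchmarkMixture(), 10000, seed = 101)
  }
  .bench_cache$big
}

bench_reference <- function() {
  if (is.null(.bench_cache$ref)) {
    .bench_cache$ref <- deriveReferencePartition(
      bench_big_sample()$data, k = 10, nRuns = 500, masterSeed = 77)
  }
  .bench_cache$ref
}

bench_small_sample <- function() {
  if (is.null(.bench_cache$small)) {
    .bench_cache$small <- sampleMixture(benchmarkMixture(), 500, seed = 202)
  }
  .bench_cache$small
}
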