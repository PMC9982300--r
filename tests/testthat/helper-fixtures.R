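# Shared fixtures. Heavy benchmark runs are memoised so the acceptance
# blocks that assert different properties of the same runs compute them
# once.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

make_random_series <- function(id = "r1", M = 5, D = 2, seed = 1,
                               label = 0L) {
  set.seed(seed)
  irregular_series(id, cumsum(c(0, rexp(M - 1))),
                   matrix(rnorm(M * D), M, D), label = label)
}

make_random_dataset <- function(n = 8, M_range = c(3, 7), D = 2, seed = 1) {
  set.seed(seed)
  lens <- seq(M_range[1], M_range[2])
  recs <- lapply(seq_len(n), function(i) {
    M <- lens[sample.int(length(lens), 1)]
    irregular_series(sprintf("r%02d", i), cumsum(c(0, rexp(M - 1))),
                     matrix(rnorm(M * D), M, D),
                     label = sample(0:1, 1))
  })
  ccts_dataset(recs)
}

small_model <- function(D = 2, H = 3, K = 2, seed = 7)
  tlstm_params(D, H, K, seed = seed)

get_forgetting_bench <- function()
  memoise_fixture("forgetting_bench", function()
    forgetting_benchmark(seeds = 1:5))

get_staging_bench <- function()
  memoise_fixture("staging_bench", function()
    staging_benchmark(seeds = 1:5))
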