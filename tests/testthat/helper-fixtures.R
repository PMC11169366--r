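# Shared miniature corpus, generated once per test session.

fixture_env <- new.env()

fixture_corpus <- function() {
  if (is.null(fixture_env$manifest)) {
    dir <- file.path(tempdir(), "mdftn-fixture-corpus")
    fixture_env$manifest <- make_test_fixtures(dir, seed = 42L, n_pairs = 10L,
                                               size = 64L)
    fixture_env$dir <- dir
  }
  fixture_env$manifest
}

fixture_dir <- function() {
  fixture_corpus()
  fixture_env$dir
}

# tiny architecture used wherever the full width is not the point
tiny_config <- function(n_sources = 2L) {
  mdftn_config(n_sources = n_sources, base_channels = 4L,
               bottleneck_channels = 8L, n_ftm = 1L)
}

random_batch <- function(side = 16L, n = 2L, seed = 1L) {
  set.seed(seed)
  array(runif(side * side * n), c(side, side, 1L, n))
}
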