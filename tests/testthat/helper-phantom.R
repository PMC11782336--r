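# Shared fixtures: a small, fast phantom configuration for unit tests and
# a cache so expensive phantoms are generated once per test file.

tiny_config <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(20, 16, 26), n_frames = 36,
                                 frame_interval_s = 0.25,
                                 breathing_period_s = 4),
                            list(...))
  do.call(phantom_config, args)
}

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(cfg) {
  key <- paste(deparse(unclass(cfg)), collapse = "")
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- generate_breathing_series(cfg)
  }
  .phantom_cache[[key]]
}

# Independent linear-interpolation percentile (order-statistic form), used
# as the oracle against the package's percentile convention.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
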