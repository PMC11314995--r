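# Deterministic fixtures built in code, plus a cached copy of the standard
# synthetic benchmark shared across test files.

# A noise-free extremity recording whose markers carry known sinusoids.
# amp_xyz gives the per-axis tone amplitude (mm); phase 0, so tones are
# bin-aligned whenever freq * duration is an integer.
make_tone_er <- function(freq = 5, amp_xyz = c(1, 1, 1), duration = 10,
                         fs = 120, n_markers = 1, baseline = c(800, 900, 1000),
                         extremity = "R_Hand", label = NULL) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  one_marker <- sapply(1:3, function(a) {
    baseline[a] + amp_xyz[a] * sin(2 * pi * freq * t)
  })
  dat <- do.call(cbind, replicate(n_markers, one_marker, simplify = FALSE))
  extremity_recording(dat, frame_rate = fs, extremity = extremity,
                      marker_names = paste0("M", seq_len(n_markers)),
                      label = label)
}

# Benchmark dataset and per-family feature tables, computed once per test run.
.bench_cache <- new.env(parent = emptyenv())

get_benchmark <- function() {
  if (is.null(.bench_cache$ds)) .bench_cache$ds <- tremor_benchmark(seed = 1)
  .bench_cache$ds
}

get_benchmark_features <- function(family) {
  key <- paste0("f_", family)
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- tremor_features(get_benchmark(), family)
  }
  .bench_cache[[key]]
}
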