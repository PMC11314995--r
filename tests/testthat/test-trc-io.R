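# TRC / CSV input-output, marker grouping, annotation mapping.

test_that("TRC roundtrip preserves shape, names, rate and values", {
  rec <- simulate_recording(duration_s = 3, marker_map = setNames(
    rep("L_Hand", 2), c("L.Wrist", "L.Thumb.M3")), seed = 4)
  expect_equal(dim(rec$data), c(360L, 6L)) # 3 s x 120 Hz, 2 markers
  path <- withr::local_tempfile(fileext = ".trc")
  write_trc(rec, path)
  back <- suppressMessages(read_trc(path))
  expect_equal(back$marker_names, rec$marker_names)
  expect_equal(back$frame_rate, rec$frame_rate)
  expect_equal(back$data, rec$data, tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(back$data - rec$data)), 1e-6)
})

test_that("a 3 s single-marker file has 360 rows x 3 kinematic columns", {
  er <- make_tone_er(duration = 3, n_markers = 1)
  rec <- recording(er$data, er$frame_rate, er$marker_names)
  path <- withr::local_tempfile(fileext = ".trc")
  write_trc(rec, path)
  back <- suppressMessages(read_trc(path))
  expect_equal(nrow(back$data), 360L)
  expect_equal(ncol(back$data), 3L)
})

test_that("malformed headers and ragged rows are parse errors", {
  path <- withr::local_tempfile(fileext = ".trc")
  writeLines(c("not a trc", "x", "y", "z", "w", ""), path)
  expect_error(read_trc(path), "malformed")

  rec <- recording(matrix(rnorm(30), ncol = 3), 120, "M1")
  write_trc(rec, path)
  lines <- readLines(path)
  lines[9] <- paste(lines[9], "99", sep = "\t") # one extra populated field
  writeLines(lines, path)
  expect_error(suppressMessages(read_trc(path)), "ragged")

  write_trc(rec, path)
  lines <- readLines(path)
  lines[9] <- sub("^(\\d+\t[0-9.]+\t)[-0-9.]+", "\\1oops", lines[9])
  writeLines(lines, path)
  expect_error(suppressMessages(read_trc(path)), "non-numeric")
})

test_that("short gaps are interpolated, long gaps reject the marker", {
  rec <- recording(matrix(seq_len(600), ncol = 3), 120, "M1")
  rec$data[100:110, 2] <- NA # 11 samples < 0.25 s * 120
  filled <- interpolate_gaps(rec)
  expect_false(anyNA(filled$data))
  expect_equal(filled$data[, 2], seq(201, 400), tolerance = 1e-12,
               ignore_attr = TRUE) # linear signal: exact reconstruction

  rec2 <- recording(cbind(matrix(rnorm(600), ncol = 3),
                          matrix(rnorm(600), ncol = 3)), 120, c("M1", "M2"))
  rec2$data[50:120, 5] <- NA # 71 samples > 0.25 s gap in M2
  expect_warning(dropped <- interpolate_gaps(rec2), "M2")
  expect_equal(dropped$marker_names, "M1")
  expect_equal(ncol(dropped$data), 3L)
})

test_that("degenerate recordings cannot be written", {
  rec <- recording(matrix(rnorm(30), ncol = 3), 120, "M1")
  rec$marker_names <- character(0)
  expect_error(write_trc(rec, withr::local_tempfile()), "no markers")
})

test_that("extremity CSV roundtrips and rejects bad input", {
  er <- make_tone_er(freq = 6, duration = 27, n_markers = 3,
                     label = "present")
  path <- withr::local_tempfile(fileext = ".csv")
  write_extremity_csv(er, path)
  back <- suppressMessages(read_extremity_csv(path, extremity = "R_Hand",
                                              label = "present"))
  expect_equal(dim(back$data), c(3240L, 9L)) # 27 s x 120 Hz, 3 markers
  expect_equal(back$data, er$data, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$frame_rate, 120)
  expect_equal(back$label, "present")

  # extremity recovered from a file-name suffix
  path2 <- file.path(withr::local_tempdir(), "trial01_R_Hand.csv")
  write_extremity_csv(er, path2)
  expect_equal(suppressMessages(read_extremity_csv(path2))$extremity, "R_Hand")

  df <- read.csv(path)
  df$M1_X[5] <- "oops"
  write.csv(df, path, row.names = FALSE)
  expect_error(suppressMessages(read_extremity_csv(path, "R_Hand")),
               "non-numeric")
  expect_error(read_extremity_csv(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("split_by_extremity groups the default 60-marker montage into 16", {
  rec <- simulate_recording(duration_s = 3, seed = 2)
  expect_equal(length(rec$marker_names), 60L)
  split <- split_by_extremity(rec)
  expect_length(split, 16L)
  expect_setequal(names(split), tremor_extremities())
  expect_setequal(unlist(lapply(split, `[[`, "marker_names")),
                  rec$marker_names)
  # no marker in two groups and per-group column blocks intact
  expect_equal(sum(vapply(split, function(e) ncol(e$data), 0L)), 180L)
  i <- match("R.Wrist", rec$marker_names)
  expect_equal(split$R_Hand$data[, 1:3],
               rec$data[, (3 * (i - 1) + 1):(3 * i)],
               ignore_attr = TRUE)
})

test_that("single-extremity maps and unmapped markers behave", {
  rec <- recording(matrix(rnorm(360 * 6), ncol = 6), 120, c("A", "B"))
  one <- split_by_extremity(rec, c(A = "L_Hand", B = "L_Hand"))
  expect_length(one, 1L)
  expect_equal(ncol(one$L_Hand$data), 6L)

  expect_warning(part <- split_by_extremity(rec, c(A = "L_Hand")), "B")
  expect_false("B" %in% unlist(lapply(part, `[[`, "marker_names")))
})

test_that("the marker-map YAML roundtrips and matches the shipped default", {
  map <- default_marker_map()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_marker_map(map, path)
  expect_equal(sort(names(read_marker_map(path))), sort(names(map)))
  expect_equal(read_marker_map(path)[names(map)], map)
  shipped <- system.file("extdata", "marker_map.yaml", package = "tremorkit")
  expect_equal(read_marker_map(shipped)[names(map)], map)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("Nose:", "- N1"), bad)
  expect_error(read_marker_map(bad), "unknown extremity")
})

test_that("annotation mapping is total, case-insensitive, and strict", {
  vocab <- names(tremorkit:::annotation_vocabulary())
  out <- map_annotation(vocab)
  expect_length(out, 14L)
  expect_setequal(unique(out), c("absent", "present"))
  # only two categories dichotomise to absent
  expect_equal(sum(out == "absent"), 2L)
  expect_equal(map_annotation("Absent"), "absent")
  expect_equal(map_annotation(
    "Dystonia, dyskinesia, or other abnormal posture or movement"), "absent")
  expect_equal(map_annotation(c("Mild", "not much", "SEVERE", "Other, or no indicator of size")),
               rep("present", 4L))
  expect_error(map_annotation("wobbly"), "wobbly")
})
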