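test_that("EDF write/read round trip preserves structure and samples", {
  set.seed(7)
  rec <- recording(matrix(rnorm(4 * 500, sd = 40), 4), 250,
                   c("F3", "F4", "C3", "C4"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path, "edf")
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$sample_rate_hz, 250)
  expect_equal(n_samples(back), 500)
  quant <- max(abs(rec$data)) / 32767
  expect_lt(max(abs(back$data - rec$data)), 1.01 * quant)
})

test_that("EDF with duplicate signal labels is rejected", {
  rec <- recording(matrix(rnorm(2 * 250), 2), 250, c("A", "B"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  # overwrite the second 16-byte label field with the first label
  con <- file(path, "r+b")
  seek(con, 256L, rw = "write")
  writeChar(formatC("A", width = 16, flag = "-"), con, eos = NULL)
  seek(con, 256L + 16L, rw = "write")
  writeChar(formatC("A", width = 16, flag = "-"), con, eos = NULL)
  close(con)
  expect_error(read_recording(path, "edf"), "duplicate")
})

test_that("matrix+sidecar reader requires a sample rate", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- recording(matrix(rnorm(2 * 100), 2), 100, c("C3", "C4"))
  write_recording_matrix(rec, path)
  back <- read_recording(path, "matrix")
  expect_equal(back$data, rec$data, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(back$channel_labels, c("C3", "C4"))
  jsonlite::write_json(list(start_time_s = 0), paste0(path, ".json"),
                       auto_unbox = TRUE)
  expect_error(read_recording(path, "matrix"), "sample_rate_hz")
})

test_that("scoring reader maps tokens, warns on unknowns, errors when empty", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("W", "N1", "N2"), path)
  sc <- read_scoring(path)
  expect_identical(sc$stages, c("W", "N1", "N2"))
  expect_equal(length(sc$stages), 3)
  writeLines(c("2", "2", "REM"), path)
  expect_identical(read_scoring(path)$stages, c("N2", "N2", "R"))
  writeLines(c("W", "X7"), path)
  expect_warning(sc <- read_scoring(path), "X7")
  expect_identical(sc$stages, c("W", "unknown"))
  writeLines(character(), path)
  expect_error(read_scoring(path), "Empty")
})

test_that("stage lookup follows epoch alignment and unknown beyond scoring", {
  sc <- scoring(c("W", "N2", "N3"), epoch_length_s = 30, offset_s = 10)
  expect_identical(stage_at(sc, c(0, 10, 39.9, 40, 99.9, 100, 500)),
                   c("unknown", "W", "W", "N2", "N3", "unknown", "unknown"))
})

test_that("layout reader parses rows, skips headers, rejects bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,x,y,z", "C3,-0.5,0,0.8", "C4,0.5,0,0.8", "Cz,0,0,1"),
             path)
  lay <- read_layout(path)
  expect_identical(lay$labels, c("C3", "C4", "Cz"))
  expect_equal(unname(lay$positions["Cz", ]), c(0, 0, 1))
  writeLines(c("C3,0,0,1", "C3,0,1,0"), path)
  expect_error(read_layout(path), "Duplicate")
  writeLines(c("C3,0,zero,1"), path)
  expect_error(read_layout(path), "row 1")
})

test_that("distance neighbors: collinear example, all-to-all, symmetry", {
  lay <- electrode_layout(c("a", "b", "c"),
                          rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  nb <- build_neighbors(lay, threshold = 1.5)$neighbor_map
  expect_setequal(nb$b, c("a", "c"))
  expect_identical(nb$a, "b")
  expect_identical(nb$c, "b")
  nb_inf <- build_neighbors(lay, threshold = Inf)$neighbor_map
  expect_true(all(lengths(nb_inf) == 2))
  expect_error(build_neighbors(lay, threshold = -1), "positive")
  # invariance under channel reordering (set-level)
  lay2 <- electrode_layout(c("c", "a", "b"),
                           rbind(c(2, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  nb2 <- build_neighbors(lay2, threshold = 1.5)$neighbor_map
  for (ch in c("a", "b", "c")) expect_setequal(nb2[[ch]], nb[[ch]])
})

test_that("event-table CSV round trip is lossless; malformed input rejected", {
  ev <- event_table(c("C3", "C4"), c(1.2345678, 10), c(2.5, 40.25),
                    c("highamp", "jump"), c("highamp", "jump"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_table(ev, path)
  back <- read_event_table(path)
  expect_equal(back$start_s, ev$start_s, tolerance = 1e-6)
  expect_equal(back$end_s, ev$end_s, tolerance = 1e-6)
  expect_identical(back$channel, ev$channel)
  # empty table -> header-only file
  write_event_table(event_table(), path)
  expect_identical(readLines(path),
                   "channel,start_s,end_s,event_type,detector")
  expect_equal(nrow(read_event_table(path)), 0)
  writeLines(c("channel,start_s,end_s,event_type,detector",
               "C3,5.0,4.0,x,x"), path)
  expect_error(read_event_table(path), "row 1")
  writeLines(c("channel,start_s,end_s,event_type,detector",
               "C3,abc,4.0,x,x"), path)
  expect_error(read_event_table(path), "Malformed")
})

test_that("recording constructor enforces its invariants", {
  expect_error(recording(matrix(0, 2, 10), 250, c("A", "A")), "Duplicate")
  expect_error(recording(matrix(0, 2, 10), -1, c("A", "B")), "positive")
  expect_error(recording(matrix(c(NA, 0), 1, 2), 250, "A"), "finite")
})
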