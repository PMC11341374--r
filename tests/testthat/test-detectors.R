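test_that("default set has nine members with sample-rate adjustments", {
  set250 <- default_detector_set(250)
  expect_length(set250, 9)
  expect_named(set250, c("highamp", "lowamp", "lowfreq", "highfreq", "jump",
                         "flatline", "deviant", "similar", "similar2"))
  expect_equal(set250$highamp$threshold, 300)
  expect_equal(set250$lowamp$min_duration_s, 30)
  expect_equal(set250$highfreq$chain[[1]]$high_hz, 120)
  expect_equal(set250$jump$chain[[1]]$order, 9)
  expect_warning(set125 <- default_detector_set(125), "highfreq")
  expect_equal(set125$flatline$threshold, 2)       # 1 uV scaled to 125 Hz
  expect_equal(set125$jump$chain[[1]]$order, 5)
  expect_warning(set150 <- default_detector_set(150), "highfreq")
  expect_length(set150, 8)
  expect_false("highfreq" %in% names(set150))
})

test_that("detector set serializes to YAML with Table-2 values and restores", {
  set <- default_detector_set(250)
  txt <- detector_set_to_yaml(set)
  for (needle in c("threshold: 300", "threshold: 5", "threshold: 8",
                   "threshold: 25", "min_duration_s: 30",
                   "padding_s: 3", "merge_gap_s: 60", "merge_gap_s: 5",
                   "low_hz: 0.3", "high_hz: 15", "low_hz: 60",
                   "high_hz: 120", "order: 9", "pair_threshold: 0.3",
                   "pair_threshold: 0.9", "pair_threshold: 0.5",
                   "window_s: 30", "window_s: 5")) {
    expect_match(txt, needle, fixed = TRUE)
  }
  back <- detector_set_from_yaml(txt)
  expect_named(back, names(set))
  for (nm in names(set)) {
    expect_equal(back[[nm]]$threshold, set[[nm]]$threshold)
    expect_equal(back[[nm]]$padding_s, set[[nm]]$padding_s)
    expect_equal(back[[nm]]$merge_gap_s, set[[nm]]$merge_gap_s)
  }
})

test_that("highamp flags padded threshold runs, nothing on silence", {
  fs <- 100
  spec <- default_detector_set(250)$highamp
  zero <- recording(matrix(0, 2, 1000), fs, c("a", "b"))
  expect_equal(nrow(run_detector(zero, spec)), 0)
  x <- matrix(0, 2, 1000)
  x[1, 101:150] <- 400
  rec <- recording(x, fs, c("a", "b"))
  ev <- run_detector(rec, spec)
  expect_equal(nrow(ev), 1)
  expect_identical(ev$channel, "a")
  expect_equal(ev$start_s, 0.9)
  expect_equal(ev$end_s, 1.6)
})

test_that("similar flags both members of a duplicated channel pair", {
  set.seed(11)
  fs <- 100
  n <- 90 * fs
  base <- rnorm(n, sd = 20)
  dat <- rbind(base, base, rnorm(n, sd = 20), rnorm(n, sd = 20))
  labs <- c("d1", "d2", "i1", "i2")
  rec <- recording(dat, fs, labs)
  lay <- electrode_layout(labs, gen_layout(4)$positions,
                          stats::setNames(lapply(labs, function(ch)
                            setdiff(labs, ch)), labs))
  ev <- run_detector(rec, default_detector_set(250)$similar, layout = lay)
  expect_setequal(unique(ev$channel), c("d1", "d2"))
  # every full 30 s window flagged, merged into one event spanning them
  for (ch in c("d1", "d2")) {
    sub <- ev[ev$channel == ch, ]
    expect_equal(min(sub$start_s), 0)
    expect_equal(max(sub$end_s), 90)
  }
})

test_that("channelwise detection commutes with channel subsetting", {
  set.seed(5)
  dat <- matrix(rnorm(3 * 2000, sd = 120), 3)
  rec <- recording(dat, 250, c("a", "b", "c"))
  spec <- default_detector_set(250)$highamp
  full <- run_detector(rec, spec)
  sub <- run_detector(subset_channels(rec, c("a", "c")), spec)
  expect_equal(sub, full[full$channel %in% c("a", "c"), ],
               ignore_attr = TRUE)
})

test_that("raising the highamp threshold never increases flagged time", {
  set.seed(6)
  rec <- recording(matrix(rnorm(2 * 3000, sd = 150), 2), 250, c("a", "b"))
  total_flagged <- function(thr) {
    spec <- detector_spec("ha", "channelwise",
                          chain = list(list(op = "abs")),
                          cmp = "gt", threshold = thr,
                          padding_s = 0.1, merge_gap_s = 1)
    ev <- run_detector(rec, spec)
    sum(ev$end_s - ev$start_s)
  }
  durs <- vapply(c(100, 200, 300, 400, 500), total_flagged, 0)
  expect_true(all(diff(durs) <= 1e-9))
})

test_that("detector-set execution is independent, ordered and deterministic", {
  set.seed(8)
  rec <- recording(matrix(rnorm(3 * 2000, sd = 100), 3), 250,
                   c("a", "b", "c"))
  lay <- electrode_layout(c("a", "b", "c"), gen_layout(3)$positions,
                          stats::setNames(lapply(c("a", "b", "c"), function(ch)
                            setdiff(c("a", "b", "c"), ch)), c("a", "b", "c")))
  expect_length(run_detector_set(rec, detector_set(list(), name = "none")), 0)
  set1 <- default_detector_set(250)
  r1 <- suppressWarnings(run_detector_set(rec, set1, layout = lay))
  r2 <- suppressWarnings(run_detector_set(rec, set1, layout = lay))
  expect_identical(r1, r2)
  expect_equal(r1$highamp, run_detector(rec, set1$highamp))
  # pairwise detectors below min_channels are skipped with a warning
  two <- subset_channels(rec, c("a", "b"))
  expect_warning(res <- run_detector(two, set1$deviant, layout = lay),
                 "min_channels")
  expect_null(res)
})

test_that("stage restriction masks statistics and event emission", {
  fs <- 100
  x <- matrix(0, 1, 120 * fs)
  x[1, (10 * fs):(11 * fs)] <- 400    # within epoch 0 (W)
  x[1, (70 * fs):(71 * fs)] <- 400    # within epoch 2 (N2)
  rec <- recording(x, fs, "a")
  sc <- scoring(c("W", "N1", "N2", "N2"), 30)
  spec <- detector_spec("ha", "channelwise", chain = list(list(op = "abs")),
                        cmp = "gt", threshold = 300, stages = "N2")
  ev <- run_detector(rec, spec, scoring = sc)
  expect_equal(nrow(ev), 1)
  expect_true(ev$start_s >= 60)
})
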