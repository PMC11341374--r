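test_that("spline kernel is symmetric and matches the Legendre oracle", {
  skip_if_not_installed("pracma")
  lay <- gen_layout(12)
  pos <- unit_positions <- lay$positions   # already unit-norm, centered below
  upos <- sleepscrub:::unit_positions(pos)
  params <- spline_params()
  g <- spline_g_matrix(upos, params = params)
  expect_equal(g, t(g), tolerance = 1e-14)
  want <- oracle_g_matrix(upos, upos, params$order_m,
                          params$n_legendre_terms)
  expect_lt(max(abs(g - want)), 1e-12)
  expect_error(
    sleepscrub:::unit_positions(rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0))),
    "zero-norm")
})

test_that("interpolation reproduces constant fields exactly", {
  lay <- gen_layout(16)
  for (n_bad in c(1, 5, 13)) {           # up to n - 3 bad channels
    bad <- seq_len(n_bad)
    good <- setdiff(1:16, bad)
    seg <- matrix(rep(c(3.5, -1.25, 0, 42), each = 16), 16, 4)
    out <- interpolate_channels(seg, good, bad, lay$positions)
    expect_lt(max(abs(out[bad, ] - seg[bad, ])), 1e-9)
    expect_identical(out[good, ], seg[good, ])
  }
})

test_that("a duplicated electrode position is reproduced as lambda -> 0", {
  lay <- gen_layout(16)
  pos <- rbind(lay$positions, lay$positions[5, ])  # channel 17 == channel 5
  set.seed(10)
  seg <- matrix(rnorm(17 * 3), 17, 3)
  out <- interpolate_channels(seg, good_idx = 1:16, bad_idx = 17, pos,
                              spline_params(regularization_lambda = 1e-12))
  expect_lt(max(abs(out[17, ] - seg[5, ])), 1e-6)
})

test_that("leave-one-out recovery of a smooth dipolar field within 10% RMS", {
  lay <- gen_layout(32)
  upos <- sleepscrub:::unit_positions(lay$positions)
  dipole <- c(0.2, -0.1, 0.6)
  field <- as.numeric(upos %*% dipole) + 0.3 * (upos[, 3])^2
  errs <- vapply(1:32, function(leave) {
    out <- interpolate_channels(matrix(field, 32, 1), setdiff(1:32, leave),
                                leave, lay$positions)
    out[leave, 1] - field[leave]
  }, 0)
  rel_rms <- sqrt(mean(errs^2)) / sqrt(mean(field^2))
  expect_lt(rel_rms, 0.10)
})

test_that("interpolation is linear in the data", {
  lay <- gen_layout(16)
  set.seed(12)
  seg <- matrix(rnorm(16 * 10), 16, 10)
  out1 <- interpolate_channels(seg, 4:16, 1:3, lay$positions)
  out2 <- interpolate_channels(3.7 * seg, 4:16, 1:3, lay$positions)
  expect_equal(out2, 3.7 * out1, tolerance = 1e-10)
})

test_that("too few clean channels raises a NotRepairable condition", {
  lay <- gen_layout(4)
  seg <- matrix(rnorm(4 * 5), 4, 5)
  expect_error(interpolate_channels(seg, 1:2, 3:4, lay$positions),
               class = "scrub_not_repairable")
})

test_that("grid-driven repair: identity, fixed values, locality", {
  set.seed(13)
  lay <- build_neighbors(gen_layout(8), threshold = Inf)
  rec <- recording(matrix(rnorm(8 * 2500, sd = 20), 8), 250, lay$labels)
  allf <- artifact_grid(matrix(FALSE, 8, 2), lay$labels, 5, 10)
  out <- repair_by_grid(rec, allf, lay, "spline")
  expect_identical(out$recording$data, rec$data)
  vals <- matrix(FALSE, 8, 2, dimnames = list(lay$labels, NULL))
  vals[2, 1] <- TRUE
  grid <- artifact_grid(vals, lay$labels, 5, 10)
  nanout <- repair_by_grid(rec, grid, lay, "nan")
  expect_true(all(is.na(nanout$recording$data[2, 1:1250])))
  expect_false(anyNA(nanout$recording$data[2, 1251:2500]))
  expect_false(anyNA(nanout$recording$data[-2, ]))
  zout <- repair_by_grid(rec, grid, lay, "zero")
  expect_equal(sum(zout$recording$data[2, 1:1250]^2), 0)
  # spline: other channels and samples beyond the crossfade are untouched
  sout <- repair_by_grid(rec, grid, lay, "spline", crossfade_s = 0.1)
  expect_identical(sout$recording$data[-2, ], rec$data[-2, ])
  cross_n <- round(0.1 / 2 * 250)
  beyond <- (1250 + cross_n + 1):2500
  expect_identical(sout$recording$data[2, beyond], rec$data[2, beyond])
  expect_false(identical(sout$recording$data[2, 1:1250], rec$data[2, 1:1250]))
  expect_equal(nrow(sout$not_repairable), 0)
})

test_that("segments without enough clean channels are reported, not altered", {
  lay <- build_neighbors(gen_layout(4), threshold = Inf)
  rec <- recording(matrix(rnorm(4 * 1250), 4), 250, lay$labels)
  vals <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 1)
  grid <- artifact_grid(vals, lay$labels, 5, 5)
  out <- repair_by_grid(rec, grid, lay, "spline")
  expect_equal(nrow(out$not_repairable), 2)
  expect_identical(out$recording$data, rec$data)
})

test_that("spline repair reduces the error of a corrupted smooth field", {
  lay <- build_neighbors(gen_layout(16), threshold = Inf)
  upos <- sleepscrub:::unit_positions(lay$positions)
  t_s <- seq(0, 5 - 1 / 250, by = 1 / 250)
  smooth <- outer(as.numeric(upos %*% c(0.5, 0.2, 0.8)),
                  10 * sin(2 * pi * 1.3 * t_s))
  corrupted <- smooth
  corrupted[3, ] <- 500
  rec <- recording(corrupted, 250, lay$labels)
  vals <- matrix(FALSE, 16, 1, dimnames = list(lay$labels, NULL))
  vals[3, 1] <- TRUE
  out <- repair_by_grid(rec, artifact_grid(vals, lay$labels, 5, 5), lay,
                        "spline")
  err_before <- sqrt(mean((corrupted[3, ] - smooth[3, ])^2))
  err_after <- sqrt(mean((out$recording$data[3, ] - smooth[3, ])^2))
  expect_lt(err_after, 0.1 * err_before)
})
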