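chans4 <- c("c1", "c2", "c3", "c4")

test_that("event-to-grid conversion follows segment overlap rules", {
  g0 <- events_to_grid(event_table(), chans4, 60)
  expect_false(any(g0$values))
  expect_equal(g0$n_segments, 12)
  ev <- event_table("c1", 0, 5, "x", "x")
  g1 <- events_to_grid(ev, chans4, 60)
  expect_true(g1$values["c1", 1])
  expect_equal(sum(g1$values), 1)
  ev2 <- event_table("c2", 4.9, 5.1, "x", "x")
  g2 <- events_to_grid(ev2, chans4, 60)
  expect_true(all(g2$values["c2", 1:2]))
  expect_equal(sum(g2$values), 2)
  expect_error(events_to_grid(event_table("zz", 0, 1, "x", "x"), chans4, 60),
               "unknown channels")
  # strict > on the overlap proportion
  g3 <- events_to_grid(ev, chans4, 60, element_min_proportion = 1)
  expect_false(any(g3$values))          # overlap 5 s is not > 5 s
  g4 <- events_to_grid(ev2, chans4, 60, element_min_proportion = 0.02)
  expect_false(any(g4$values))          # 0.1 s is not > 0.1 s
  # the final partial segment uses its true duration
  g5 <- events_to_grid(event_table("c1", 60, 62, "x", "x"), chans4, 62,
                       element_min_proportion = 0.3)
  expect_true(g5$values["c1", 13])      # 2 s overlap > 0.3 * 2 s
})

test_that("global-channel events mark all channels", {
  ev <- event_table(GLOBAL_CHANNEL, 10, 20, "ref", "ref")
  g <- events_to_grid(ev, chans4, 60)
  expect_true(all(g$values[, 3:4]))
})

test_that("pooling is an element-wise OR with monotone behavior", {
  set.seed(2)
  a <- artifact_grid(matrix(runif(40) < 0.3, 4, 10), chans4)
  b <- artifact_grid(matrix(runif(40) < 0.3, 4, 10), chans4)
  allf <- artifact_grid(matrix(FALSE, 4, 10), chans4)
  expect_equal(pool_grids(list(a = a))$values, a$values)
  expect_equal(pool_grids(list(a = a, z = allf))$values, a$values)
  pooled <- pool_grids(list(a = a, b = b))
  expect_true(all(pooled$values >= a$values))
  expect_true(all(pooled$values >= b$values))
})

test_that("spatial expansion adds surrounded channels only", {
  nb <- list(c1 = c("c2", "c3", "c4", "c5"), c2 = "c1", c3 = "c1",
             c4 = "c1", c5 = "c1")
  chans5 <- paste0("c", 1:5)
  vals <- matrix(FALSE, 5, 2, dimnames = list(chans5, NULL))
  vals[c("c2", "c3", "c4"), 1] <- TRUE   # 3 of c1's 4 neighbors
  basic <- artifact_grid(vals, chans5)
  sp <- spatial_expand(basic, nb, 0.75)
  expect_true(sp$values["c1", 1])
  expect_equal(sum(sp$values), 1)
  expect_false(any(spatial_expand(basic, nb, NULL)$values))  # OFF
  # already-artifactual channels are not in the additions grid
  expect_false(any(sp$values[c("c2", "c3", "c4"), 1]))
  # isolated channel never added
  nb_iso <- c(nb, list(c6 = character()))
  vals6 <- rbind(vals, c6 = c(FALSE, FALSE))
  sp6 <- spatial_expand(artifact_grid(vals6, c(chans5, "c6")), nb_iso, 0.1)
  expect_false(any(sp6$values["c6", ]))
})

test_that("segment rejection applies >= on the channel fraction", {
  vals <- matrix(FALSE, 64, 3)
  vals[1:16, 2] <- TRUE
  g <- artifact_grid(vals, paste0("e", 1:64))
  expect_equal(reject_segments(g, 0.25), c(FALSE, TRUE, FALSE))
  expect_equal(reject_segments(g, NULL), rep(FALSE, 3))
  allf <- artifact_grid(matrix(FALSE, 4, 5), chans4)
  expect_false(any(reject_segments(allf, 0.01)))
})

test_that("temporal expansion uses non-rejected segments only", {
  vals <- matrix(FALSE, 2, 100, dimnames = list(c("a", "b"), NULL))
  vals["a", 1:30] <- TRUE                    # 30 of 100 artifactual
  g <- artifact_grid(vals, c("a", "b"), duration_s = 500)
  te <- temporal_expand(g, rep(FALSE, 100), 0.25)
  expect_true(all(te$values["a", 31:100]))   # additions only
  expect_false(any(te$values["a", 1:30]))
  expect_false(any(te$values["b", ]))
  expect_false(any(temporal_expand(g, rep(FALSE, 100), NULL)$values))
  # a channel artifactual only within rejected segments is not expanded
  rej <- rep(FALSE, 100); rej[1:30] <- TRUE
  te2 <- temporal_expand(g, rej, 0.25)
  expect_false(any(te2$values))
})

test_that("repair composition subtracts rejection and is idempotent", {
  set.seed(4)
  basic <- artifact_grid(matrix(runif(40) < 0.4, 4, 10), chans4)
  spatial <- artifact_grid(matrix(FALSE, 4, 10), chans4)
  temporal <- artifact_grid(matrix(FALSE, 4, 10), chans4)
  rej <- rep(FALSE, 10); rej[3] <- TRUE
  rep1 <- compose_repair(basic, spatial, temporal, rej)
  expect_false(any(rep1$values[, 3]))
  norej <- compose_repair(basic, spatial, temporal, rep(FALSE, 10))
  expect_equal(norej$values, basic$values)
  rep2 <- compose_repair(rep1, spatial, temporal, rej)
  expect_equal(rep2$values, rep1$values)
})

test_that("grid summary percentages and stage partition identity hold", {
  vals <- matrix(FALSE, 4, 12, dimnames = list(chans4, NULL))
  vals["c1", ] <- TRUE
  gs <- build_grid_set(list(d = grid_to_events(artifact_grid(vals, chans4))),
                       chans4, 60)
  sc <- scoring(c("N2", "N3"), 30)
  sm <- grid_summary(gs, sc)
  expect_equal(sm$percent[sm$measure == "basic" & sm$stage == "all"], 25)
  st <- sm[sm$measure == "basic" & sm$stage != "all", ]
  expect_equal(sum(st$percent * st$n_segments) / 12,
               sm$percent[sm$measure == "basic" & sm$stage == "all"])
  allf <- build_grid_set(list(), chans4, 60)
  sm0 <- grid_summary(allf, sc)
  expect_true(all(sm0$percent == 0))
  gl <- glance(allf)
  expect_equal(gl$basic_pct, 0)
  expect_equal(gl$n_segments, 12)
})

test_that("grid/event round trip and run coalescing", {
  set.seed(9)
  vals <- matrix(runif(48) < 0.4, 4, 12, dimnames = list(chans4, NULL))
  g <- artifact_grid(vals, chans4, 5, 60, origin = "basic")
  back <- events_to_grid(grid_to_events(g), chans4, 60, origin = "basic")
  expect_equal(back$values, g$values)
  ev <- grid_to_events(artifact_grid(
    matrix(c(TRUE, TRUE, FALSE, TRUE), 1, 4), "c1", 5, 20))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start_s, c(0, 15))
  expect_equal(ev$end_s, c(10, 20))
  expect_equal(nrow(grid_to_events(artifact_grid(matrix(FALSE, 2, 3),
                                                 c("a", "b")))), 0)
})

test_that("five-step grid algebra matches the brute-force oracle", {
  set.seed(123)
  lay <- build_neighbors(gen_layout(8), threshold = 1.2)
  thresholds <- c(0, 0.25, 0.5, 0.75, 1)
  for (i in 1:40) {
    vals <- matrix(runif(160) < runif(1, 0.05, 0.6), 8, 20,
                   dimnames = list(lay$labels, NULL))
    for (thr in thresholds) {
      params <- grid_params(spatial_threshold = thr,
                            rejection_threshold = thr,
                            temporal_threshold = thr)
      basic <- artifact_grid(vals, lay$labels, 5, 100, "d")
      gs <- build_grid_set(list(d = grid_to_events(basic)), lay$labels, 100,
                           params, lay)
      want <- oracle_grid_steps(vals, lay$neighbor_map, lay$labels,
                                thr, thr, thr)
      expect_equal(unname(gs$spatial$values), unname(want$spatial))
      expect_equal(unname(gs$rejection), want$reject)
      expect_equal(unname(gs$temporal$values), unname(want$temporal))
      expect_equal(unname(gs$repair$values), unname(want$repair))
      expect_false(any(gs$repair$values[, gs$rejection]))
    }
  }
})

test_that("pipeline is monotone in detector output", {
  set.seed(31)
  params <- grid_params(rejection_threshold = 0.25)
  ev1 <- random_events(chans4, 100, 10)
  ev2 <- dplyr::bind_rows(ev1, random_events(chans4, 100, 5))
  g1 <- build_grid_set(list(d = ev1), chans4, 100, params)
  g2 <- build_grid_set(list(d = ev2), chans4, 100, params)
  expect_true(mean(g2$basic$values) >= mean(g1$basic$values))
  expect_true(sum(g2$rejection) >= sum(g1$rejection))
})
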