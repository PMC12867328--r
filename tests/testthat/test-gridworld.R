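test_that("world construction labels walls by side with horizontal corners", {
  w <- empty_world(20, 20)
  codes <- cell_codes()
  expect_equal(w$cells[5, 20], codes[["WALL_N"]])
  expect_equal(w$cells[5, 1], codes[["WALL_S"]])
  expect_equal(w$cells[1, 5], codes[["WALL_W"]])
  expect_equal(w$cells[20, 5], codes[["WALL_E"]])
  # corners take the horizontal wall label
  expect_equal(w$cells[1, 20], codes[["WALL_N"]])
  expect_equal(w$cells[20, 1], codes[["WALL_S"]])
  expect_true(all(w$cells[2:19, 2:19] == codes[["EMPTY"]]))
})

test_that("turning changes only heading and forward moves only position", {
  w <- empty_world(10, 10, reward = c(8, 8))
  s <- agent_state(4, 4, "N")
  r <- step(w, s, "TURN_CW_90")
  expect_equal(c(r$state$x, r$state$y, r$state$d), c(4, 4, 1))
  expect_equal(r$reward, 0)
  r <- step(w, s, "TURN_180")
  expect_equal(r$state$d, 2)
  r <- step(w, s, "TURN_CCW_90")
  expect_equal(r$state$d, 3)
  r <- step(w, s, "GO_FORWARD")
  expect_equal(c(r$state$x, r$state$y, r$state$d), c(4, 5, 0))
  expect_false(r$done)
})

test_that("blocked forward moves are no-ops and reward entry terminates", {
  w <- empty_world(10, 10, reward = c(8, 8))
  # facing the north wall from just below it
  s <- agent_state(4, 8, "N")
  r <- step(w, s, "GO_FORWARD")
  expect_equal(c(r$state$x, r$state$y, r$state$d), c(4, 8, 0))
  # stepping onto the reward
  s <- agent_state(8, 7, "N")
  r <- step(w, s, "GO_FORWARD")
  expect_true(r$done)
  expect_equal(r$reward, 1)
  expect_error(step(w, s, 7), "invalid action")
  expect_error(step(w, agent_state(0, 0, 0), 0), "not on a traversable")
})

test_that("action-frame bijection matches the worked compass examples", {
  acts <- action_sets()
  # facing East, "North" requires an anticlockwise quarter turn
  expect_equal(rotate_action("E", "NORTH"), acts$ego[["TURN_CCW_90"]])
  # facing North, "North" is go-forward
  expect_equal(rotate_action("N", "NORTH"), acts$ego[["GO_FORWARD"]])
  # bijection law over all (d, a)
  for (d in 0:3) {
    expect_equal(sort(vapply(0:3, function(a) rotate_action(d, a),
                             integer(1))), 0:3)
    for (a in 0:3)
      expect_equal(inverse_rotate_action(d, rotate_action(d, a)), a)
  }
})

test_that("ego view geometry: empty world, walls ahead, own-row layout", {
  w <- empty_world(13, 13)
  v <- ego_view(w, agent_state(6, 6, "N"), H = 2)
  expect_equal(dim(v), c(3, 5))
  expect_true(all(v == cell_codes()[["EMPTY"]]))
  # one cell from the north boundary, facing it: whole far row is WALL_N
  v <- ego_view(w, agent_state(6, 10, "N"), H = 2)
  expect_true(all(v[3, ] == cell_codes()[["WALL_N"]]))
  # heading-aligned frames: same cell, all four directions, empty world
  for (d in 0:3)
    expect_true(all(ego_view(w, agent_state(6, 6, d), H = 2) == 0L))
  # the reward is invisible by default and labelled only on request
  wr <- set_reward(w, c(6, 8))
  v <- ego_view(wr, agent_state(6, 6, "N"), H = 2)
  expect_equal(v[3, 3], cell_codes()[["EMPTY"]])
  v <- ego_view(wr, agent_state(6, 6, "N"), H = 2, render_reward = TRUE)
  expect_equal(v[3, 3], cell_codes()[["REWARD"]])
})

test_that("views are equivariant under joint rotation of world and heading", {
  # a barrier pattern and its 90 deg-rotated copy inside a 9x9 world; views
  # along correspondingly rotated headings must be identical
  base <- rbind(c(3L, 5L), c(4L, 5L), c(5L, 3L))
  rot <- cbind(8L - base[, 2], base[, 1]) # (x,y) -> (8-y, x): +90 deg about centre
  w1 <- tiny_world(9, 9, barriers = base)
  w2 <- tiny_world(9, 9, barriers = rot)
  p1 <- c(4L, 4L); p2 <- c(8L - p1[2], p1[1])
  for (d in 0:3) {
    v1 <- ego_view(w1, agent_state(p1[1], p1[2], d), H = 2)
    v2 <- ego_view(w2, agent_state(p2[1], p2[2], (d + 3L) %% 4L), H = 2)
    expect_equal(unclass(v1), unclass(v2), ignore_attr = TRUE)
  }
})

test_that("occlusion: a barrier hides the cell behind it", {
  # barrier directly ahead at distance 1; the cell at distance 2 on the same
  # ray is occluded
  w <- tiny_world(9, 9, barriers = rbind(c(4L, 5L)))
  v <- ego_view(w, agent_state(4, 4, "N"), H = 2)
  codes <- cell_codes()
  expect_equal(v[2, 3], codes[["BARRIER"]])
  expect_equal(v[3, 3], codes[["OCCLUDED"]])
})

test_that("line of sight agrees with a dense segment-sampling oracle", {
  set.seed(42)
  w <- tiny_world(9, 9,
                  barriers = rbind(c(3L, 3L), c(5L, 4L), c(2L, 6L), c(6L, 6L)))
  cells <- expand.grid(x = 0:8, y = 0:8)
  for (k in 1:300) {
    from <- unlist(cells[sample.int(nrow(cells), 1), ])
    to <- unlist(cells[sample.int(nrow(cells), 1), ])
    got <- line_of_sight_blocked(w, from, to)
    want <- segment_blocked_dense(w, from, to)
    expect_identical(got, want)
  }
  # trivial cases
  expect_false(line_of_sight_blocked(w, c(4, 4), c(4, 4)))
  expect_false(line_of_sight_blocked(w, c(4, 4), c(4, 5)))
  # a 5-cell straight ray with a barrier mid-ray
  expect_true(line_of_sight_blocked(w, c(5, 2), c(5, 6)))
})

test_that("corner-grazing diagonals do not block", {
  # the diagonal from (3,4) to (5,6) passes exactly through the lattice
  # corner (4,5); the two cells it merely grazes there, (4,4) and (3,5), must
  # not block, while the cell it passes through, (4,5), must
  w1 <- tiny_world(9, 9, barriers = rbind(c(4L, 4L)))
  expect_false(line_of_sight_blocked(w1, c(3, 4), c(5, 6)))
  w2 <- tiny_world(9, 9, barriers = rbind(c(3L, 5L)))
  expect_false(line_of_sight_blocked(w2, c(3, 4), c(5, 6)))
  w3 <- tiny_world(9, 9, barriers = rbind(c(4L, 5L)))
  expect_true(line_of_sight_blocked(w3, c(3, 4), c(5, 6)))
  expect_true(line_of_sight_blocked(w3, c(4, 3), c(4, 7)))
})

test_that("occlusion is monotone along straight rays", {
  w <- tiny_world(11, 11, barriers = rbind(c(5L, 5L), c(6L, 7L)))
  dirs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 2), c(2, 1), c(-1, 1))
  for (i in seq_len(nrow(dirs))) {
    dd <- dirs[i, ]
    for (sx in 1:9) for (sy in 1:9) {
      blocked_seen <- FALSE
      for (k in 1:9) {
        tx <- sx + k * dd[1]; ty <- sy + k * dd[2]
        if (tx < 0 || ty < 0 || tx > 10 || ty > 10) break
        b <- line_of_sight_blocked(w, c(sx, sy), c(tx, ty))
        if (blocked_seen) expect_true(b)
        blocked_seen <- blocked_seen || b
      }
    }
  }
})

test_that("reachable_set agrees with recursive flood fill on small worlds", {
  w <- empty_world(20, 20)
  expect_equal(nrow(reachable_set(w, c(1, 1))), 324)
  # exhaustive check over random small worlds
  set.seed(7)
  for (k in 1:20) {
    wk <- empty_world(8, 8)
    obs <- which(matrix(stats::runif(36) < 0.3, 6, 6), arr.ind = TRUE)
    wk$cells[obs + 1L] <- cell_codes()[["BARRIER"]]
    starts <- which(wk$cells[2:7, 2:7] == 0L, arr.ind = TRUE)
    if (!nrow(starts)) next
    st <- starts[1, ]
    got <- reachable_set(wk, st)
    want <- flood_fill_reachable(wk, st)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE])
  }
  # a wall fully bisecting the interior: only the start's component remains
  wb <- empty_world(8, 8)
  wb$cells[5, 2:7] <- cell_codes()[["BARRIER"]] # column x = 4
  expect_equal(nrow(reachable_set(wb, c(1, 1))), 3 * 6)
  expect_error(reachable_set(wb, c(4, 4)), "not traversable")
})

test_that("world JSON serialisation round-trips exactly", {
  set.seed(3)
  p <- generator_params("ALIGNED_FIXED")
  w <- generate_barrier_world(p, reward_corner(20, 20, "TR"))
  path <- withr::local_tempfile(fileext = ".json")
  write_world(w, path)
  w2 <- read_world(path)
  expect_identical(w2$cells, w$cells)
  expect_identical(w2$reward, w$reward)
  expect_identical(w2$footprint, w$footprint)
  cv <- w$cavity[order(w$cavity[, 1], w$cavity[, 2]), ]
  cv2 <- w2$cavity[order(w2$cavity[, 1], w2$cavity[, 2]), ]
  expect_identical(unname(cv2), unname(cv))
})
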