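test_that("codebook encoding is stable, injective and reconstructible", {
  cb <- ego_codebook(H = 2)
  w <- empty_world(8, 8)
  v1 <- ego_view(w, agent_state(3, 3, "N"), H = 2)
  v2 <- ego_view(w, agent_state(3, 3, "E"), H = 2)
  i1 <- encode_view(cb, v1)
  expect_identical(encode_view(cb, v1), i1)
  # same view from an aliased location maps to the same index
  expect_identical(encode_view(cb, ego_view(w, agent_state(4, 4, "N"), H = 2)),
                   i1)
  v2m <- unclass(v2); v2m[2, 2] <- cell_codes()[["BARRIER"]]
  expect_false(encode_view(cb, v2) == encode_view(cb, v2m))
  expect_identical(unclass(view_from_index(cb, i1)), unclass(v1),
                   ignore_attr = TRUE)
  expect_error(view_from_index(cb, 99), "out of range")
})

test_that("enumerated view count matches brute-force enumeration", {
  w <- empty_world(8, 8) # 6x6 interior
  cb <- ego_codebook(H = 2)
  vt <- enumerate_world_views(w, cb)
  keys <- character()
  for (x in 1:6) for (y in 1:6) for (d in 0:3)
    keys <- c(keys, paste(as.integer(ego_view(w, agent_state(x, y, d), H = 2)),
                          collapse = ","))
  expect_equal(n_views(cb), length(unique(keys)))
  expect_true(all(vt >= 0))
  expect_true(all(sort(unique(vt)) == 0:(n_views(cb) - 1L)))
})

test_that("closed-form SR: row sums, gamma limits, action consistency", {
  # 2-state symmetric chain
  T2 <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  sr <- uniform_policy_sr(T2, 0.5)
  expect_equal(rowSums(sr$M_s), rep(1 / (1 - 0.5), 2))
  # gamma -> 0 recovers the one-step matrix
  sr0 <- uniform_policy_sr(T2, 1e-9)
  expect_equal(sr0$M_s, T2, tolerance = 1e-6)
  # action-conditioned tables: M_a = T_a (I + gamma M_s)
  Ta <- list(matrix(c(1, 1, 0, 0), 2, 2), matrix(c(0, 0, 1, 1), 2, 2))
  sr <- uniform_policy_sr(T2, 0.5, Ta)
  expect_equal(sr$M[[1]], Ta[[1]] %*% (diag(2) + 0.5 * sr$M_s))
  expect_error(uniform_policy_sr(matrix(c(1, 0.5, 0, 0.4), 2, 2), 0.5),
               "row-stochastic")
})

test_that("TD updates: zero rate, full-rate substitution, convergence", {
  M <- matrix(0, 3, 3)
  expect_identical(td_update_state_sr(M, 0, 1, 0, 0.9), M)
  M1 <- td_update_state_sr(M, 0, 1, 1, 0.9)
  expect_equal(M1[1, ], c(0, 1, 0)) # zero table, alpha 1: one-hot target
  expect_error(td_update_state_sr(M, 0, 1, -0.1, 0.9), "alpha")
  # full-rate state-action update against a converged state-state table
  T3 <- matrix(1 / 3, 3, 3)
  Ms <- uniform_policy_sr(T3, 0.8)$M_s
  Mlist <- list(matrix(0, 3, 3))
  M2 <- td_update_state_action_sr(Mlist, Ms, 0, 0, 2, 1, 0.8)
  want <- 0.8 * Ms[3, ]; want[3] <- want[3] + 1
  expect_equal(M2[[1]][1, ], want)
  # repeated sweeps over all transitions of a 3-state chain approach the
  # closed form (single-sample sequential sweeps equilibrate within O(alpha))
  Tc <- matrix(c(0, 1, 0,
                 0.5, 0, 0.5,
                 0, 1, 0), 3, 3, byrow = TRUE)
  gamma <- 0.6
  M <- matrix(0, 3, 3)
  for (it in 1:4000) {
    for (s in 0:2) for (s2 in 0:2) {
      if (Tc[s + 1, s2 + 1] > 0)
        M <- td_update_state_sr(M, s, s2, 0.01 * Tc[s + 1, s2 + 1], gamma)
    }
  }
  closed <- uniform_policy_sr(Tc, gamma)$M_s
  expect_equal(M, closed, tolerance = 5e-3)
  # the expected-update sweeps hit the fixed point exactly
  conv <- td_converge_sr(Tc, gamma, tol = 1e-12)
  expect_equal(conv$M_s, closed, tolerance = 1e-9)
})

test_that("allocentric SR init matches a dense inverse on a 5x5 interior", {
  sr <- init_allocentric_sr(0.9, width = 7, height = 7)
  tr <- build_allo_transitions(empty_world(7, 7))
  direct <- tr$T %*% solve(diag(25) - 0.9 * tr$T)
  expect_equal(sr$M_s, direct, tolerance = 1e-10)
  expect_equal(rowSums(sr$M_s), rep(1 / (1 - 0.9), 25))
  # 4-fold symmetry at the centre cell of the empty world
  centre <- 2 + 2 * 5 + 1 # (2,2) of the 0..4 interior
  row <- matrix(sr$M_s[centre, ], 5, 5)
  expect_equal(row, row[5:1, ], tolerance = 1e-10) # mirror in x
  expect_equal(row, t(row), tolerance = 1e-10)     # diagonal
})

test_that("egocentric transition matrices average aliased rows correctly", {
  w <- empty_world(7, 7)
  cb <- ego_codebook(H = 2)
  tr <- build_ego_transitions(list(w), cb)
  expect_equal(rowSums(tr$T), rep(1, n_views(cb)), tolerance = 1e-12)
  for (a in 1:4)
    expect_equal(Matrix::rowSums(tr$T_actions[[a]]), rep(1, n_views(cb)),
                 tolerance = 1e-12)
  # definition check: the row of a view under an action equals the mean over
  # its instantiations of one-hot(next view)
  vt <- tr$view_tables[[1]]
  for (probe in c(vt[(2 + 2 * 5) * 4 + 1], vt[1])) {
    inst <- which(vt == probe) - 1L # positions s*4 + d
    for (a in 0:3) {
      want <- numeric(n_views(cb))
      for (p in inst) {
        s <- p %/% 4L; d <- p %% 4L
        xy <- egosr:::allo_coords(w, s)
        st <- step(w, agent_state(xy[1], xy[2], d), a)
        s2 <- egosr:::allo_index(w, st$state$x, st$state$y)
        v2 <- vt[s2 * 4L + st$state$d + 1L]
        want[v2 + 1L] <- want[v2 + 1L] + 1 / length(inst)
      }
      expect_equal(as.numeric(tr$T_actions[[a + 1]][probe + 1, ]), want,
                   tolerance = 1e-12)
    }
  }
  # single-world task: average equals that world's matrix (idempotent)
  cb2 <- ego_codebook(H = 2)
  tr2 <- build_ego_transitions(list(w), cb2)
  expect_equal(tr$T, tr2$T)
})

test_that("TD-converged SRs match closed forms on small worlds (both frames)", {
  # allocentric frame on a 4x4-interior world with one obstacle: expected-
  # update TD sweeps converge to the closed form exactly; single-sample
  # sequential sweeps get within O(alpha)
  w <- tiny_world(6, 6, barriers = rbind(c(2L, 2L)))
  tr <- build_allo_transitions(w)
  gamma <- 0.9
  conv <- td_converge_sr(tr$T, gamma, tr$T_actions, tol = 1e-12)
  closed <- uniform_policy_sr(tr$T, gamma, tr$T_actions)
  expect_lt(max(abs(conv$M_s - closed$M_s)), 1e-6)
  for (a in 1:4) expect_lt(max(abs(conv$M[[a]] - closed$M[[a]])), 1e-6)
  # egocentric frame: expected-update sweeps on the aliased view chain
  cb <- ego_codebook(H = 2)
  tre <- build_ego_transitions(list(w), cb)
  conv_e <- td_converge_sr(tre$T, 0.8, tre$T_actions, tol = 1e-12)
  closed_e <- uniform_policy_sr(tre$T, 0.8, tre$T_actions)
  expect_lt(max(abs(conv_e$M_s - closed_e$M_s)), 1e-6)
  for (a in 1:4) expect_lt(max(abs(conv_e$M[[a]] - closed_e$M[[a]])), 1e-6)
})

test_that("egocentric SR init: aliased-average fixed point and row sums", {
  set.seed(4)
  p <- generator_params("ALIGNED_FIXED", width = 12, height = 12,
                        barrier_size = 3, attempts = 4)
  task <- generate_task(p, episodes_per_world = 10)
  cb <- ego_codebook(H = 2)
  sr <- init_egocentric_sr(task, 0.95, cb)
  nE <- n_views(cb)
  expect_equal(rowSums(sr$M_s), rep(1 / (1 - 0.95), nE), tolerance = 1e-8)
  # non-negativity and codebook bound
  expect_true(all(sr$M_s >= 0))
  expect_lte(nE, length(task$worlds) * 100 * 4)
})
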