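# Egocentric-view codebook, closed-form uniform-policy SR initialisation, and
# online TD updates for state-state and state-action SRs in both frames.

#' Egocentric view codebook
#'
#' A mutable bijection between observed egocentric views and dense 0-based
#' integer indices. Encoding a previously seen view returns its existing
#' index; new views append. Because distinct world states can produce the same
#' view (aliasing), the number of egocentric states is typically far below the
#' number of `(x, y, d)` states.
#'
#' @param H Horizon of the views this codebook accepts.
#' @return An `ego_codebook` (environment).
#' @export
ego_codebook <- function(H = 2L) {
  cb <- new.env(parent = emptyenv())
  cb$map <- new.env(parent = emptyenv(), size = 4096L)
  cb$keys <- character()
  cb$H <- as.integer(H)
  cb$warned_ce <- FALSE
  class(cb) <- "ego_codebook"
  cb
}

#' @export
print.ego_codebook <- function(x, ...) {
  cat(sprintf("<ego_codebook H=%d, %d views (reported C_E = %d)>\n", x$H,
              n_views(x), c_e_reported(x$H)))
  invisible(x)
}

#' Number of views in a codebook
#' @param codebook An [ego_codebook()].
#' @return Integer count `N_E`.
#' @export
n_views <- function(codebook) length(codebook$keys)

#' Reported egocentric state-space dimension
#'
#' The dimension `2(H+1)(2H+1) - 1` quoted for the egocentric state space;
#' kept as metadata only, since the enumerated count of distinct categorical
#' views is what actually sizes the tables.
#'
#' @param H Horizon.
#' @return Integer.
#' @export
c_e_reported <- function(H) 2L * (H + 1L) * (2L * H + 1L) - 1L

view_key <- function(view) paste(as.integer(view), collapse = ",")

#' Encode a view into a codebook index
#'
#' @param codebook An [ego_codebook()].
#' @param view An `ego_view` matrix (or any integer matrix of cell codes).
#' @return 0-based integer index; new views extend the codebook.
#' @export
encode_view <- function(codebook, view) {
  key <- view_key(view)
  idx <- codebook$map[[key]]
  if (is.null(idx)) {
    idx <- length(codebook$keys)
    assign(key, idx, envir = codebook$map)
    codebook$keys <- c(codebook$keys, key)
    if (!codebook$warned_ce && length(codebook$keys) > c_e_reported(codebook$H)) {
      codebook$warned_ce <- TRUE
      message(sprintf(
        "codebook: enumerated view count (%d) exceeds the reported C_E = %d; tables are sized by the enumerated count",
        length(codebook$keys), c_e_reported(codebook$H)))
    }
  }
  idx
}

#' Reconstruct the view for a codebook index
#' @param codebook An [ego_codebook()].
#' @param index 0-based index.
#' @return An `ego_view` integer matrix.
#' @export
view_from_index <- function(codebook, index) {
  if (index < 0 || index >= n_views(codebook)) abort("index out of range")
  vals <- as.integer(strsplit(codebook$keys[index + 1L], ",", fixed = TRUE)[[1]])
  H <- codebook$H
  structure(matrix(vals, nrow = H + 1L, ncol = 2L * H + 1L),
            class = c("ego_view", "matrix"), H = H)
}

#' Enumerate and encode the egocentric views of a world
#'
#' Visits every traversable `(x, y, d)` state, encodes its occluded view into
#' the (shared, growing) codebook and returns the per-state view index table
#' used by the simulator.
#'
#' @param world A `gridworld`.
#' @param codebook An [ego_codebook()].
#' @return Integer vector of length `N_A * 4`, indexed by
#'   `allo_index * 4 + d`, holding 0-based view indices (`-1` where the cell
#'   is not traversable).
#' @export
enumerate_world_views <- function(world, codebook) {
  H <- codebook$H
  nA <- n_allo_states(world)
  out <- rep(-1L, nA * 4L)
  for (y in 1:(world$height - 2L)) for (x in 1:(world$width - 2L)) {
    if (!is_traversable(world, x, y)) next
    base <- allo_index(world, x, y) * 4L
    for (d in 0:3) {
      v <- ego_view_cpp(world$cells, x, y, d, H, -1L, -1L, FALSE)
      out[base + d + 1L] <- encode_view(codebook, v)
    }
  }
  out
}

#' Closed-form successor representation under a fixed transition matrix
#'
#' For a row-stochastic one-step matrix `T` the fixed point of the
#' next-state-indicator TD update is `M_s = T (I - gamma T)^{-1}`, and the
#' action-conditioned SR is `M_a = T_a (I + gamma M_s)` for each
#' action-conditioned one-step matrix `T_a`. Matrices are in standard
#' orientation (rows = source state).
#'
#' @param T Row-stochastic one-step transition matrix (dense or
#'   `Matrix`-sparse).
#' @param gamma Discount in (0, 1).
#' @param T_actions Optional list of action-conditioned one-step matrices.
#' @return List with `M_s` and (if `T_actions` given) `M` (list of matrices).
#' @export
uniform_policy_sr <- function(T, gamma, T_actions = NULL) {
  if (gamma <= 0 || gamma >= 1) abort("gamma must be in (0, 1)")
  n <- nrow(T)
  Td <- as.matrix(T)
  rs <- rowSums(Td)
  if (any(abs(rs - 1) > 1e-8)) abort("T must be row-stochastic")
  A <- diag(n) - gamma * Td
  M_s <- t(solve(t(A), t(Td))) # T %*% solve(A), via one LU factorisation
  out <- list(M_s = M_s)
  if (!is.null(T_actions)) {
    IgM <- diag(n) + gamma * M_s
    out$M <- lapply(T_actions, function(Ta) as.matrix(Ta %*% IgM))
  }
  out
}

#' Allocentric transition matrices of a world
#'
#' One-step dynamics under a uniformly random allocentric action: each
#' compass direction with probability 1/4, blocked moves self-looping.
#' States are the fixed interior index set; untraversable cells get identity
#' rows (they are never visited).
#'
#' @param world A `gridworld`.
#' @return List with `T` (uniform mixture) and `T_actions` (4 deterministic
#'   matrices in N, E, S, W order), both dense, rows = source.
#' @export
build_allo_transitions <- function(world) {
  nA <- n_allo_states(world)
  T_actions <- lapply(1:4, function(a) matrix(0, nA, nA))
  for (y in 1:(world$height - 2L)) for (x in 1:(world$width - 2L)) {
    s <- allo_index(world, x, y) + 1L
    if (!is_traversable(world, x, y)) {
      for (a in 1:4) T_actions[[a]][s, s] <- 1
      next
    }
    for (a in 1:4) {
      nx <- x + DIR_DX[a]; ny <- y + DIR_DY[a]
      s2 <- if (is_traversable(world, nx, ny)) allo_index(world, nx, ny) + 1L else s
      T_actions[[a]][s, s2] <- 1
    }
  }
  T <- (T_actions[[1]] + T_actions[[2]] + T_actions[[3]] + T_actions[[4]]) / 4
  list(T = T, T_actions = T_actions)
}

#' Initialise the allocentric SR tables
#'
#' Builds the uniform-random-allocentric-action transition matrix on the
#' empty walled world of the given dimensions and applies the closed form.
#'
#' @param gamma_a Allocentric discount.
#' @param width,height World dimensions.
#' @return List with `M_s` (N_A x N_A) and `M` (list of 4 matrices), rows =
#'   source state.
#' @export
init_allocentric_sr <- function(gamma_a = 0.95, width = 20L, height = 20L) {
  tr <- build_allo_transitions(empty_world(width, height))
  uniform_policy_sr(tr$T, gamma_a, tr$T_actions)
}

#' Egocentric transition matrices of a set of worlds
#'
#' Enumerates every traversable `(x, y, d)` state of each world, encodes its
#' view, and builds each world's view-to-view transition matrix under
#' uniformly random egocentric actions; a view aliased at several states
#' contributes the mean of its per-state rows (weighted by instantiation
#' count). Matrices are then averaged across worlds, per view over the worlds
#' in which that view occurs, keeping rows stochastic.
#'
#' @param worlds List of `gridworld`s (e.g. `task$worlds`).
#' @param codebook An [ego_codebook()]; grown in place.
#' @return List with `T` (dense mixture matrix), `T_actions` (4 sparse
#'   matrices in ego-action order), `view_tables` (per-world view index
#'   tables).
#' @export
build_ego_transitions <- function(worlds, codebook) {
  if (!length(worlds)) abort("need at least one world")
  view_tables <- lapply(worlds, enumerate_world_views, codebook = codebook)
  nE <- n_views(codebook)
  # accumulate across worlds: per action, counts of (view -> next view),
  # normalised within world by each view's instantiation count, then averaged
  # over the worlds containing the view
  act_num <- lapply(1:4, function(a) Matrix::Matrix(0, nE, nE, sparse = TRUE))
  present <- numeric(nE)
  for (wi in seq_along(worlds)) {
    world <- worlds[[wi]]
    vt <- view_tables[[wi]]
    nAw <- n_allo_states(world)
    inst <- numeric(nE)
    maxlen <- nAw * 4L
    ii <- lapply(1:4, function(a) integer(maxlen))
    jj <- lapply(1:4, function(a) integer(maxlen))
    k <- 0L
    for (s in 0:(nAw - 1L)) {
      xy <- allo_coords(world, s)
      for (d in 0:3) {
        v <- vt[s * 4L + d + 1L]
        if (v < 0L) next
        inst[v + 1L] <- inst[v + 1L] + 1
        k <- k + 1L
        for (a in 0:3) {
          if (a == 0L) {
            nx <- xy[1] + DIR_DX[d + 1L]; ny <- xy[2] + DIR_DY[d + 1L]
            if (is_traversable(world, nx, ny)) {
              s2 <- allo_index(world, nx, ny); d2 <- d
            } else { s2 <- s; d2 <- d }
          } else { s2 <- s; d2 <- (d + a) %% 4L }
          v2 <- vt[s2 * 4L + d2 + 1L]
          ii[[a + 1L]][k] <- v + 1L
          jj[[a + 1L]][k] <- v2 + 1L
        }
      }
    }
    seen <- inst > 0
    present[seen] <- present[seen] + 1
    rw <- ifelse(seen, 1 / pmax(inst, 1), 0)
    for (a in 1:4) {
      Cw <- Matrix::sparseMatrix(i = ii[[a]][seq_len(k)],
                                 j = jj[[a]][seq_len(k)], x = 1,
                                 dims = c(nE, nE))
      act_num[[a]] <- act_num[[a]] + Matrix::Diagonal(x = rw) %*% Cw
    }
  }
  inv_pres <- Matrix::Diagonal(x = 1 / pmax(present, 1))
  T_actions <- lapply(act_num, function(Mx) methods::as(inv_pres %*% Mx, "CsparseMatrix"))
  T <- as.matrix((T_actions[[1]] + T_actions[[2]] + T_actions[[3]] +
                    T_actions[[4]]) / 4)
  list(T = T, T_actions = T_actions, view_tables = view_tables)
}

#' Initialise the egocentric SR tables from a task
#'
#' Builds the across-world average egocentric transition matrix under
#' uniformly random egocentric actions (see [build_ego_transitions()]) and
#' applies the closed-form uniform-policy SR.
#'
#' @param task An `sr_task` (or list with `$worlds`).
#' @param gamma_e Egocentric discount.
#' @param codebook An [ego_codebook()]; grown in place.
#' @return List with `M_s`, `M` (4 matrices) and `view_tables`.
#' @export
init_egocentric_sr <- function(task, gamma_e = 0.95, codebook = ego_codebook()) {
  tr <- build_ego_transitions(task$worlds, codebook)
  sr <- uniform_policy_sr(tr$T, gamma_e, tr$T_actions)
  sr$view_tables <- tr$view_tables
  sr
}

#' Run TD sweeps to convergence under known transition probabilities
#'
#' Applies the next-state-indicator TD update in expectation: each sweep
#' replaces row `s` by a step toward `sum_s' T[s, s'] (onehot(s') + gamma *
#' M_s[, | s'])` (and likewise for the action-conditioned tables). This is the
#' deterministic limit of the online update rule; unlike single-sample
#' sequential sweeps (whose equilibrium carries an O(alpha) bias), it
#' contracts geometrically to the exact fixed point `T (I - gamma T)^{-1}`.
#'
#' @param T Row-stochastic transition matrix.
#' @param gamma Discount.
#' @param T_actions Optional list of action-conditioned one-step matrices.
#' @param alpha Step size in (0, 1].
#' @param tol Max-norm change at which to stop.
#' @param max_sweeps Sweep cap.
#' @return List with `M_s`, optionally `M`, and `sweeps` used.
#' @export
td_converge_sr <- function(T, gamma, T_actions = NULL, alpha = 1,
                           tol = 1e-10, max_sweeps = 10000L) {
  T <- as.matrix(T)
  n <- nrow(T)
  M <- matrix(0, n, n)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    target <- T + gamma * (T %*% M)
    delta <- alpha * (target - M)
    M <- M + delta
    if (max(abs(delta)) < tol || sweeps >= max_sweeps) break
  }
  out <- list(M_s = M, sweeps = sweeps)
  if (!is.null(T_actions)) {
    out$M <- lapply(T_actions, function(Ta) {
      Ma <- matrix(0, n, n)
      Tad <- as.matrix(Ta)
      for (k in seq_len(max_sweeps)) {
        target <- Tad + gamma * (Tad %*% M)
        d <- alpha * (target - Ma)
        Ma <- Ma + d
        if (max(abs(d)) < tol) break
      }
      Ma
    })
  }
  out
}

#' TD update of a state-state SR
#'
#' After observing the transition `s -> s_next`, moves row `s` toward the
#' next-state-indicator target `onehot(s_next) + gamma * M_s[, | s_next]`.
#' On terminal transitions the bootstrap term is dropped.
#'
#' @param M_s State-state SR matrix, rows = source state.
#' @param s,s_next 0-based state indices.
#' @param alpha Learning rate (>= 0).
#' @param gamma Discount.
#' @param terminal Was this transition into a terminal state?
#' @return The updated matrix.
#' @export
td_update_state_sr <- function(M_s, s, s_next, alpha, gamma,
                               terminal = FALSE) {
  if (alpha < 0) abort("alpha must be >= 0")
  g <- if (terminal) 0 else gamma
  target <- g * M_s[s_next + 1L, ]
  target[s_next + 1L] <- target[s_next + 1L] + 1
  M_s[s + 1L, ] <- M_s[s + 1L, ] + alpha * (target - M_s[s + 1L, ])
  M_s
}

#' TD update of a state-action SR
#'
#' Moves row `(s, a)` toward `onehot(s_next) + gamma * M_s[, | s_next]`,
#' bootstrapping off the state-state table (updated concurrently by
#' [td_update_state_sr()]).
#'
#' @param M List of per-action SR matrices (rows = source state).
#' @param M_s The companion state-state SR.
#' @param s,a,s_next 0-based state and action indices.
#' @inheritParams td_update_state_sr
#' @return The updated list `M`.
#' @export
td_update_state_action_sr <- function(M, M_s, s, a, s_next, alpha, gamma,
                                      terminal = FALSE) {
  if (alpha < 0) abort("alpha must be >= 0")
  g <- if (terminal) 0 else gamma
  target <- g * M_s[s_next + 1L, ]
  target[s_next + 1L] <- target[s_next + 1L] + 1
  Ma <- M[[a + 1L]]
  Ma[s + 1L, ] <- Ma[s + 1L, ] + alpha * (target - Ma[s + 1L, ])
  M[[a + 1L]] <- Ma
  M
}
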