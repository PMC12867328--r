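# Episode/task/paradigm orchestration, metrics (counted steps, hole time,
# occupancy traces), multi-seed aggregation, and ablation sweeps.

#' @importFrom dplyr %>% group_by summarise mutate filter arrange bind_rows
#'   ungroup across left_join n
NULL

world_arrays <- function(agent, world) {
  nA <- n_allo_states(world)
  fwd <- matrix(0L, nA, 4L)
  trav <- logical(nA)
  for (y in 1:(world$height - 2L)) for (x in 1:(world$width - 2L)) {
    s <- allo_index(world, x, y)
    trav[s + 1L] <- is_traversable(world, x, y)
    for (d in 0:3) {
      nx <- x + DIR_DX[d + 1L]; ny <- y + DIR_DY[d + 1L]
      fwd[s + 1L, d + 1L] <- if (trav[s + 1L] &&
                                 is_traversable(world, nx, ny))
        allo_index(world, nx, ny) else s
    }
  }
  reward_idx <- allo_index(world, world$reward[1], world$reward[2])
  starts <- which(trav) - 1L
  starts <- starts[starts != reward_idx]
  list(fwd_next = fwd, reward_idx = reward_idx, start_cells = starts,
       traversable = trav)
}

# Mask of interior cells within Chebyshev distance 1 of a boundary cell.
near_wall_mask <- function(world) {
  nA <- n_allo_states(world)
  xy <- allo_coords(world, 0:(nA - 1L))
  xy[, 1] == 1L | xy[, 1] == world$width - 2L |
    xy[, 2] == 1L | xy[, 2] == world$height - 2L
}

# Mask of interior cells on or within Chebyshev distance 1 of a world's
# barrier footprint (cavity cells are inside the footprint and so included).
barrier_region_mask <- function(world, ref_world = world) {
  nA <- n_allo_states(world)
  out <- logical(nA)
  fp <- which(ref_world$footprint, arr.ind = TRUE) - 1L
  if (!nrow(fp)) return(out)
  for (i in seq_len(nrow(fp))) {
    for (dx in -1:1) for (dy in -1:1) {
      x <- fp[i, 1] + dx; y <- fp[i, 2] + dy
      if (x >= 1L && x <= world$width - 2L && y >= 1L &&
          y <= world$height - 2L)
        out[allo_index(world, x, y) + 1L] <- TRUE
    }
  }
  out
}

cavity_mask <- function(world) {
  nA <- n_allo_states(world)
  out <- logical(nA)
  if (nrow(world$cavity))
    out[allo_index(world, world$cavity[, 1], world$cavity[, 2]) + 1L] <- TRUE
  out
}

run_params_list <- function(agent) {
  cfg <- agent$cfg
  list(gamma_a = cfg$gamma_a, gamma_e = cfg$gamma_e, gamma_q = cfg$gamma_q,
       alpha_a = cfg$alpha_a, alpha_e = cfg$alpha_e, eta = cfg$eta,
       beta1 = cfg$beta1, beta2 = cfg$beta2, eps_adam = cfg$eps_adam,
       epsilon = cfg$epsilon, tau = cfg$tau, step_cap = cfg$step_cap,
       adam_no_sqrt = cfg$adam_no_sqrt,
       variant = variant_code(agent$variant))
}

call_core <- function(agent, world, arrays, region_masks, n_episodes,
                      learn = TRUE, record_traj = FALSE,
                      view_table = NULL) {
  u <- agent_uses(agent)
  use_ego <- u$ego_sr || u$ego_onehot
  if (is.null(view_table))
    view_table <- if (use_ego) grow_agent_for_world(agent, world) else
      rep(-1L, n_allo_states(world) * 4L)
  # the compiled core mutates the agent's tables, weights, moments and step
  # counter in place
  agent$t <- agent$t + 0 # ensure a private, writable copy of the counter
  run_episodes_cpp(
    n_episodes = as.integer(n_episodes), fwd_next = arrays$fwd_next,
    view_idx = as.integer(view_table), reward_idx = arrays$reward_idx,
    start_cells = arrays$start_cells, region_masks = region_masks,
    Ms_A = agent$Ms_A, MA_list = agent$M_A, Ms_E = agent$Ms_E,
    ME_list = agent$M_E,
    w = agent$w, m = agent$m, v = agent$v, t_step = agent$t,
    par = run_params_list(agent), learn = learn, record_traj = record_traj)
}

#' Run a single episode
#'
#' Samples a legal start state (uniform over traversable non-reward cells and
#' headings) and lets the agent act and learn until it reaches the reward or
#' hits the step cap.
#'
#' @param agent An `sr_agent` (learned state is updated in place).
#' @param world A `gridworld` with a reward.
#' @param learn If `FALSE`, the agent's tables and weights are frozen (useful
#'   for greedy policy rollouts).
#' @param record_trajectory Record the full state-action sequence?
#' @return An `episode_record` list: `counted_steps` (go-forward selections,
#'   blocked ones included), `primitive_steps`, `hole_steps` (primitive steps
#'   whose resulting position is inside a barrier cavity), `truncated`, and a
#'   `trajectory` tibble (`x`, `y`, `d`, `action`; the final row has
#'   `action = NA`).
#' @export
run_episode <- function(agent, world, learn = TRUE,
                        record_trajectory = TRUE) {
  arrays <- world_arrays(agent, world)
  masks <- cbind(cavity = cavity_mask(world))
  out <- call_core(agent, world, arrays, masks, 1L, learn = learn,
                   record_traj = record_trajectory)
  traj <- NULL
  if (record_trajectory) {
    tm <- out$trajectories[[1]]
    xy <- allo_coords(world, tm[, 1])
    traj <- tibble(x = xy[, 1], y = xy[, 2], d = tm[, 2],
                   action = ifelse(tm[, 3] < 0, NA_integer_, tm[, 3]))
  }
  structure(list(counted_steps = out$counted[1],
                 primitive_steps = out$primitive[1],
                 hole_steps = out$region_counts[1, 1],
                 truncated = out$truncated[1], trajectory = traj),
            class = "episode_record")
}

#' Run an agent through a task
#'
#' Runs `episodes_per_world` episodes in each world in order. Nothing is
#' reset at a world switch: SR tables keep adapting by TD, the codebook grows
#' if new views appear, and weights and optimizer state carry over (continual
#' learning). Per-episode occupancy proportions needed by the downstream GLM
#' analyses are recorded as the episodes run.
#'
#' @param agent An `sr_agent` built for (or grown to) this task.
#' @param task An `sr_task`.
#' @param episodes_per_world Override of the task's episode count.
#' @return A tibble with one row per episode: `world`, `episode` (within
#'   world), `episode_global`, `counted_steps`, `primitive_steps`,
#'   `hole_steps`, `truncated`, `f_walls`, `f_current`, and `f_prev_k`
#'   (proportion of primitive steps in the barrier region of the world `k`
#'   switches back; `NA` before world `k+1`).
#' @export
run_task <- function(agent, task, episodes_per_world = NULL) {
  n_ep <- if (is.null(episodes_per_world)) task$episodes_per_world
  else as.integer(episodes_per_world)
  worlds <- task$worlds
  K <- length(worlds)
  if (K == 0L || n_ep == 0L) return(empty_run_tibble(K))
  barrier_cols <- lapply(worlds, function(wd)
    barrier_region_mask(worlds[[1]], ref_world = wd))
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    world <- worlds[[k]]
    arrays <- world_arrays(agent, world)
    masks <- do.call(cbind, c(list(cavity = cavity_mask(world),
                                   near_wall = near_wall_mask(world)),
                              barrier_cols))
    out <- call_core(agent, world, arrays, masks, n_ep)
    prim <- pmax(out$primitive, 1L)
    rc <- out$region_counts
    fk <- matrix(NA_real_, n_ep, K - 1L)
    if (K > 1L) for (j in seq_len(K - 1L)) if (k - j >= 1L)
      fk[, j] <- rc[, 2L + (k - j)] / prim
    colnames(fk) <- paste0("f_prev_", seq_len(K - 1L))
    rows[[k]] <- dplyr::bind_cols(
      tibble(world = k, episode = seq_len(n_ep),
             counted_steps = out$counted, primitive_steps = out$primitive,
             hole_steps = rc[, 1L], truncated = out$truncated,
             f_walls = rc[, 2L] / prim, f_current = rc[, 2L + k] / prim),
      as_tibble(fk))
  }
  res <- dplyr::bind_rows(rows)
  res$episode_global <- seq_len(nrow(res))
  res
}

empty_run_tibble <- function(K) {
  fk <- stats::setNames(
    rep(list(numeric()), max(K - 1L, 0L)),
    if (K > 1L) paste0("f_prev_", seq_len(K - 1L)) else character())
  dplyr::bind_cols(
    tibble(world = integer(), episode = integer(), counted_steps = integer(),
           primitive_steps = integer(), hole_steps = integer(),
           truncated = logical(), f_walls = numeric(), f_current = numeric()),
    as_tibble(fk), tibble(episode_global = integer()))
}

#' Paired lesion comparison across task seeds
#'
#' For each task seed, mints one task and runs every agent variant on an
#' identical copy with an identical run seed (paired design), so that all
#' variants see bit-identical world sequences.
#'
#' @param params A [generator_params()] describing the paradigm.
#' @param variants Character vector of lesion variants to compare.
#' @param n_tasks Number of task seeds.
#' @param episodes_per_world Episodes per world (the headline protocol uses
#'   1000; scaled-down comparisons use 200-300).
#' @param H Egocentric horizon.
#' @param config An [agent_config()].
#' @param seed Master seed; per-task world and run seeds are derived from it
#'   via [seed_streams()].
#' @return An `sr_comparison` tibble: per-episode records with `task_seed`
#'   and `variant` columns, plus per-world barrier pixel counts as attribute
#'   `world_info`.
#' @export
run_paradigm_comparison <- function(params, variants = c("FULL", "ALLO_ONLY"),
                                    n_tasks = 30L, episodes_per_world = 1000L,
                                    H = 2L, config = agent_config(),
                                    seed = 1L) {
  variants <- vapply(variants, match.arg, character(1),
                     choices = LESION_VARIANTS)
  streams <- seed_streams(seed)
  all_rows <- list()
  world_info <- list()
  for (ti in seq_len(n_tasks)) {
    set.seed(streams$worldgen + ti)
    task <- generate_task(params, episodes_per_world = episodes_per_world)
    world_info[[ti]] <- tibble(
      task_seed = ti, world = seq_along(task$worlds),
      barrier_pixels = vapply(task$worlds, barrier_pixels, integer(1)))
    for (v in variants) {
      agent <- sr_agent(task, H = H, config = config, variant = v)
      set.seed(streams$policy + ti)
      res <- run_task(agent, task)
      res$task_seed <- ti
      res$variant <- v
      all_rows[[length(all_rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(all_rows)
  attr(out, "world_info") <- dplyr::bind_rows(world_info)
  attr(out, "params") <- params
  class(out) <- c("sr_comparison", class(out))
  out
}

#' Horizon sweep
#'
#' Re-runs the paired FULL vs ALLO_ONLY comparison for several egocentric
#' horizons. The allocentric-only agent takes no egocentric input, so it is
#' run once per task seed and shared across horizons.
#'
#' @param H_values Integer vector of horizons (each >= 1).
#' @inheritParams run_paradigm_comparison
#' @return A tibble of per-episode records with `H` (`NA` for the shared
#'   `ALLO_ONLY` runs), `task_seed` and `variant` columns.
#' @export
horizon_sweep <- function(H_values = c(2L, 3L, 4L), params = generator_params(),
                          n_tasks = 10L, episodes_per_world = 300L,
                          config = agent_config(), seed = 1L) {
  if (any(H_values < 1L)) abort("every horizon must be >= 1")
  streams <- seed_streams(seed)
  rows <- list()
  for (ti in seq_len(n_tasks)) {
    set.seed(streams$worldgen + ti)
    task <- generate_task(params, episodes_per_world = episodes_per_world)
    agent <- sr_agent(task, H = 2L, config = config, variant = "ALLO_ONLY")
    set.seed(streams$policy + ti)
    res <- run_task(agent, task)
    res$task_seed <- ti; res$variant <- "ALLO_ONLY"; res$H <- NA_integer_
    rows[[length(rows) + 1L]] <- res
    for (H in H_values) {
      agent <- sr_agent(task, H = H, config = config, variant = "FULL")
      set.seed(streams$policy + ti)
      res <- run_task(agent, task)
      res$task_seed <- ti; res$variant <- "FULL"; res$H <- as.integer(H)
      rows[[length(rows) + 1L]] <- res
    }
  }
  dplyr::bind_rows(rows)
}

#' Post-switch performance summary
#'
#' Mean counted steps over the first `n_episodes` episodes of each world
#' after the first (the episodes immediately following an environment
#' switch), per task seed and variant, and mean hole time over those worlds.
#'
#' @param comparison An `sr_comparison` tibble.
#' @param n_episodes Window length after each switch.
#' @return A tibble with `task_seed`, `variant`, `post_switch_steps`,
#'   `hole_time`.
#' @export
post_switch_summary <- function(comparison, n_episodes = 100L) {
  comparison %>%
    filter(.data$world > 1L) %>%
    group_by(.data$task_seed, .data$variant) %>%
    summarise(
      post_switch_steps = mean(.data$counted_steps[.data$episode <= n_episodes]),
      hole_time = mean(.data$hole_steps), .groups = "drop")
}

#' Paired sign test between two variants
#'
#' Exact binomial sign test across task seeds of the hypothesis that
#' `better` has strictly smaller values of `metric` than `worse`.
#'
#' @param summary_tbl Output of [post_switch_summary()].
#' @param metric Column name to compare.
#' @param better,worse Variant names.
#' @return A list with `n_seeds`, `n_better` and `p_value` (one-sided).
#' @export
variant_sign_test <- function(summary_tbl, metric = "post_switch_steps",
                              better = "FULL", worse = "ALLO_ONLY") {
  wide <- tidyr::pivot_wider(summary_tbl[, c("task_seed", "variant", metric)],
                             names_from = "variant",
                             values_from = dplyr::all_of(metric))
  if (!all(c(better, worse) %in% names(wide)))
    abort("both variants must be present")
  k <- sum(wide[[better]] < wide[[worse]])
  n <- nrow(wide)
  list(n_seeds = n, n_better = k,
       p_value = stats::binom.test(k, n, alternative = "greater")$p.value)
}

#' Mean counted-step learning curves
#'
#' Per-episode mean and standard deviation of counted steps across task
#' seeds, per variant.
#'
#' @param comparison An `sr_comparison` tibble.
#' @return A tibble with `variant`, `episode_global`, `world`, `mean_steps`,
#'   `sd_steps`.
#' @export
learning_curves <- function(comparison) {
  comparison %>%
    group_by(.data$variant, .data$episode_global, .data$world) %>%
    summarise(mean_steps = mean(.data$counted_steps),
              sd_steps = stats::sd(.data$counted_steps), .groups = "drop")
}

#' Per-episode step ratios between two variants
#'
#' Ratio of counted steps taken by `num` to `den` in identical episodes of
#' the paired design.
#'
#' @param comparison An `sr_comparison` tibble.
#' @param num,den Variant names.
#' @return A tibble with `task_seed`, `episode_global`, `ratio`.
#' @export
step_ratios <- function(comparison, num = "FULL", den = "ALLO_ONLY") {
  a <- comparison %>% filter(.data$variant == num)
  b <- comparison %>% filter(.data$variant == den)
  tibble(task_seed = a$task_seed, episode_global = a$episode_global,
         ratio = a$counted_steps / pmax(b$counted_steps, 1L))
}
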