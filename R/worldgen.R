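# Generative models for tasks: U-barrier worlds (aligned / varied size /
# random orientation), fully-random connected worlds, and 5-world task
# sequences with alternating reward corners.

#' Generator parameters
#'
#' @param paradigm One of `"ALIGNED_FIXED"` (the main paradigm: first world's
#'   barriers share one orientation, later worlds sample orientations freely),
#'   `"ALIGNED_VARSIZE"` (aligned barriers, sizes sampled per barrier),
#'   `"RANDOM_ORIENT_VARSIZE"` (random orientations and sizes) or
#'   `"FULLY_RANDOM"` (single-pixel obstacles at a target density).
#' @param width,height World dimensions including the boundary ring.
#' @param barrier_size Outer size (square) of fixed-size U barriers.
#' @param size_range Inclusive range of outer sizes for the `VARSIZE`
#'   paradigms.
#' @param attempts Independent barrier placement attempts per world.
#' @param buffer Clearance (in cells, Chebyshev) required around a barrier
#'   footprint.
#' @param density Target obstacle density for `FULLY_RANDOM` worlds (fraction
#'   of interior cells).
#' @param lift_alignment If `TRUE` (default for `ALIGNED_FIXED`), worlds after
#'   the first sample barrier orientations freely, reproducing the main
#'   multi-world paradigm; if `FALSE`, every world keeps aligned orientations.
#' @param stall_cap Consecutive rejected obstacle candidates tolerated before
#'   `FULLY_RANDOM` generation fails.
#' @return A `generator_params` list.
#' @export
generator_params <- function(paradigm = c("ALIGNED_FIXED", "ALIGNED_VARSIZE",
                                          "RANDOM_ORIENT_VARSIZE",
                                          "FULLY_RANDOM"),
                             width = 20L, height = 20L, barrier_size = 4L,
                             size_range = c(3L, 6L), attempts = 20L,
                             buffer = 1L, density = 0.2,
                             lift_alignment = NULL, stall_cap = 1000L) {
  paradigm <- match.arg(paradigm)
  if (attempts < 0L) abort("attempts must be >= 0")
  if (buffer < 0L) abort("buffer must be >= 0")
  if (density < 0 || density >= 1) abort("density must be in [0, 1)")
  if (barrier_size < 3L || barrier_size > width - 2L - 2L)
    abort("barrier_size must fit the interior (>= 3)")
  if (size_range[1] < 3L) abort("size_range minimum is 3")
  if (is.null(lift_alignment)) lift_alignment <- paradigm == "ALIGNED_FIXED"
  structure(list(paradigm = paradigm, width = as.integer(width),
                 height = as.integer(height),
                 barrier_size = as.integer(barrier_size),
                 size_range = as.integer(size_range),
                 attempts = as.integer(attempts), buffer = as.integer(buffer),
                 density = density, lift_alignment = lift_alignment,
                 stall_cap = as.integer(stall_cap)),
            class = "generator_params")
}

#' Reward corner coordinates
#'
#' Interior corner cells used by the task generator; rewards alternate between
#' the top-right and bottom-right corners.
#'
#' @param width,height World dimensions.
#' @param which `"TR"` or `"BR"`.
#' @return Length-2 integer coordinate.
#' @export
reward_corner <- function(width, height, which = c("TR", "BR")) {
  which <- match.arg(which)
  if (which == "TR") c(width - 2L, height - 2L) else c(width - 2L, 1L)
}

u_barrier_cells <- function(x0, y_top, size, orientation) {
  # footprint: columns x0..x1, rows y0..y_top (y_top is the north edge)
  x1 <- x0 + size - 1L; y0 <- y_top - size + 1L
  fx <- rep(x0:x1, times = size); fy <- rep(y0:y_top, each = size)
  side <- c(N = 0L, E = 1L, S = 2L, W = 3L)[[orientation]]
  solid <- (fy == y_top & side != 0L) | (fy == y0 & side != 2L) |
    (fx == x1 & side != 1L) | (fx == x0 & side != 3L)
  list(footprint = cbind(x = fx, y = fy),
       barrier = cbind(x = fx[solid], y = fy[solid]),
       cavity = cbind(x = fx[!solid], y = fy[!solid]))
}

#' Place a U-shaped barrier
#'
#' Stamps a U of barrier cells — a square of the given outer size whose
#' interior cavity is open on the `orientation` side — anchored at its
#' top-left footprint corner, provided the footprint plus a clearance buffer
#' overlaps no wall, no reward cell and no other barrier footprint. The cavity
#' cells stay empty (traversable) and are recorded on the world.
#'
#' @param world A `gridworld`.
#' @param anchor Length-2 `(x, y_top)`: leftmost column and top row of the
#'   footprint.
#' @param size Outer size (>= 3).
#' @param orientation Opening side: one of `"N"`, `"E"`, `"S"`, `"W"`.
#' @param buffer Clearance width in cells (default 1).
#' @return List with `world` (possibly modified) and `placed` flag.
#' @export
place_u_barrier <- function(world, anchor, size, orientation, buffer = 1L) {
  size <- as.integer(size)
  if (size < 3L) abort("barrier outer size must be >= 3")
  if (size > min(world$width, world$height) - 2L)
    abort("barrier too large for the interior")
  orientation <- match.arg(orientation, c("N", "E", "S", "W"))
  x0 <- as.integer(anchor[1]); y_top <- as.integer(anchor[2])
  x1 <- x0 + size - 1L; y0 <- y_top - size + 1L
  # expanded rectangle = footprint + buffer; must be interior, empty of other
  # footprints, and must not contain the reward
  ex <- (x0 - buffer):(x1 + buffer); ey <- (y0 - buffer):(y_top + buffer)
  if (min(ex) < 1L || min(ey) < 1L || max(ex) > world$width - 2L ||
      max(ey) > world$height - 2L)
    return(list(world = world, placed = FALSE))
  exp_cells <- cbind(rep(ex, times = length(ey)), rep(ey, each = length(ex)))
  if (any(world$footprint[exp_cells + 1L]))
    return(list(world = world, placed = FALSE))
  if (!is.null(world$reward) &&
      any(exp_cells[, 1] == world$reward[1] & exp_cells[, 2] == world$reward[2]))
    return(list(world = world, placed = FALSE))
  geom <- u_barrier_cells(x0, y_top, size, orientation)
  world$cells[geom$barrier + 1L] <- CELL_BARRIER
  world$footprint[geom$footprint + 1L] <- TRUE
  world$barriers[[length(world$barriers) + 1L]] <-
    list(anchor = c(x0, y_top), size = size, orientation = orientation)
  world$cavity <- rbind(world$cavity, geom$cavity)
  list(world = world, placed = TRUE)
}

aligned_orientation <- function(params, reward) {
  # opening faces the reward's vertical side: exits at the top when the reward
  # is in the top half, at the bottom otherwise
  if (reward[2] >= (params$height - 1L) / 2) "N" else "S"
}

#' Generate a U-barrier world
#'
#' Starts from an empty walled world with the reward at the given corner and
#' makes `attempts` independent placement attempts, sampling a top-left anchor
#' uniformly over the interior and, depending on the paradigm, an orientation
#' and outer size. Placements violating clearance are skipped; placements that
#' would disconnect traversable space or cut off the reward are rejected.
#' Consumes the R random number stream (seed with [set.seed()]).
#'
#' @param params A [generator_params()] object.
#' @param reward Reward cell coordinate (see [reward_corner()]).
#' @param aligned If `TRUE`, all barriers share the aligned orientation
#'   (opening towards the reward's vertical side); if `FALSE`, orientations
#'   are sampled uniformly per barrier.
#' @return A `gridworld`.
#' @export
generate_barrier_world <- function(params, reward,
                                   aligned = params$paradigm %in%
                                     c("ALIGNED_FIXED", "ALIGNED_VARSIZE")) {
  world <- empty_world(params$width, params$height, reward = reward)
  varsize <- params$paradigm %in% c("ALIGNED_VARSIZE", "RANDOM_ORIENT_VARSIZE")
  ori_aligned <- aligned_orientation(params, reward)
  if (params$attempts > 0L) for (i in seq_len(params$attempts)) {
    ax <- sample.int(params$width - 2L, 1L)
    ay <- sample.int(params$height - 2L, 1L)
    ori <- if (aligned) ori_aligned else
      c("N", "E", "S", "W")[sample.int(4L, 1L)]
    size <- if (varsize)
      sample(seq(params$size_range[1], params$size_range[2]), 1L)
    else params$barrier_size
    res <- place_u_barrier(world, c(ax, ay), size, ori, params$buffer)
    if (res$placed) {
      cand <- res$world
      reach <- reachable_set(cand, cand$reward)
      n_trav <- sum(cand$cells[2:(cand$width - 1L), 2:(cand$height - 1L)] ==
                      CELL_EMPTY)
      if (nrow(reach) == n_trav) world <- cand # else reject: disconnects space
    }
  }
  world$meta <- list(paradigm = params$paradigm, aligned = aligned,
                     n_barriers = length(world$barriers))
  world
}

#' Generate a fully-random connected obstacle world
#'
#' Scatters single-pixel obstacles one at a time until the obstacle density of
#' the interior reaches the target. Each candidate is rejected if it would
#' make the reward unreachable or disconnect traversable space, checked by a
#' breadth-first search from the corner opposite the reward compared against
#' the set of non-obstacle cells.
#'
#' @param params A [generator_params()] with `paradigm = "FULLY_RANDOM"`.
#' @param reward Reward cell coordinate.
#' @return A `gridworld`.
#' @export
generate_random_world <- function(params, reward) {
  if (params$paradigm != "FULLY_RANDOM")
    abort("generate_random_world requires the FULLY_RANDOM paradigm")
  world <- empty_world(params$width, params$height, reward = reward)
  interior_n <- (params$width - 2L) * (params$height - 2L)
  opposite <- c(ifelse(reward[1] > params$width / 2, 1L, params$width - 2L),
                ifelse(reward[2] > params$height / 2, 1L, params$height - 2L))
  n_obs <- 0L; rejections <- 0L
  while (n_obs / interior_n < params$density) {
    ax <- sample.int(params$width - 2L, 1L)
    ay <- sample.int(params$height - 2L, 1L)
    bad <- (ax == reward[1] && ay == reward[2]) ||
      (ax == opposite[1] && ay == opposite[2]) ||
      world$cells[ax + 1L, ay + 1L] != CELL_EMPTY
    if (!bad) {
      cand <- world
      cand$cells[ax + 1L, ay + 1L] <- CELL_BARRIER
      cand$footprint[ax + 1L, ay + 1L] <- TRUE
      reach <- reachable_set(cand, opposite)
      n_trav <- sum(cand$cells[2:(cand$width - 1L), 2:(cand$height - 1L)] ==
                      CELL_EMPTY)
      ok <- nrow(reach) == n_trav &&
        any(reach[, 1] == reward[1] & reach[, 2] == reward[2])
      if (ok) {
        world <- cand; n_obs <- n_obs + 1L; rejections <- 0L
        next
      }
    }
    rejections <- rejections + 1L
    if (rejections > params$stall_cap)
      abort(sprintf(
        "random world generation stalled after %d consecutive rejections (%d obstacles placed)",
        rejections, n_obs))
  }
  world$meta <- list(paradigm = "FULLY_RANDOM", n_obstacles = n_obs,
                     density = n_obs / interior_n)
  world
}

#' Generate a task: a sequence of worlds with alternating reward corners
#'
#' A task is (by default) 5 worlds whose rewards alternate between the
#' top-right and bottom-right interior corners. Under the main
#' `ALIGNED_FIXED` paradigm the first world's barriers all share the aligned
#' orientation and the constraint is lifted for the remaining worlds; the
#' `VARSIZE` paradigms keep their own orientation rules throughout, and
#' `FULLY_RANDOM` produces connected single-pixel-obstacle worlds.
#'
#' @param params A [generator_params()] object.
#' @param n_worlds Number of worlds (default 5).
#' @param episodes_per_world Episodes the runner will spend per world
#'   (default 1000; carried on the task object).
#' @return An `sr_task` object (list of worlds plus bookkeeping).
#' @export
generate_task <- function(params, n_worlds = 5L, episodes_per_world = 1000L) {
  corners <- rep(c("TR", "BR"), length.out = n_worlds)
  worlds <- vector("list", n_worlds)
  for (k in seq_len(n_worlds)) {
    rc <- reward_corner(params$width, params$height, corners[k])
    if (params$paradigm == "FULLY_RANDOM") {
      worlds[[k]] <- generate_random_world(params, rc)
    } else {
      aligned <- if (params$paradigm == "RANDOM_ORIENT_VARSIZE") FALSE
      else if (k == 1L) TRUE
      else !params$lift_alignment
      worlds[[k]] <- generate_barrier_world(params, rc, aligned = aligned)
    }
    worlds[[k]]$meta$world_index <- k
    worlds[[k]]$meta$reward_corner <- corners[k]
  }
  structure(list(worlds = worlds, episodes_per_world =
                   as.integer(episodes_per_world), params = params),
            class = "sr_task")
}

#' @export
print.sr_task <- function(x, ...) {
  cat(sprintf("<sr_task: %d worlds (%s), %d episodes/world>\n",
              length(x$worlds), x$params$paradigm, x$episodes_per_world))
  invisible(x)
}

#' Barrier pixel count of a world
#'
#' Number of barrier-labelled cells; used as the barrier-count proxy regressor
#' in the Poisson GLM analysis.
#'
#' @param world A `gridworld`.
#' @return Integer count.
#' @export
barrier_pixels <- function(world) sum(world$cells == CELL_BARRIER)
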