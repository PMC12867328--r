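#' @useDynLib egosr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort .data
NULL

# Integer cell codes shared with src/core.cpp.
CELL_EMPTY <- 0L
CELL_BARRIER <- 1L
CELL_WALL_N <- 2L
CELL_WALL_E <- 3L
CELL_WALL_S <- 4L
CELL_WALL_W <- 5L
CELL_OUTSIDE <- 6L
CELL_OCCLUDED <- 7L
CELL_REWARD <- 8L

CELL_CHARS <- c(".", "#", "N", "E", "S", "W", "o", "x", "R")

#' Cell label codes
#'
#' Named integer codes used in world grids and egocentric views. `OUTSIDE` and
#' `OCCLUDED` occur only in views; `REWARD` only in views when reward rendering
#' is switched on.
#'
#' @return Named integer vector of cell codes.
#' @export
cell_codes <- function() {
  c(EMPTY = CELL_EMPTY, BARRIER = CELL_BARRIER, WALL_N = CELL_WALL_N,
    WALL_E = CELL_WALL_E, WALL_S = CELL_WALL_S, WALL_W = CELL_WALL_W,
    OUTSIDE = CELL_OUTSIDE, OCCLUDED = CELL_OCCLUDED, REWARD = CELL_REWARD)
}

# Directions: N=0 (0,+1), E=1 (+1,0), S=2 (0,-1), W=3 (-1,0). y grows north.
DIR_DX <- c(0L, 1L, 0L, -1L)
DIR_DY <- c(1L, 0L, -1L, 0L)
DIR_NAMES <- c("N", "E", "S", "W")

# Egocentric actions, in fixed index order.
EGO_ACTIONS <- c("GO_FORWARD", "TURN_CW_90", "TURN_180", "TURN_CCW_90")
ALLO_ACTIONS <- c("NORTH", "EAST", "SOUTH", "WEST")

#' Action sets
#'
#' The four egocentric actions (go-forward, turn 90 deg clockwise, turn 180
#' deg, turn 90 deg anticlockwise) and the four allocentric actions (compass
#' moves), with their fixed 0-based indices.
#'
#' @return A list with `ego` and `allo` named integer vectors.
#' @export
action_sets <- function() {
  list(ego = stats::setNames(0:3, EGO_ACTIONS),
       allo = stats::setNames(0:3, ALLO_ACTIONS))
}

#' Create an empty walled gridworld
#'
#' Builds a `width` x `height` grid (default 20 x 20) whose outermost ring is
#' wall cells labelled by side; corner cells take the horizontal wall label
#' (`WALL_N`/`WALL_S`). Coordinates are 0-based `(x, y)` with `y` increasing
#' northwards, so row `y = height - 1` is the north wall. The interior is
#' empty and traversable.
#'
#' @param width,height Total cell counts including the boundary ring.
#' @param reward Length-2 integer vector, interior coordinate of the reward
#'   cell, or `NULL` for no reward yet.
#' @return A `gridworld` object.
#' @export
empty_world <- function(width = 20L, height = 20L, reward = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 3L || height < 3L) abort("world must be at least 3x3")
  cells <- matrix(CELL_EMPTY, nrow = width, ncol = height)
  cells[, height] <- CELL_WALL_N
  cells[, 1L] <- CELL_WALL_S
  cells[1L, 2:(height - 1L)] <- CELL_WALL_W
  cells[width, 2:(height - 1L)] <- CELL_WALL_E
  w <- structure(
    list(width = width, height = height, cells = cells,
         reward = NULL, barriers = list(),
         cavity = matrix(integer(), ncol = 2L,
                         dimnames = list(NULL, c("x", "y"))),
         footprint = matrix(FALSE, nrow = width, ncol = height),
         meta = list()),
    class = "gridworld")
  if (!is.null(reward)) w <- set_reward(w, reward)
  w
}

#' Set the reward cell of a world
#'
#' @param world A `gridworld`.
#' @param cell Length-2 integer `(x, y)`, an empty interior cell.
#' @return The modified world.
#' @export
set_reward <- function(world, cell) {
  cell <- as.integer(cell)
  if (!is_interior(world, cell[1], cell[2]) ||
      world$cells[cell[1] + 1L, cell[2] + 1L] != CELL_EMPTY)
    abort("reward cell must be an empty interior cell")
  world$reward <- cell
  world
}

is_interior <- function(world, x, y) {
  x >= 1L & x <= world$width - 2L & y >= 1L & y <= world$height - 2L
}

cell_at <- function(world, x, y) world$cells[x + 1L, y + 1L]

#' Is a cell traversable?
#'
#' Traversable cells are `EMPTY` interior cells (the reward cell included).
#'
#' @param world A `gridworld`.
#' @param x,y 0-based cell coordinates (vectorised).
#' @return Logical vector.
#' @export
is_traversable <- function(world, x, y) {
  inside <- x >= 0L & x < world$width & y >= 0L & y < world$height
  out <- logical(length(inside))
  out[inside] <- world$cells[cbind(x[inside] + 1L, y[inside] + 1L)] == CELL_EMPTY
  out
}

#' @export
print.gridworld <- function(x, ...) {
  cat(sprintf("<gridworld %dx%d, %d barrier(s), reward %s>\n", x$width,
              x$height, length(x$barriers),
              if (is.null(x$reward)) "unset"
              else sprintf("(%d,%d)", x$reward[1], x$reward[2])))
  ch <- matrix(CELL_CHARS[x$cells + 1L], nrow = x$width)
  if (!is.null(x$reward)) ch[x$reward[1] + 1L, x$reward[2] + 1L] <- "R"
  for (y in (x$height - 1L):0L)
    cat(paste0(ch[, y + 1L], collapse = ""), "\n")
  invisible(x)
}

#' Agent state
#'
#' @param x,y 0-based traversable cell coordinates.
#' @param d Head direction: 0=N, 1=E, 2=S, 3=W (or one of "N","E","S","W").
#' @return An `agent_state` list.
#' @export
agent_state <- function(x, y, d) {
  if (is.character(d)) d <- match(d, DIR_NAMES) - 1L
  d <- as.integer(d)
  if (is.na(d) || d < 0L || d > 3L) abort("invalid direction")
  structure(list(x = as.integer(x), y = as.integer(y), d = d),
            class = "agent_state")
}

check_state <- function(world, state) {
  if (!is_traversable(world, state$x, state$y))
    abort("agent state is not on a traversable cell")
  invisible(state)
}

#' One primitive environment step
#'
#' Turn actions change only the head direction; `GO_FORWARD` moves one cell in
#' the heading direction if the target cell is traversable and is otherwise a
#' no-op (the agent stays put but the step still counts as primitive time).
#' Reaching the reward cell yields reward 1 and terminates the episode.
#'
#' @param world A `gridworld` with a reward set.
#' @param state An `agent_state`.
#' @param action Ego action index 0-3 or name (see [action_sets()]).
#' @return A list with `state` (next `agent_state`), `reward`, `done`.
#' @export
step <- function(world, state, action) {
  if (is.character(action)) action <- match(action, EGO_ACTIONS) - 1L
  action <- as.integer(action)
  if (is.na(action) || action < 0L || action > 3L) abort("invalid action index")
  check_state(world, state)
  if (action == 0L) {
    nx <- state$x + DIR_DX[state$d + 1L]
    ny <- state$y + DIR_DY[state$d + 1L]
    if (!is_traversable(world, nx, ny)) { nx <- state$x; ny <- state$y }
    nxt <- agent_state(nx, ny, state$d)
  } else {
    nxt <- agent_state(state$x, state$y, (state$d + action) %% 4L)
  }
  done <- !is.null(world$reward) && nxt$x == world$reward[1] &&
    nxt$y == world$reward[2]
  list(state = nxt, reward = as.numeric(done), done = done)
}

#' Occluded egocentric view
#'
#' Extracts the `(H+1) x (2H+1)` agent-centred, heading-aligned window. Row 1
#' is the agent's own row (its own cell is always `EMPTY`), rows extend
#' forward; columns run from `H` cells to the agent's left to `H` cells to its
#' right. Cells beyond the padded grid are `OUTSIDE`; cells whose line of
#' sight from the agent crosses a barrier or wall cell are `OCCLUDED`.
#'
#' @param world A `gridworld`.
#' @param state An `agent_state`.
#' @param H Horizon (window depth in cells), >= 1.
#' @param render_reward If `TRUE`, the reward cell is shown with a distinct
#'   `REWARD` label; by default it is rendered as `EMPTY`, leaving reward
#'   localisation to the allocentric pathway.
#' @return Integer matrix of cell codes with class `ego_view`.
#' @export
ego_view <- function(world, state, H = 2L, render_reward = FALSE) {
  check_state(world, state)
  rx <- if (!is.null(world$reward)) world$reward[1] else -1L
  ry <- if (!is.null(world$reward)) world$reward[2] else -1L
  v <- ego_view_cpp(world$cells, state$x, state$y, state$d, as.integer(H),
                    rx, ry, isTRUE(render_reward))
  structure(v, class = c("ego_view", "matrix"), H = as.integer(H))
}

#' @export
print.ego_view <- function(x, ...) {
  H <- attr(x, "H")
  cat(sprintf("<ego_view H=%d> (top row is farthest ahead)\n", H))
  for (r in nrow(x):1) cat(paste0(CELL_CHARS[x[r, ] + 1L], collapse = ""), "\n")
  invisible(x)
}

#' Line-of-sight test between two cells
#'
#' `TRUE` iff the straight segment between the two cell centres passes through
#' the interior of a barrier or wall cell strictly between the endpoints
#' (supercover traversal; a cell grazed exactly at a corner does not block).
#'
#' @param world A `gridworld`.
#' @param from,to Length-2 0-based cell coordinates.
#' @return Logical flag.
#' @export
line_of_sight_blocked <- function(world, from, to) {
  los_blocked_cpp(world$cells, as.integer(from[1]), as.integer(from[2]),
                  as.integer(to[1]), as.integer(to[2]))
}

#' Rotate an allocentric action into the egocentric frame (and back)
#'
#' For head direction `d`, the allocentric action equal to `d` maps to
#' `GO_FORWARD`, the action 90 deg clockwise of `d` to `TURN_CW_90`, the
#' opposite to `TURN_180` and the anticlockwise one to `TURN_CCW_90`. With the
#' package's fixed index orders both maps are modular arithmetic:
#' `ego = (allo - d) mod 4` and `allo = (d + ego) mod 4`.
#'
#' @param d Head direction index 0-3 (or "N","E","S","W").
#' @param a_allo Allocentric action index 0-3 (or name).
#' @param a_ego Egocentric action index 0-3 (or name).
#' @return The mapped action index (0-based).
#' @export
rotate_action <- function(d, a_allo) {
  if (is.character(d)) d <- match(d, DIR_NAMES) - 1L
  if (is.character(a_allo)) a_allo <- match(a_allo, ALLO_ACTIONS) - 1L
  if (any(is.na(d) | d < 0 | d > 3)) abort("invalid direction")
  if (any(is.na(a_allo) | a_allo < 0 | a_allo > 3)) abort("invalid action")
  (as.integer(a_allo) - as.integer(d)) %% 4L
}

#' @rdname rotate_action
#' @export
inverse_rotate_action <- function(d, a_ego) {
  if (is.character(d)) d <- match(d, DIR_NAMES) - 1L
  if (is.character(a_ego)) a_ego <- match(a_ego, EGO_ACTIONS) - 1L
  if (any(is.na(d) | d < 0 | d > 3)) abort("invalid direction")
  if (any(is.na(a_ego) | a_ego < 0 | a_ego > 3)) abort("invalid action")
  (as.integer(d) + as.integer(a_ego)) %% 4L
}

#' Breadth-first reachable set
#'
#' Closure of 4-neighbour moves through traversable cells from a start cell.
#'
#' @param world A `gridworld`.
#' @param start Length-2 0-based coordinates of a traversable cell.
#' @return Integer matrix with columns `x`, `y`, one row per reachable cell.
#' @export
reachable_set <- function(world, start) {
  sx <- as.integer(start[1]); sy <- as.integer(start[2])
  if (!is_traversable(world, sx, sy)) abort("start cell not traversable")
  seen <- matrix(FALSE, world$width, world$height)
  seen[sx + 1L, sy + 1L] <- TRUE
  queue <- list(c(sx, sy)); head <- 1L
  while (head <= length(queue)) {
    p <- queue[[head]]; head <- head + 1L
    for (dd in 1:4) {
      nx <- p[1] + DIR_DX[dd]; ny <- p[2] + DIR_DY[dd]
      if (!seen[nx + 1L, ny + 1L] && is_traversable(world, nx, ny)) {
        seen[nx + 1L, ny + 1L] <- TRUE
        queue[[length(queue) + 1L]] <- c(nx, ny)
      }
    }
  }
  out <- which(seen, arr.ind = TRUE) - 1L
  colnames(out) <- c("x", "y")
  out
}

# --- allocentric state indexing -------------------------------------------
# The allocentric state space is the full interior of the (empty) walled
# world; index = (x-1) + (y-1)*(width-2), 0-based. Barrier worlds share the
# same indexing (barrier cells are simply never visited).

n_allo_states <- function(world) (world$width - 2L) * (world$height - 2L)

allo_index <- function(world, x, y) (x - 1L) + (y - 1L) * (world$width - 2L)

allo_coords <- function(world, idx) {
  wi <- world$width - 2L
  cbind(x = idx %% wi + 1L, y = idx %/% wi + 1L)
}

#' Serialise a world to JSON
#'
#' Plain-text JSON with the cell grid as rows of single-character codes
#' (`.` empty, `#` barrier, `N`/`E`/`S`/`W` walls, `R` reward), plus barrier
#' descriptors and generator metadata. Round-trips exactly through
#' [read_world()].
#'
#' @param world A `gridworld`.
#' @param path File path to write to (or `NULL` to return the JSON string).
#' @return `path` invisibly, or the JSON string.
#' @export
write_world <- function(world, path = NULL) {
  ch <- matrix(CELL_CHARS[world$cells + 1L], nrow = world$width)
  if (!is.null(world$reward)) ch[world$reward[1] + 1L, world$reward[2] + 1L] <- "R"
  rows <- vapply((world$height - 1L):0L,
                 function(y) paste0(ch[, y + 1L], collapse = ""), character(1))
  obj <- list(width = world$width, height = world$height, rows = rows,
              barriers = world$barriers, cavity = unname(world$cavity),
              meta = world$meta)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a world from JSON
#'
#' @param path File path or JSON string produced by [write_world()].
#' @return A `gridworld`.
#' @export
read_world <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  width <- as.integer(obj$width); height <- as.integer(obj$height)
  cells <- matrix(CELL_EMPTY, width, height)
  reward <- NULL
  for (i in seq_along(obj$rows)) {
    y <- height - i # rows are written north first
    chars <- strsplit(obj$rows[[i]], "")[[1]]
    for (x in seq_len(width) - 1L) {
      ch <- chars[x + 1L]
      if (ch == "R") { reward <- c(x, y); ch <- "." }
      cells[x + 1L, y + 1L] <- match(ch, CELL_CHARS) - 1L
    }
  }
  w <- structure(
    list(width = width, height = height, cells = cells, reward = reward,
         barriers = if (length(obj$barriers)) obj$barriers else list(),
         cavity = if (length(obj$cavity)) {
           cv <- matrix(as.integer(as.matrix(obj$cavity)), ncol = 2L)
           colnames(cv) <- c("x", "y"); cv
         } else matrix(integer(), ncol = 2L,
                       dimnames = list(NULL, c("x", "y"))),
         meta = if (length(obj$meta)) obj$meta else list()),
    class = "gridworld")
  fp <- w$cells == CELL_BARRIER
  if (nrow(w$cavity)) fp[w$cavity + 1L] <- TRUE
  w$footprint <- fp
  w
}
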