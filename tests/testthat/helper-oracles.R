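# Independent oracles used across the suite. These deliberately use different
# algorithms from the package internals (recursion instead of BFS, dense
# segment sampling instead of supercover traversal, hand-rolled IRLS instead
# of stats::glm) so that agreement is informative.

# Recursive flood fill over traversable cells (depth-first, not BFS).
flood_fill_reachable <- function(world, start) {
  seen <- matrix(FALSE, world$width, world$height)
  recurse <- function(x, y) {
    if (seen[x + 1L, y + 1L] || !is_traversable(world, x, y)) return(invisible())
    seen[x + 1L, y + 1L] <<- TRUE
    recurse(x + 1L, y); recurse(x - 1L, y); recurse(x, y + 1L); recurse(x, y - 1L)
  }
  recurse(start[1], start[2])
  out <- which(seen, arr.ind = TRUE) - 1L
  colnames(out) <- c("x", "y")
  out
}

# Dense-sampling line-of-sight oracle: walk the segment between cell centres
# at ~1/2003 steps and flag any strictly-between blocking cell whose interior
# contains a sample point. The prime step count avoids landing exactly on
# cell boundaries for the integer offsets used in views.
segment_blocked_dense <- function(world, from, to) {
  dx <- to[1] - from[1]; dy <- to[2] - from[2]
  if (abs(dx) + abs(dy) <= 1) return(FALSE)
  ts <- seq_len(2002L) / 2003
  px <- from[1] + 0.5 + ts * dx
  py <- from[2] + 0.5 + ts * dy
  cx <- floor(px); cy <- floor(py)
  keep <- !(cx == from[1] & cy == from[2]) & !(cx == to[1] & cy == to[2])
  if (!any(keep)) return(FALSE)
  codes <- world$cells[cbind(cx[keep] + 1L, cy[keep] + 1L)]
  any(codes >= 1L & codes <= 5L)
}

# Hand-rolled IRLS for Poisson (log link) and binomial (logit link) GLMs.
irls_glm <- function(X, y, family = c("poisson", "binomial"),
                     tol = 1e-10, maxit = 50L) {
  family <- match.arg(family)
  beta <- rep(0, ncol(X))
  if (family == "poisson") beta[1] <- log(mean(y) + 0.1) # keep mu sane at start
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    if (family == "poisson") {
      mu <- exp(eta); wt <- mu; z <- eta + (y - mu) / mu
    } else {
      mu <- 1 / (1 + exp(-eta)); wt <- mu * (1 - mu)
      wt <- pmax(wt, 1e-10); z <- eta + (y - mu) / wt
    }
    WX <- X * wt
    beta_new <- solve(crossprod(X, WX), crossprod(WX, z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.numeric(beta)
}

# Deep copy of an sr_agent, forcing fresh numeric storage so that in-place
# mutation by the compiled core cannot alias the copy.
clone_agent <- function(agent) {
  ag <- new.env(parent = emptyenv())
  for (nm in ls(agent)) ag[[nm]] <- agent[[nm]]
  ag$Ms_A <- agent$Ms_A + 0
  ag$M_A <- lapply(agent$M_A, function(M) M + 0)
  ag$Ms_E <- agent$Ms_E + 0
  ag$M_E <- lapply(agent$M_E, function(M) M + 0)
  ag$w <- agent$w + 0; ag$m <- agent$m + 0; ag$v <- agent$v + 0
  ag$t <- agent$t + 0
  cb <- ego_codebook(agent$codebook$H)
  for (key in agent$codebook$keys) {
    idx <- length(cb$keys)
    assign(key, idx, envir = cb$map)
    cb$keys <- c(cb$keys, key)
  }
  ag$codebook <- cb
  class(ag) <- "sr_agent"
  ag
}

# A small walled world with a hand-placed barrier pattern, for view tests.
tiny_world <- function(width = 8L, height = 8L, reward = NULL,
                       barriers = NULL) {
  w <- empty_world(width, height, reward = reward)
  if (!is.null(barriers)) {
    w$cells[barriers + 1L] <- 1L # BARRIER code
    w$footprint[barriers + 1L] <- TRUE
  }
  w
}

# Tiny task wrapper around explicit worlds.
tiny_task <- function(worlds, episodes_per_world = 10L,
                      params = generator_params(width = worlds[[1]]$width,
                                                height = worlds[[1]]$height,
                                                barrier_size = 3L)) {
  structure(list(worlds = worlds, episodes_per_world = episodes_per_world,
                 params = params), class = "sr_task")
}

# Pure-R reference episode mirroring the compiled runner's RNG draws exactly.
reference_episode <- function(agent, world, cap = 200L) {
  vt <- grow_agent_for_world(agent, world)
  arrays <- egosr:::world_arrays(agent, world)
  starts <- arrays$start_cells
  i <- min(length(starts) - 1L, floor(stats::runif(1) * length(starts)))
  cA <- starts[i + 1L]
  xy <- egosr:::allo_coords(world, cA)
  d <- min(3L, floor(stats::runif(1) * 4))
  state <- agent_state(xy[1], xy[2], d)
  n <- 0L; counted <- 0L; done <- FALSE
  while (n < cap && !done) {
    out <- egosr:::agent_act_and_learn(agent, world, state, vt)
    state <- out$state; done <- out$done
    n <- n + 1L; counted <- counted + as.integer(out$counted)
  }
  list(counted = counted, primitive = n, done = done, state = state)
}

make_small_task <- function(seed = 4, width = 10, height = 10, attempts = 2,
                            n_ep = 10) {
  set.seed(seed)
  p <- generator_params("ALIGNED_FIXED", width = width, height = height,
                        barrier_size = 3, attempts = attempts)
  generate_task(p, episodes_per_world = n_ep)
}
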