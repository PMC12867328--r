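# Linear Q over concatenated two-frame SR features, epsilon-softmax action
# selection, ADAM-based Q-learning, and lesion variants.

LESION_VARIANTS <- c("FULL", "ALLO_ONLY", "EGO_ONLY", "EGO_QLEARNER", "NO_ADAM")

variant_code <- function(variant) {
  match.arg(variant, LESION_VARIANTS)
  match(variant, LESION_VARIANTS) - 1L
}

#' Agent hyperparameter configuration
#'
#' Defaults were fixed once by a small search that tuned the parameters
#' shared with the lesioned baseline for that baseline's performance first
#' and the egocentric parameters on top; they are documented, with units and
#' rationale, in the package vignette.
#'
#' @param gamma_a,gamma_e SR discounts for the allocentric and egocentric
#'   frames.
#' @param gamma_q Q-learning discount (defaults to `gamma_a`).
#' @param alpha_a,alpha_e SR TD learning rates.
#' @param eta ADAM step size.
#' @param beta1,beta2,eps_adam ADAM moment decays and stabiliser.
#' @param epsilon Uniform-exploration probability.
#' @param tau Softmax temperature.
#' @param step_cap Primitive-step cap per episode (truncation).
#' @param adam_no_sqrt If `TRUE`, uses the literal update
#'   `w <- w + eta * mhat / vhat` (no square root, no stabiliser) instead of
#'   the standard ADAM step.
#' @return A named list of class `agent_config`.
#' @export
agent_config <- function(gamma_a = 0.95, gamma_e = 0.95, gamma_q = gamma_a,
                         alpha_a = 0.05, alpha_e = 0.05, eta = 0.005,
                         beta1 = 0.9, beta2 = 0.999, eps_adam = 1e-8,
                         epsilon = 0.1, tau = 0.2, step_cap = 10000L,
                         adam_no_sqrt = FALSE) {
  cfg <- list(gamma_a = gamma_a, gamma_e = gamma_e, gamma_q = gamma_q,
              alpha_a = alpha_a, alpha_e = alpha_e, eta = eta, beta1 = beta1,
              beta2 = beta2, eps_adam = eps_adam, epsilon = epsilon,
              tau = tau, step_cap = as.integer(step_cap),
              adam_no_sqrt = isTRUE(adam_no_sqrt))
  for (nm in c("gamma_a", "gamma_e", "gamma_q"))
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      abort(sprintf("%s must be in (0, 1)", nm))
  for (nm in c("alpha_a", "alpha_e", "eta"))
    if (cfg[[nm]] < 0) abort(sprintf("%s must be >= 0", nm))
  if (cfg$epsilon < 0 || cfg$epsilon > 1) abort("epsilon must be in [0, 1]")
  if (cfg$tau <= 0) abort("tau must be > 0")
  structure(cfg, class = c("agent_config", "list"))
}

#' Build a composite SR navigation agent for a task
#'
#' Initialises the allocentric SR from the empty walled world, the egocentric
#' SR from the across-world average egocentric transition matrix of the task,
#' and a zero weight vector with fresh optimizer state. Lesioned variants
#' omit the absent pathway's tables: `ALLO_ONLY` carries no egocentric SR,
#' `EGO_ONLY` no allocentric tables, `EGO_QLEARNER` uses the allocentric SR
#' plus a one-hot egocentric state feature (no egocentric SR), and `NO_ADAM`
#' is the full agent with a plain (non-adaptive) gradient step.
#'
#' The agent is a mutable environment: SR tables, weights and optimizer
#' moments are updated in place as it acts. SR tables are stored transposed
#' (`[target, source]`) so the SR vector of a state is a contiguous column.
#'
#' @param task An `sr_task`.
#' @param H Egocentric horizon.
#' @param config An [agent_config()].
#' @param variant Lesion variant, one of
#'   `"FULL"`, `"ALLO_ONLY"`, `"EGO_ONLY"`, `"EGO_QLEARNER"`, `"NO_ADAM"`.
#' @return An `sr_agent` environment.
#' @export
sr_agent <- function(task, H = 2L, config = agent_config(),
                     variant = "FULL") {
  variant <- match.arg(variant, LESION_VARIANTS)
  width <- task$params$width; height <- task$params$height
  nA <- (width - 2L) * (height - 2L)
  use_allo <- variant != "EGO_ONLY"
  use_ego_sr <- variant %in% c("FULL", "NO_ADAM", "EGO_ONLY")
  use_ego <- use_ego_sr || variant == "EGO_QLEARNER"

  ag <- new.env(parent = emptyenv())
  ag$variant <- variant
  ag$H <- as.integer(H)
  ag$cfg <- config
  ag$width <- width; ag$height <- height
  ag$n_allo <- nA
  ag$codebook <- ego_codebook(H)
  ag$view_tables <- list()

  if (use_allo) {
    sr <- init_allocentric_sr(config$gamma_a, width, height)
    ag$Ms_A <- t(sr$M_s)
    ag$M_A <- lapply(sr$M, t)
  } else {
    ag$Ms_A <- matrix(0, nA, nA) # carried but never read or written
    ag$M_A <- lapply(1:4, function(a) matrix(0, nA, nA))
  }
  if (use_ego) {
    if (use_ego_sr) {
      sr_e <- init_egocentric_sr(task, config$gamma_e, ag$codebook)
      ag$Ms_E <- t(sr_e$M_s)
      ag$M_E <- lapply(sr_e$M, t)
      ag$view_tables <- sr_e$view_tables
    } else {
      ag$view_tables <- lapply(task$worlds, enumerate_world_views,
                               codebook = ag$codebook)
      ag$Ms_E <- matrix(0, 0L, 0L) # one-hot features: no egocentric SR
      ag$M_E <- lapply(1:4, function(a) matrix(0, 0L, 0L))
    }
  } else {
    ag$Ms_E <- matrix(0, 0L, 0L)
    ag$M_E <- lapply(1:4, function(a) matrix(0, 0L, 0L))
  }
  ag$n_ego <- if (use_ego) n_views(ag$codebook) else 0L
  ntot <- nA + ag$n_ego
  ag$w <- numeric(ntot)
  ag$m <- numeric(ntot)
  ag$v <- numeric(ntot)
  ag$t <- 0
  ag$world_keys <- vapply(task$worlds, world_key, character(1))
  class(ag) <- "sr_agent"
  ag
}

world_key <- function(world) {
  paste0(paste(world$cells, collapse = ""), "|",
         paste(world$reward, collapse = ","))
}

#' @export
print.sr_agent <- function(x, ...) {
  cat(sprintf("<sr_agent %s: N_A=%d, N_E=%d, H=%d, t=%d>\n", x$variant,
              x$n_allo, x$n_ego, x$H, as.integer(x$t)))
  invisible(x)
}

#' Grow an agent to cover a world's egocentric views
#'
#' Enumerates the world's views; views not yet in the codebook are appended,
#' their state-state SR rows initialised to the codebook-wide mean row, new
#' columns to zero, and the weight vector and optimizer moments extended with
#' zeros. A no-op for worlds whose views are already known.
#'
#' @param agent An `sr_agent`.
#' @param world A `gridworld`.
#' @return The world's view index table (invisibly stored on the agent too).
#' @export
grow_agent_for_world <- function(agent, world) {
  key <- world_key(world)
  hit <- match(key, agent$world_keys)
  if (!is.na(hit) && hit <= length(agent$view_tables) &&
      !is.null(agent$view_tables[[hit]]))
    return(invisible(agent$view_tables[[hit]]))
  u <- agent_uses(agent)
  use_ego <- u$ego_sr || u$ego_onehot
  if (!use_ego) {
    vt <- rep(-1L, n_allo_states(world) * 4L)
  } else {
    old_n <- n_views(agent$codebook)
    vt <- enumerate_world_views(world, agent$codebook)
    new_n <- n_views(agent$codebook)
    if (new_n > old_n) {
      k <- new_n - old_n
      if (u$ego_sr) {
        grow <- function(M) {
          out <- matrix(0, new_n, new_n)
          if (old_n > 0) {
            out[1:old_n, 1:old_n] <- M
            mean_row <- rowMeans(M) # stored transposed: mean SR row
            out[1:old_n, (old_n + 1):new_n] <- mean_row
          }
          out
        }
        agent$Ms_E <- grow(agent$Ms_E)
        agent$M_E <- lapply(agent$M_E, grow)
      }
      agent$n_ego <- new_n
      agent$w <- c(agent$w, numeric(k))
      agent$m <- c(agent$m, numeric(k))
      agent$v <- c(agent$v, numeric(k))
    }
  }
  if (is.na(hit)) {
    agent$world_keys <- c(agent$world_keys, key)
    hit <- length(agent$world_keys)
  }
  agent$view_tables[[hit]] <- vt
  invisible(vt)
}

#' Save and restore an agent checkpoint
#'
#' Serialises the complete learned state — SR tables, codebook, weights,
#' optimizer moments and step counter — to an R data container with a JSON
#' sidecar describing shapes and hyperparameters, so a run can be resumed or
#' a trained checkpoint analysed later. (Resumption also needs the RNG state;
#' capture `.Random.seed` alongside if exact continuation matters.)
#'
#' @param agent An `sr_agent`.
#' @param path File path for the checkpoint (`.rds`); the sidecar is written
#'   to `paste0(path, ".json")`.
#' @return `path` invisibly ([save_agent()]); an `sr_agent`
#'   ([load_agent()]).
#' @export
save_agent <- function(agent, path) {
  obj <- list(variant = agent$variant, H = agent$H, cfg = agent$cfg,
              width = agent$width, height = agent$height,
              n_allo = agent$n_allo, n_ego = agent$n_ego,
              codebook_keys = agent$codebook$keys,
              Ms_A = agent$Ms_A, M_A = agent$M_A, Ms_E = agent$Ms_E,
              M_E = agent$M_E, w = agent$w, m = agent$m, v = agent$v,
              t = agent$t, world_keys = agent$world_keys,
              view_tables = agent$view_tables)
  saveRDS(obj, path)
  side <- list(variant = obj$variant, H = obj$H, n_allo = obj$n_allo,
               n_ego = obj$n_ego, t = obj$t, config = unclass(obj$cfg))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) {
  obj <- readRDS(path)
  ag <- new.env(parent = emptyenv())
  for (nm in setdiff(names(obj), "codebook_keys")) ag[[nm]] <- obj[[nm]]
  cb <- ego_codebook(obj$H)
  for (key in obj$codebook_keys) {
    assign(key, length(cb$keys), envir = cb$map)
    cb$keys <- c(cb$keys, key)
  }
  ag$codebook <- cb
  class(ag) <- "sr_agent"
  ag
}

# Per-variant feature-block usage flags.
agent_uses <- function(agent) {
  list(allo = agent$variant != "EGO_ONLY",
       ego_sr = agent$variant %in% c("FULL", "NO_ADAM", "EGO_ONLY"),
       ego_onehot = agent$variant == "EGO_QLEARNER")
}

#' Feature vector for one state-action pair
#'
#' Concatenation of the allocentric state-action SR row for the
#' frame-rotated action and the egocentric state-action SR row:
#' `[M_A[, | s_A, R_d^{-1}(a)], M_E[, | s_E, a]]`. Lesioned variants zero the
#' absent block; the egocentric Q-learner replaces the egocentric SR row with
#' a one-hot of the view index.
#'
#' @param agent An `sr_agent`.
#' @param s_A 0-based allocentric cell index.
#' @param s_E 0-based egocentric view index (ignored by `ALLO_ONLY`).
#' @param d Head direction 0-3.
#' @param a Ego action 0-3.
#' @return Numeric vector of length `N_A + N_E`.
#' @export
feature_vector <- function(agent, s_A, s_E, d, a) {
  u <- agent_uses(agent)
  fa <- numeric(agent$n_allo)
  if (u$allo) {
    aA <- (d + a) %% 4L
    fa <- agent$M_A[[aA + 1L]][, s_A + 1L]
  }
  fe <- numeric(agent$n_ego)
  if (u$ego_sr && agent$n_ego > 0) fe <- agent$M_E[[a + 1L]][, s_E + 1L]
  if (u$ego_onehot) fe[s_E + 1L] <- 1
  c(fa, fe)
}

#' Q-values of the four egocentric actions
#'
#' `Q(s, a) = w . feature_vector(s, a)` for each ego action.
#'
#' @inheritParams feature_vector
#' @return Numeric vector of 4 action values (ego-action order).
#' @export
q_values <- function(agent, s_A, s_E, d) {
  vapply(0:3, function(a)
    sum(agent$w * feature_vector(agent, s_A, s_E, d, a)), numeric(1))
}

#' Epsilon-softmax action selection
#'
#' With probability `epsilon` a uniform action; otherwise a draw from
#' `softmax(q / tau)` with max-subtraction. Consumes exactly two uniform
#' variates from the R stream on either branch, mirroring the compiled
#' simulator's draws.
#'
#' @param q Numeric vector of 4 finite action values.
#' @param epsilon Uniform-exploration probability.
#' @param tau Softmax temperature (> 0).
#' @return Ego action index 0-3.
#' @export
select_action <- function(q, epsilon, tau) {
  if (any(!is.finite(q))) abort("action values must be finite")
  if (tau <= 0) abort("tau must be > 0")
  u1 <- stats::runif(1)
  if (u1 < epsilon) return(min(3L, as.integer(floor(stats::runif(1) * 4))))
  p <- exp((q - max(q)) / tau)
  u2 <- stats::runif(1) * sum(p)
  acc <- cumsum(p)
  min(which(u2 <= acc)[1] - 1L, 3L)
}

#' One semi-gradient Q-learning step with ADAM
#'
#' Computes the TD error
#' `delta = r + gamma_q * max_a' Q(s', a') - Q(s, a)` (no bootstrap on
#' terminal transitions), forms the gradient `g = delta * feature_vector`,
#' and applies a bias-corrected ADAM update to the full weight vector. The
#' `NO_ADAM` variant takes a plain step `w <- w + eta * g`.
#'
#' @param agent An `sr_agent` (modified in place).
#' @param s_A,s_E,d Pre-step state indices.
#' @param a Ego action taken.
#' @param r Reward received.
#' @param s_A2,s_E2,d2 Post-step state indices.
#' @param done Terminal flag.
#' @return The TD error, invisibly.
#' @export
adam_q_update <- function(agent, s_A, s_E, d, a, r, s_A2, s_E2, d2, done) {
  cfg <- agent$cfg
  qsa <- sum(agent$w * feature_vector(agent, s_A, s_E, d, a))
  qmax <- if (done) 0 else max(q_values(agent, s_A2, s_E2, d2))
  delta <- r + (if (done) 0 else cfg$gamma_q * qmax) - qsa
  g <- delta * feature_vector(agent, s_A, s_E, d, a)
  agent$t <- agent$t + 1
  if (agent$variant == "NO_ADAM") {
    agent$w <- agent$w + cfg$eta * g
  } else {
    agent$m <- cfg$beta1 * agent$m + (1 - cfg$beta1) * g
    agent$v <- cfg$beta2 * agent$v + (1 - cfg$beta2) * g^2
    mhat <- agent$m / (1 - cfg$beta1^agent$t)
    vhat <- agent$v / (1 - cfg$beta2^agent$t)
    agent$w <- if (cfg$adam_no_sqrt)
      agent$w + ifelse(vhat == 0, 0, cfg$eta * mhat / vhat)
    else agent$w + cfg$eta * mhat / (sqrt(vhat) + cfg$eps_adam)
  }
  invisible(delta)
}

# Reference (pure-R) implementation of one act-and-learn step; mirrors the
# compiled path bit for bit, including RNG draw order and the convention that
# the Q update reads the concurrently updated SR tables.
agent_act_and_learn <- function(agent, world, state, view_table) {
  cfg <- agent$cfg
  u <- agent_uses(agent)
  use_ego <- u$ego_sr || u$ego_onehot
  s_A <- allo_index(world, state$x, state$y)
  s_E <- if (use_ego) view_table[s_A * 4L + state$d + 1L] else 0L
  q <- q_values(agent, s_A, s_E, state$d)
  a <- select_action(q, cfg$epsilon, cfg$tau)
  res <- step(world, state, a)
  s_A2 <- allo_index(world, res$state$x, res$state$y)
  s_E2 <- if (use_ego) view_table[s_A2 * 4L + res$state$d + 1L] else 0L
  aA <- (state$d + a) %% 4L
  if (u$allo) {
    MsT <- t(agent$Ms_A)
    MsT <- td_update_state_sr(MsT, s_A, s_A2, cfg$alpha_a, cfg$gamma_a,
                              res$done)
    MT <- lapply(agent$M_A, t)
    MT <- td_update_state_action_sr(MT, MsT, s_A, aA, s_A2, cfg$alpha_a,
                                    cfg$gamma_a, res$done)
    agent$Ms_A <- t(MsT)
    agent$M_A <- lapply(MT, t)
  }
  if (u$ego_sr) {
    MsT <- t(agent$Ms_E)
    MsT <- td_update_state_sr(MsT, s_E, s_E2, cfg$alpha_e, cfg$gamma_e,
                              res$done)
    MT <- lapply(agent$M_E, t)
    MT <- td_update_state_action_sr(MT, MsT, s_E, a, s_E2, cfg$alpha_e,
                                    cfg$gamma_e, res$done)
    agent$Ms_E <- t(MsT)
    agent$M_E <- lapply(MT, t)
  }
  adam_q_update(agent, s_A, s_E, state$d, a, res$reward, s_A2, s_E2,
                res$state$d, res$done)
  list(state = res$state, action = a, reward = res$reward, done = res$done,
       counted = a == 0L)
}
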