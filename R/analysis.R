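# Value decomposition, dual-frame SR visualisation exports, and the two GLM
# analyses.

#' Decompose the learned value function into frame components
#'
#' For every traversable `(x, y, d)` state the greedy action
#' `a* = argmax_a Q(s, a)` is found (ties broken by the fixed action order)
#' and the value is split into the allocentric-block and egocentric-block
#' contributions at `a*`: `V = V_a + V_e` exactly, by linearity of the
#' Q-function. `V_e` is averaged over head directions to give `v_e_mean`,
#' with per-direction residuals `v_e - v_e_mean`.
#'
#' @param agent A trained `sr_agent`.
#' @param world A `gridworld` whose views are covered by the agent's
#'   codebook.
#' @return A `value_decomposition` tibble with columns `x`, `y`, `d`,
#'   `action`, `v`, `v_a`, `v_e`, `v_e_mean`, `v_e_resid`.
#' @export
decompose_value <- function(agent, world) {
  if (!length(agent$w) || agent$t == 0)
    abort("agent has no trained weights to decompose")
  u <- agent_uses(agent)
  use_ego <- u$ego_sr || u$ego_onehot
  vt <- grow_agent_for_world(agent, world)
  nA <- agent$n_allo
  wA <- agent$w[seq_len(nA)]
  wE <- if (agent$n_ego > 0) agent$w[nA + seq_len(agent$n_ego)] else numeric()
  rows <- list()
  for (y in 1:(world$height - 2L)) for (x in 1:(world$width - 2L)) {
    if (!is_traversable(world, x, y)) next
    s <- allo_index(world, x, y)
    for (d in 0:3) {
      sE <- if (use_ego) vt[s * 4L + d + 1L] else 0L
      qa <- numeric(4); qe <- numeric(4)
      for (a in 0:3) {
        if (u$allo) {
          aA <- (d + a) %% 4L
          qa[a + 1L] <- sum(wA * agent$M_A[[aA + 1L]][, s + 1L])
        }
        if (u$ego_sr) qe[a + 1L] <- sum(wE * agent$M_E[[a + 1L]][, sE + 1L])
        else if (u$ego_onehot) qe[a + 1L] <- wE[sE + 1L]
      }
      q <- qa + qe
      astar <- which.max(q) # first maximum: fixed-order tie-break
      rows[[length(rows) + 1L]] <-
        c(x = x, y = y, d = d, action = astar - 1L, v = q[astar],
          v_a = qa[astar], v_e = qe[astar])
    }
  }
  out <- as_tibble(do.call(rbind, rows))
  out <- out %>%
    group_by(.data$x, .data$y) %>%
    mutate(v_e_mean = mean(.data$v_e),
           v_e_resid = .data$v_e - .data$v_e_mean) %>%
    ungroup()
  class(out) <- c("value_decomposition", class(out))
  out
}

#' Egocentric-frame plot data for an egocentric SR row
#'
#' Bins the expected future occupancies in one egocentric state-state SR row
#' into 5 equal-width bins between the smallest and largest positive entry
#' and returns the views falling in the top 3 bins (the top 60% of the
#' occupancy range), in descending bin order. Zero-occupancy views are
#' excluded. Bin membership is invariant to positive rescaling of the row.
#'
#' @param agent An `sr_agent` with an egocentric SR.
#' @param view_index 0-based codebook index of the source view.
#' @param n_bins,top_bins Number of bins and how many top bins to return.
#' @param quantile_bins If `TRUE`, uses equal-count (quantile) bins instead
#'   of equal-width bins.
#' @return A tibble with `bin` (1 = highest occupancy), `bin_lo`, `bin_hi`,
#'   `view_index`, `occupancy`.
#' @export
ego_sr_egocentric_plot_data <- function(agent, view_index, n_bins = 5L,
                                        top_bins = 3L,
                                        quantile_bins = FALSE) {
  if (agent$n_ego == 0L) abort("agent has no egocentric SR")
  row <- agent$Ms_E[, view_index + 1L]
  pos <- which(row > 0)
  if (!length(pos)) abort("SR row has no positive occupancies")
  occ <- row[pos]
  if (max(occ) == min(occ)) # degenerate row: everything is top-bin
    return(tibble(bin = rep(1L, length(occ)), bin_lo = min(occ),
                  bin_hi = max(occ), view_index = pos - 1L, occupancy = occ))
  brk <- if (quantile_bins)
    stats::quantile(occ, probs = seq(0, 1, length.out = n_bins + 1L))
  else seq(min(occ), max(occ), length.out = n_bins + 1L)
  brk[1] <- brk[1] - 1e-12
  bin_raw <- cut(occ, breaks = brk, labels = FALSE) # 1 = lowest bin
  bin <- n_bins + 1L - bin_raw # 1 = highest-occupancy bin
  keep <- bin <= top_bins
  tibble(bin = bin[keep],
         bin_lo = brk[bin_raw[keep]], bin_hi = brk[bin_raw[keep] + 1L],
         view_index = pos[keep] - 1L, occupancy = occ[keep]) %>%
    arrange(.data$bin, dplyr::desc(.data$occupancy))
}

#' Allocentric-frame plot data for an egocentric SR row
#'
#' Four direction-indexed heat maps: the value at `(x, y)` of map `d` is the
#' expected future occupancy of the egocentric state associated with position
#' `(x, y)` and head direction `d`. States sharing a view (aliasing) produce
#' constant-valued blocks.
#'
#' @param agent An `sr_agent` with an egocentric SR.
#' @param view_index 0-based source view index.
#' @param world A `gridworld` consistent with the agent's codebook; an error
#'   is raised if any view of the world is absent from the codebook.
#' @return A tibble with `x`, `y`, `d`, `occupancy`.
#' @export
ego_sr_allocentric_plot_data <- function(agent, view_index, world) {
  if (agent$n_ego == 0L) abort("agent has no egocentric SR")
  key <- world_key(world)
  hit <- match(key, agent$world_keys)
  if (is.na(hit) || hit > length(agent$view_tables) ||
      is.null(agent$view_tables[[hit]]))
    abort("world's views are not in the agent's codebook (codebook/world mismatch)")
  vt <- agent$view_tables[[hit]]
  row <- agent$Ms_E[, view_index + 1L]
  rows <- list()
  for (y in 1:(world$height - 2L)) for (x in 1:(world$width - 2L)) {
    if (!is_traversable(world, x, y)) next
    s <- allo_index(world, x, y)
    for (d in 0:3) {
      v <- vt[s * 4L + d + 1L]
      rows[[length(rows) + 1L]] <- c(x = x, y = y, d = d,
                                     occupancy = row[v + 1L])
    }
  }
  as_tibble(do.call(rbind, rows))
}

#' Occupancy features of an episode trajectory
#'
#' Proportions of primitive steps whose resulting position is (a) within
#' Chebyshev distance 1 of a boundary wall, (b) in the barrier region (cavity
#' cells or cells within distance 1 of the barrier footprint) of the current
#' world, and (c) in the barrier region of the world `k` switches earlier,
#' for each `k` up to `world_index - 1`.
#'
#' @param record An `episode_record` with a trajectory (see [run_episode()]).
#' @param task The `sr_task` the episode came from.
#' @param world_index 1-based index of the world the episode ran in.
#' @return A tibble with `f_walls`, `f_current` and `f_prev_k` columns.
#' @export
occupancy_features <- function(record, task, world_index) {
  if (world_index < 1L || world_index > length(task$worlds))
    abort("world index out of range")
  world <- task$worlds[[world_index]]
  traj <- record$trajectory
  if (is.null(traj)) abort("record carries no trajectory")
  # positions after each primitive step (drop the start state)
  pos <- traj[-1L, c("x", "y")]
  n <- nrow(pos)
  if (n == 0L) abort("empty trajectory")
  idx <- allo_index(world, pos$x, pos$y) + 1L
  nw <- near_wall_mask(world)
  out <- tibble(f_walls = sum(nw[idx]) / n,
                f_current = sum(barrier_region_mask(world)[idx]) / n)
  k_max <- world_index - 1L
  K <- length(task$worlds)
  for (k in seq_len(K - 1L)) {
    out[[paste0("f_prev_", k)]] <- if (k <= k_max)
      sum(barrier_region_mask(world, task$worlds[[world_index - k]])[idx]) / n
    else NA_real_
  }
  out
}

glm_fit_tibble <- function(fit, extra = list()) {
  sm <- summary(fit)$coefficients
  out <- tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                std_error = unname(sm[, 2]), statistic = unname(sm[, 3]),
                p_value = unname(sm[, 4]))
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Poisson GLM of per-world mean steps on barrier count
#'
#' Fits `log E[mean steps] = b0 + b1 * barrier count` by Poisson regression
#' with a log link, with the number of barrier-labelled pixels as the
#' barrier-count proxy. Fits are per task seed; use
#' [aggregate_barrier_glm()] to summarise the slope across seeds.
#'
#' @param data A data frame with columns `mean_steps` and `barrier_pixels`
#'   (one row per world).
#' @return A `sr_glm` object wrapping the fit, with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
fit_barrier_poisson_glm <- function(data) {
  if (nrow(data) < 2L) abort("need at least 2 worlds")
  if (length(unique(data$barrier_pixels)) < 2L)
    abort("barrier count regressor is constant")
  if (any(!is.finite(data$mean_steps))) abort("non-finite response")
  fit <- withCallingHandlers(
    stats::glm(mean_steps ~ barrier_pixels, data = data,
               family = stats::poisson()),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, kind = "barrier_poisson", link = "log"),
            class = "sr_glm")
}

#' Aggregate per-seed barrier GLM slopes
#'
#' Fits the barrier Poisson GLM once per task seed and variant from an
#' `sr_comparison` and reports the mean and standard deviation of the
#' barrier-count coefficient across seeds.
#'
#' @param comparison An `sr_comparison` tibble (with `world_info` attribute).
#' @return A tibble with `variant`, `beta1_mean`, `beta1_sd`, `n_seeds`.
#' @export
aggregate_barrier_glm <- function(comparison) {
  wi <- attr(comparison, "world_info")
  if (is.null(wi)) abort("comparison lacks world_info")
  per_world <- comparison %>%
    group_by(.data$variant, .data$task_seed, .data$world) %>%
    summarise(mean_steps = mean(.data$counted_steps), .groups = "drop") %>%
    left_join(wi, by = c("task_seed", "world"))
  per_world %>%
    group_by(.data$variant, .data$task_seed) %>%
    dplyr::group_modify(function(df, key) {
      fit <- fit_barrier_poisson_glm(df)
      tibble(beta1 = generics::tidy(fit)$estimate[2])
    }) %>%
    group_by(.data$variant) %>%
    summarise(beta1_mean = mean(.data$beta1), beta1_sd = stats::sd(.data$beta1),
              n_seeds = dplyr::n(), .groups = "drop")
}

#' Logistic GLM distinguishing lesioned from full agents by occupancy
#'
#' Fits, separately within each chunk of `chunk_size` episodes,
#' `logit P(lesioned) = b0 + b_walls f_walls + b_current f_current +
#' sum_k b_k f_k` on single-episode occupancy proportions. Features that are
#' entirely missing (no previously seen world) are dropped; perfect
#' separation is detected and reported on the output rather than silently
#' dropped.
#'
#' @param data A data frame with columns `lesioned` (logical or 0/1),
#'   `episode_global`, `f_walls`, `f_current` and `f_prev_*`.
#' @param chunk_size Episodes per chunk (default 25).
#' @return A tibble of per-chunk coefficients: `chunk`, `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `separation`.
#' @export
fit_occupancy_logistic_glm <- function(data, chunk_size = 25L) {
  if (length(unique(data$lesioned)) < 2L)
    abort("both agent classes must be present")
  data$chunk <- (data$episode_global - 1L) %/% chunk_size + 1L
  fk <- grep("^f_prev_", names(data), value = TRUE)
  out <- lapply(split(data, data$chunk), function(df) {
    feats <- c("f_walls", "f_current",
               fk[vapply(fk, function(cn) all(!is.na(df[[cn]])) &&
                           any(df[[cn]] != 0), logical(1))])
    form <- stats::as.formula(paste("lesioned ~",
                                    paste(feats, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(form, data = df,
                                       family = stats::binomial()))
    eps <- 1e-8
    sep <- !fit$converged ||
      any(fit$fitted.values > 1 - eps | fit$fitted.values < eps)
    glm_fit_tibble(fit, extra = list(chunk = df$chunk[1], separation = sep))
  })
  dplyr::bind_rows(out)
}

#' @export
print.sr_glm <- function(x, ...) {
  cat(sprintf("<sr_glm %s (%s link)>\n", x$kind, x$link))
  print(generics::tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sr_glm <- function(x, ...) glm_fit_tibble(x$fit)

#' @export
glance.sr_glm <- function(x, ...) {
  fit <- x$fit
  tibble(null_deviance = fit$null.deviance, df_null = fit$df.null,
         deviance = fit$deviance, df_residual = fit$df.residual,
         aic = fit$aic, nobs = length(fit$y))
}

#' @export
tidy.value_decomposition <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.value_decomposition <- function(x, ...) {
  tibble(n_states = nrow(x),
         v_range = max(x$v) - min(x$v),
         max_decomposition_error = max(abs(x$v - (x$v_a + x$v_e))))
}
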