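# ggplot2 display methods for worlds, comparisons and value decompositions.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_vline
#'   facet_wrap labs scale_fill_viridis_c scale_fill_manual coord_equal
#'   theme_minimal geom_ribbon
#' @export
ggplot2::autoplot

#' Plot a gridworld
#'
#' Tile map of the cell grid with the reward marked.
#'
#' @param world A `gridworld`.
#' @return A ggplot object.
#' @export
plot_world <- function(world) {
  nA <- n_allo_states(world)
  all_xy <- expand.grid(x = 0:(world$width - 1L), y = 0:(world$height - 1L))
  lab <- names(cell_codes())[world$cells[as.matrix(all_xy) + 1L] + 1L]
  df <- tibble(x = all_xy$x, y = all_xy$y, cell = lab)
  if (!is.null(world$reward))
    df$cell[df$x == world$reward[1] & df$y == world$reward[2]] <- "REWARD"
  cols <- c(EMPTY = "white", BARRIER = "grey55", WALL_N = "grey20",
            WALL_E = "grey30", WALL_S = "grey40", WALL_W = "grey10",
            REWARD = "seagreen3")
  ggplot(df, aes(.data$x, .data$y, fill = .data$cell)) +
    geom_tile(colour = "grey85", linewidth = 0.1) +
    scale_fill_manual(values = cols) +
    coord_equal() + theme_minimal() + labs(x = NULL, y = NULL)
}

#' @rdname run_paradigm_comparison
#' @param object An `sr_comparison` tibble.
#' @param window Rolling-mean window (episodes) applied to the curves for
#'   display.
#' @param ... Unused.
#' @export
autoplot.sr_comparison <- function(object, window = 25L, ...) {
  curves <- learning_curves(object)
  roll <- function(z) stats::filter(z, rep(1 / window, window), sides = 1)
  curves <- curves %>% group_by(.data$variant) %>%
    arrange(.data$episode_global, .by_group = TRUE) %>%
    mutate(smooth = as.numeric(roll(.data$mean_steps))) %>% ungroup()
  switches <- curves %>% group_by(.data$world) %>%
    summarise(at = min(.data$episode_global), .groups = "drop") %>%
    filter(.data$world > 1)
  ggplot(curves, aes(.data$episode_global, .data$smooth,
                     colour = .data$variant)) +
    geom_line(na.rm = TRUE) +
    geom_vline(data = switches, aes(xintercept = .data$at),
               linetype = "dashed", colour = "grey60") +
    theme_minimal() +
    labs(x = "episode", y = sprintf("mean counted steps (window %d)", window),
         colour = "agent")
}

#' @rdname decompose_value
#' @param object A `value_decomposition` tibble.
#' @param component One of `"value"` (head-direction-averaged total value),
#'   `"components"` (allocentric vs egocentric-mean maps) or `"residuals"`
#'   (per-direction egocentric residuals).
#' @param ... Unused.
#' @export
autoplot.value_decomposition <- function(object,
                                         component = c("value", "components",
                                                       "residuals"), ...) {
  component <- match.arg(component)
  if (component == "residuals") {
    df <- object %>% mutate(dir = factor(DIR_NAMES[.data$d + 1L],
                                         levels = DIR_NAMES))
    return(ggplot(df, aes(.data$x, .data$y, fill = .data$v_e_resid)) +
             geom_tile() + facet_wrap(~dir) + coord_equal() +
             scale_fill_viridis_c() + theme_minimal() +
             labs(fill = "egocentric residual"))
  }
  by_cell <- object %>% group_by(.data$x, .data$y) %>%
    summarise(v = mean(.data$v), v_a = mean(.data$v_a),
              v_e = mean(.data$v_e), .groups = "drop")
  if (component == "value")
    return(ggplot(by_cell, aes(.data$x, .data$y, fill = .data$v)) +
             geom_tile() + coord_equal() + scale_fill_viridis_c() +
             theme_minimal() + labs(fill = "V"))
  long <- tidyr::pivot_longer(by_cell, c("v_a", "v_e"),
                              names_to = "part", values_to = "value")
  ggplot(long, aes(.data$x, .data$y, fill = .data$value)) +
    geom_tile() + facet_wrap(~part) + coord_equal() +
    scale_fill_viridis_c() + theme_minimal()
}
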