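#' Plot a value map
#'
#' Tile plot of a `width x height` value map in map orientation (north up),
#' with walls hatched out and goals/start marked when a world is supplied.
#'
#' @param value_map a value matrix indexed `[x, y]`.
#' @param world optional [gridworld()] for wall/goal/start overlays.
#' @return A ggplot object.
#' @export
plot_value_map <- function(value_map, world = NULL) {
  df <- expand.grid(x = seq_len(nrow(value_map)),
                    y = seq_len(ncol(value_map)))
  df$value <- value_map[cbind(df$x, df$y)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x", y = "y", fill = "value")
  if (!is.null(world)) {
    walls <- which(!world$passable, arr.ind = TRUE)
    p <- p +
      ggplot2::annotate("point", x = walls[, 1], y = walls[, 2],
                        shape = 4, size = 1, colour = "grey40") +
      ggplot2::annotate("point", x = world$goals$x, y = world$goals$y,
                        shape = 21, size = 3, fill = "green") +
      ggplot2::annotate("point", x = world$start[1], y = world$start[2],
                        shape = 22, size = 3, fill = "black")
  }
  p
}

#' Plot smoothed learning curves
#'
#' Cross-run mean of a per-episode metric, smoothed with the trailing
#' 11-episode window, one line per agent, with a +/- SD ribbon.
#'
#' @param episodes the `episodes` tibble from an experiment runner.
#' @param metric one of `"reward_per_step"`, `"steps"`, `"wall_hits"`.
#' @param window smoothing window (default 11).
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(episodes, metric = "reward_per_step",
                                 window = 11L) {
  stopifnot(metric %in% names(episodes))
  agents <- unique(episodes$agent)
  rows <- lapply(agents, function(a) {
    sub <- episodes[episodes$agent == a, ]
    series <- lapply(split(sub, sub$run), function(r) {
      r[[metric]][order(r$episode)]
    })
    agg <- aggregate_runs(series)
    sm <- moving_stats(agg$mean, window = window)
    tibble::tibble(agent = a, episode = sm$index, mean = sm$mean,
                   sd = moving_stats(agg$sd, window = window)$mean)
  })
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$episode, y = .data$mean,
                                   colour = .data$agent,
                                   fill = .data$agent)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "episode", y = metric)
}

#' Plot a generalization profile
#'
#' Line plot of a ring-averaged value profile from
#' [radial_value_profile()].
#'
#' @param profile tibble with `distance` and `mean_value`.
#' @return A ggplot object.
#' @export
plot_generalization_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$distance,
                                        y = .data$mean_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance from updated square", y = "mean value")
}
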