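#' Per-episode metrics from a transition trace
#'
#' Every executed action counts as a step (wall hits included); the total
#' reward sums signed rewards, so in a painful world it is the entered
#' goal's reward minus the number of wall hits.
#'
#' @param trace a transition tibble as returned by [run_episode()] (columns
#'   `episode`, `reward`, `wall_hit`, ...).
#' @return A tibble with one row per episode: `episode`, `steps`,
#'   `total_reward`, `wall_hits`, `reward_per_step`.
#' @export
episode_metrics <- function(trace) {
  if (is.null(trace) || nrow(trace) == 0) stop("empty trace")
  eps <- sort(unique(trace$episode))
  rows <- lapply(eps, function(e) {
    tr <- trace[trace$episode == e, ]
    tibble::tibble(
      episode = e,
      steps = nrow(tr),
      total_reward = sum(tr$reward),
      wall_hits = sum(tr$wall_hit),
      reward_per_step = sum(tr$reward) / nrow(tr)
    )
  })
  do.call(rbind, rows)
}

#' Trailing moving average and SD
#'
#' Learning curves are smoothed with a trailing window of `window` episodes
#' (the current episode plus the `window - 1` preceding ones, truncated at
#' the head of the series while fewer are available).
#'
#' @param series numeric vector, indexed by episode.
#' @param window window width (default 11).
#' @param sd_type `"population"` (divide by n; the default, since the bands
#'   are descriptive) or `"sample"`.
#' @return A tibble with columns `index`, `mean`, `sd`, `n`.
#' @export
moving_stats <- function(series, window = 11L,
                         sd_type = c("population", "sample")) {
  stopifnot(window >= 1)
  sd_type <- match.arg(sd_type)
  n <- length(series)
  out_mean <- numeric(n)
  out_sd <- numeric(n)
  out_n <- integer(n)
  for (e in seq_len(n)) {
    w <- series[max(1, e - window + 1):e]
    out_mean[e] <- mean(w)
    dev <- w - out_mean[e]
    denom <- if (sd_type == "population") length(w) else max(1, length(w) - 1)
    out_sd[e] <- sqrt(sum(dev^2) / denom)
    out_n[e] <- length(w)
  }
  tibble::tibble(index = seq_len(n), mean = out_mean, sd = out_sd, n = out_n)
}

#' Pointwise aggregation across runs
#'
#' Means and SDs of an episode-indexed metric across runs. Runs of unequal
#' length (e.g. step-budgeted runs ending mid-episode) are aggregated over
#' whichever runs reach each episode, with the per-episode sample size
#' reported.
#'
#' @param per_run_series a list of numeric vectors, one per run.
#' @param sd_type as in [moving_stats()].
#' @return A tibble with columns `index`, `mean`, `sd`, `n`.
#' @export
aggregate_runs <- function(per_run_series,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(per_run_series) == 0) stop("no runs to aggregate")
  len <- max(vapply(per_run_series, length, integer(1)))
  mat <- vapply(per_run_series, function(s) c(s, rep(NA_real_, len - length(s))),
                numeric(len))
  mat <- matrix(mat, nrow = len)
  m <- rowMeans(mat, na.rm = TRUE)
  nn <- rowSums(!is.na(mat))
  dev2 <- (mat - m)^2
  ss <- rowSums(dev2, na.rm = TRUE)
  denom <- if (sd_type == "population") nn else pmax(1, nn - 1)
  s <- sqrt(ss / denom)
  s[nn <= 1 & sd_type == "sample"] <- 0
  tibble::tibble(index = seq_len(len), mean = m, sd = s, n = as.integer(nn))
}

#' Mean value over wall squares
#'
#' The value map averaged over all impassable squares (the border ring
#' included by default); the quantity tracked by the relearning protocol.
#'
#' @param value_map a `width x height` value matrix.
#' @param world the matching [gridworld()].
#' @param include_border include the impassable border ring (default) or
#'   restrict to interior walls.
#' @export
wall_value_mean <- function(value_map, world, include_border = TRUE) {
  stopifnot(nrow(value_map) == world$width, ncol(value_map) == world$height)
  mask <- !world$passable
  if (!include_border) {
    mask[c(1, world$width), ] <- FALSE
    mask[, c(1, world$height)] <- FALSE
  }
  if (!any(mask)) stop("world has no wall squares under this mask")
  mean(value_map[mask])
}

#' Location and size of the value maximum
#'
#' Scans all squares of a value map (walls included), breaking ties toward
#' the smallest `x`, then smallest `y`, and reports the maximum, its
#' position, and the Manhattan distance from that position to the nearest
#' goal -- the diagnostic used to detect aberrant valuation: a healthy
#' agent's maximum sits on a goal.
#'
#' @inheritParams wall_value_mean
#' @return A one-row tibble: `max_value`, `x`, `y`,
#'   `distance_to_nearest_goal`.
#' @export
value_argmax <- function(value_map, world) {
  best <- -Inf
  bx <- 1L; by <- 1L
  for (x in seq_len(nrow(value_map))) {
    for (y in seq_len(ncol(value_map))) {
      if (value_map[x, y] > best) {
        best <- value_map[x, y]
        bx <- x; by <- y
      }
    }
  }
  d <- min(abs(world$goals$x - bx) + abs(world$goals$y - by))
  tibble::tibble(max_value = best, x = bx, y = by,
                 distance_to_nearest_goal = d)
}

#' Snapshot of an agent's value map
#'
#' Alias of [value_map()] named for its role in the experiment protocols
#' (value-function snapshots at selected episodes).
#'
#' @param agent an agent.
#' @param world unused; accepted so callers can pass the environment for
#'   symmetry with the other map summaries.
#' @export
snapshot_value_map <- function(agent, world = NULL) {
  value_map(agent)
}

#' Ring-averaged value profile
#'
#' Averages a value map over rings of (rounded) Euclidean distance from a
#' centre square; the standard way to display a stimulus-generalization
#' gradient: value against distance from the trained square.
#'
#' @param value_map a value matrix.
#' @param center `c(x, y)`.
#' @param max_dist largest ring to report.
#' @return A tibble with columns `distance`, `mean_value`, `n_squares`.
#' @export
radial_value_profile <- function(value_map, center, max_dist = 12L) {
  xs <- rep(seq_len(nrow(value_map)), times = ncol(value_map))
  ys <- rep(seq_len(ncol(value_map)), each = nrow(value_map))
  d <- round(sqrt((xs - center[1])^2 + (ys - center[2])^2))
  v <- as.vector(value_map)
  keep <- d <= max_dist
  agg <- tapply(v[keep], d[keep], mean)
  cnt <- tapply(v[keep], d[keep], length)
  tibble::tibble(
    distance = as.integer(names(agg)),
    mean_value = as.numeric(agg),
    n_squares = as.integer(cnt)
  )
}

#' Write a value map as a CSV grid
#'
#' Exports a `width x height` value map in map orientation (first row is
#' the northernmost `y`, columns are `x`), matching the ASCII maze layout.
#'
#' @param value_map a value matrix indexed `[x, y]`.
#' @param path file path.
#' @export
write_value_map <- function(value_map, path) {
  grid <- t(value_map)[rev(seq_len(ncol(value_map))), , drop = FALSE]
  utils::write.table(grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
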