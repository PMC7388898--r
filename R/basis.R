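#' Specification of the fixed Gaussian basis layer
#'
#' The value network encodes the agent's position as a one-hot indicator
#' over the `width x height` grid (`n_input = 400` units by default) and
#' projects it through a *fixed* connection table onto `n_hidden` (default
#' 900) hidden units. Each hidden unit `k` is a two-dimensional Gaussian
#' receptive field centred at `(a_k, b_k)` with variance `sigma_k^2` drawn
#' from a log-normal distribution whose shape is controlled by the
#' generalization metaparameter `theta`: centres tile the grid evenly and
#' receptive-field widths span narrow to broad, which is what produces a
#' graded stimulus-generalization profile. Optional sparse additive noise
#' (strength `A`, per-entry probability `rho`) models an anomalous encoding
#' and is drawn once, before learning, then frozen.
#'
#' @param theta generalization metaparameter (> 0): larger values give a
#'   wider log-variance spread, i.e. more broad receptive fields.
#' @param n_hidden number of hidden units (default 900).
#' @param width,height grid dimensions (default 20 x 20, so
#'   `n_input = 400`).
#' @param noise_strength noise amplitude `A >= 0` (0 disables noise).
#' @param noise_fraction probability `rho` in `[0, 1]` that an entry of the
#'   connection table receives the additive noise `A`.
#' @return An object of class `basis_spec`.
#' @export
basis_spec <- function(theta = 1, n_hidden = 900L, width = 20L, height = 20L,
                       noise_strength = 0, noise_fraction = 0) {
  if (theta <= 0) stop("theta must be > 0")
  if (noise_strength < 0) stop("noise_strength must be >= 0")
  if (noise_fraction < 0 || noise_fraction > 1) {
    stop("noise_fraction must be in [0, 1]")
  }
  structure(
    list(theta = theta, n_hidden = as.integer(n_hidden),
         width = as.integer(width), height = as.integer(height),
         n_input = as.integer(width * height),
         noise_strength = noise_strength, noise_fraction = noise_fraction),
    class = "basis_spec"
  )
}

#' One-hot position encoding
#'
#' The input-layer indicator: a `width x height` matrix with a single 1 at
#' the agent's position `(x, y)`.
#'
#' @param x,y 1-based position.
#' @param width,height grid dimensions.
#' @export
encode_position <- function(x, y, width = 20L, height = 20L) {
  if (x < 1 || x > width || y < 1 || y > height) {
    stop("position (", x, ",", y, ") outside the ", width, "x", height,
         " grid")
  }
  I <- matrix(0, width, height)
  I[x, y] <- 1
  I
}

# Linear index of position (x, y): p = height*(x-1) + y, p in 1..n_input.
position_index <- function(x, y, height = 20L) {
  as.integer(height * (x - 1L) + y)
}

#' Receptive-field centres
#'
#' Centres tile the grid so that the centre index grows linearly with the
#' hidden-unit index: unit `k` is centred at the position with linear index
#' `L = ceiling(n_input * k / n_hidden)`, i.e. `a_k = floor((L-1)/height)+1`,
#' `b_k = ((L-1) mod height) + 1`.
#'
#' @inheritParams basis_spec
#' @return A tibble with columns `k`, `a`, `b`.
#' @export
basis_centers <- function(n_hidden = 900L, width = 20L, height = 20L) {
  n_input <- width * height
  k <- seq_len(n_hidden)
  L <- ceiling(n_input * k / n_hidden)
  tibble::tibble(
    k = k,
    a = as.integer((L - 1) %/% height + 1),
    b = as.integer((L - 1) %% height + 1)
  )
}

#' Sample receptive-field variances
#'
#' `sigma_k^2 ~ LogN(-0.7/theta, 0.7*theta)`, read as (mean, SD) of the log.
#' Increasing `theta` both raises the median width and, mainly, widens the
#' spread, so some units respond very broadly.
#'
#' @inheritParams basis_spec
#' @return A numeric vector of `n_hidden` positive variances.
#' @export
sample_variances <- function(theta, n_hidden = 900L) {
  if (theta <= 0) stop("theta must be > 0")
  stats::rlnorm(n_hidden, meanlog = -0.7 / theta, sdlog = 0.7 * theta)
}

#' Sample frozen connection noise
#'
#' Each entry of the `n_input x n_hidden` table independently takes the
#' value `A` with probability `rho` and 0 otherwise. The realization is
#' drawn once per run, before learning, and never changed.
#'
#' @param A noise strength (>= 0).
#' @param rho per-entry noise probability in `[0, 1]`.
#' @param n_input,n_hidden table dimensions.
#' @return An `n_input x n_hidden` matrix of 0s and `A`s.
#' @export
sample_noise <- function(A, rho, n_input = 400L, n_hidden = 900L) {
  if (A < 0) stop("noise strength A must be >= 0")
  if (rho < 0 || rho > 1) stop("noise fraction rho must be in [0, 1]")
  if (A == 0 || rho == 0) {
    return(matrix(0, n_input, n_hidden))
  }
  matrix(A * (stats::runif(n_input * n_hidden) < rho), n_input, n_hidden)
}

#' Build the fixed basis network
#'
#' Assembles the connection table
#' `M[p, k] = (exp(-((x - a_k)^2 + (y - b_k)^2) / (2 sigma_k^2)) + eps[p, k]) / n_input`
#' where `p` is the linear index of position `(x, y)`. Variances (and noise,
#' if enabled) are drawn from the current R random stream; call `set.seed()`
#' first for a reproducible network.
#'
#' @param spec a [basis_spec()].
#' @param variances optional explicit variance vector (overrides sampling;
#'   intended for audits and controlled examples).
#' @param noise optional explicit noise table (same purpose).
#' @return An object of class `basis_network`: list with fields `M`
#'   (`n_input x n_hidden`), `centers`, `variances`, `spec`.
#' @export
build_basis <- function(spec = basis_spec(), variances = NULL, noise = NULL) {
  ctr <- basis_centers(spec$n_hidden, spec$width, spec$height)
  if (is.null(variances)) {
    variances <- sample_variances(spec$theta, spec$n_hidden)
  }
  stopifnot(length(variances) == spec$n_hidden, all(variances > 0))
  if (is.null(noise) &&
      spec$noise_strength > 0 && spec$noise_fraction > 0) {
    noise <- sample_noise(spec$noise_strength, spec$noise_fraction,
                          spec$n_input, spec$n_hidden)
  }
  # positions in linear-index order: p = height*(x-1) + y
  xs <- rep(seq_len(spec$width), each = spec$height)
  ys <- rep(seq_len(spec$height), times = spec$width)
  d2 <- outer(xs, ctr$a, "-")^2 + outer(ys, ctr$b, "-")^2
  M <- exp(-sweep(d2, 2, 2 * variances, "/"))
  if (!is.null(noise)) M <- M + noise
  M <- M / spec$n_input
  structure(
    list(M = M, centers = ctr, variances = variances, spec = spec),
    class = "basis_network"
  )
}

#' @export
print.basis_network <- function(x, ...) {
  cat(sprintf(
    "<basis_network %d inputs -> %d hidden units, theta = %g, A = %g, rho = %g>\n",
    x$spec$n_input, x$spec$n_hidden, x$spec$theta,
    x$spec$noise_strength, x$spec$noise_fraction
  ))
  invisible(x)
}

#' Hidden-layer activity at a position
#'
#' With a one-hot input, the hidden activity is simply the row of the
#' connection table at the position's linear index:
#' `h_k(x, y) = M[p(x, y), k]`.
#'
#' @param net a [basis_network()][build_basis].
#' @param x,y position.
#' @return Numeric vector of length `n_hidden`.
#' @export
hidden_activity <- function(net, x, y) {
  if (x < 1 || x > net$spec$width || y < 1 || y > net$spec$height) {
    stop("position (", x, ",", y, ") outside the grid")
  }
  net$M[position_index(x, y, net$spec$height), ]
}

#' Export / import a basis network as plain text
#'
#' Writes the connection table as a dense tab-separated file together with a
#' JSON sidecar (`<path>.json`) holding the spec, centres and variances, so
#' a network can be audited or reloaded exactly.
#'
#' @param net a basis network.
#' @param path path of the tabular file.
#' @export
write_basis <- function(net, path) {
  utils::write.table(net$M, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(
    spec = unclass(net$spec),
    centers = as.list(net$centers),
    variances = net$variances
  )
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for the sidecar")
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for the sidecar")
  }
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- do.call(basis_spec, sidecar$spec[c("theta", "n_hidden", "width",
                                             "height", "noise_strength",
                                             "noise_fraction")])
  M <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(M) <- NULL
  structure(
    list(M = M, centers = tibble::as_tibble(sidecar$centers),
         variances = sidecar$variances, spec = spec),
    class = "basis_network"
  )
}
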