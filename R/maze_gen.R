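#' Generate a random painful maze
#'
#' Builds a 20x20 painful navigation world following the construction rule
#' used for the experiment layouts: a wide passage with the start at one end
#' and a reward-1 goal at the other, and a narrow passage branching off it
#' perpendicular to the wide passage, ending in a reward-2 goal. The safe
#' goal is thus cheap to reach; the high-reward goal requires entering a
#' narrow (wall-hugging, hence risky) corridor. Uses the current R random
#' stream; call `set.seed()` first for reproducibility.
#'
#' @param wide_width width of the wide passage in squares (default 3).
#' @param narrow_width width of the narrow passage in squares (default 1).
#' @param min_length minimum length of each passage in squares (default 8).
#' @param size grid size (default 20; passages must fit the interior ring).
#' @param max_tries bounded rejection sampling before giving up.
#' @return A [gridworld()] with `wall_penalty = -1`.
#' @export
generate_painful_maze <- function(wide_width = 3, narrow_width = 1,
                                  min_length = 8, size = 20,
                                  max_tries = 200) {
  interior <- size - 2L
  if (wide_width + narrow_width + 2 > interior || min_length + 2 > interior) {
    stop("passage widths/lengths do not fit the ", interior, "x", interior,
         " interior")
  }
  for (try in seq_len(max_tries)) {
    w <- try_painful_maze(wide_width, narrow_width, min_length, size)
    if (!is.null(w)) return(w)
  }
  stop("maze generation failed after ", max_tries, " attempts")
}

# One sampling attempt; NULL if the sampled geometry is infeasible.
try_painful_maze <- function(wide_width, narrow_width, min_length, size) {
  lo <- 2L
  hi <- size - 1L
  horizontal <- stats::runif(1) < 0.5

  # wide passage: lanes `perp0..perp0+wide_width-1` across, span `c0..c1` along
  perp0 <- sample(lo:(hi - wide_width + 1L), 1)
  perp1 <- perp0 + wide_width - 1L
  len <- sample(min_length:(hi - lo + 1L), 1)
  c0 <- sample(lo:(hi - len + 1L), 1)
  c1 <- c0 + len - 1L

  # branch: perpendicular, from a along-coordinate strictly inside the span
  if (c1 - 1L < c0 + 1L) return(NULL)
  b_from <- c0 + 1L
  b_to <- c1 - narrow_width
  if (b_to < b_from) return(NULL)
  bpos <- sample(b_from:b_to, 1)
  bdir <- if (stats::runif(1) < 0.5) 1L else -1L
  edge <- if (bdir == 1L) perp1 else perp0
  room <- if (bdir == 1L) hi - edge else edge - lo
  if (room < min_length) return(NULL)
  blen <- sample(min_length:room, 1)

  passable <- matrix(FALSE, size, size)
  mid <- perp0 + (wide_width - 1L) %/% 2L
  if (horizontal) {
    passable[c0:c1, perp0:perp1] <- TRUE
    passable[bpos:(bpos + narrow_width - 1L),
             (edge + bdir):(edge + bdir * blen)] <- TRUE
    start <- c(c0, mid)
    g1 <- c(c1, mid)
    g2 <- c(bpos, edge + bdir * blen)
  } else {
    passable[perp0:perp1, c0:c1] <- TRUE
    passable[(edge + bdir):(edge + bdir * blen),
             bpos:(bpos + narrow_width - 1L)] <- TRUE
    start <- c(mid, c0)
    g1 <- c(mid, c1)
    g2 <- c(edge + bdir * blen, bpos)
  }
  # swap ends of the wide passage at random
  if (stats::runif(1) < 0.5) {
    tmp <- start; start <- g1; g1 <- tmp
  }
  goals <- tibble::tibble(x = c(g1[1], g2[1]), y = c(g1[2], g2[2]),
                          reward = c(1, 2))
  out <- tryCatch(gridworld(passable, start, goals, wall_penalty = -1),
                  error = function(e) NULL)
  out
}

#' Generate a batch of distinct painful mazes
#'
#' Repeatedly calls [generate_painful_maze()], discarding any layout that is
#' identical to an earlier one up to the eight symmetries of the square
#' (rotations and reflections), so the batch contains genuinely different
#' configurations.
#'
#' @param n number of mazes.
#' @inheritParams generate_painful_maze
#' @return A list of `n` [gridworld()] objects.
#' @export
generate_painful_mazes <- function(n, wide_width = 3, narrow_width = 1,
                                   min_length = 8, size = 20,
                                   max_tries = 200) {
  seen <- character(0)
  out <- vector("list", n)
  got <- 0L
  for (try in seq_len(max_tries * n)) {
    w <- generate_painful_maze(wide_width, narrow_width, min_length, size,
                               max_tries)
    key <- maze_canonical_key(w)
    if (key %in% seen) next
    got <- got + 1L
    seen <- c(seen, key)
    out[[got]] <- w
    if (got == n) return(out)
  }
  stop("could not generate ", n, " symmetry-distinct mazes")
}

# Canonical form of a maze under the dihedral group of the square: encode
# passability plus square roles as a character matrix, apply all 8
# transforms, keep the lexicographically smallest serialization.
maze_canonical_key <- function(world) {
  m <- matrix(".", world$width, world$height)
  m[!world$passable] <- "#"
  m[world$start[1], world$start[2]] <- "S"
  for (i in seq_len(nrow(world$goals))) {
    m[world$goals$x[i], world$goals$y[i]] <-
      if (world$goals$reward[i] >= 2) "H" else "G"
  }
  forms <- character(8)
  cur <- m
  for (r in 1:4) {
    cur <- t(cur)[, rev(seq_len(ncol(cur))), drop = FALSE]  # rotate 90
    forms[r] <- paste(cur, collapse = "")
    forms[4 + r] <- paste(cur[rev(seq_len(nrow(cur))), ], collapse = "")
  }
  min(forms)
}
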