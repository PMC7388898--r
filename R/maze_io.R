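#' ASCII maze format
#'
#' Mazes are stored as plain text: exactly `height` lines of `width`
#' characters (the map), followed by a trailing header block of `key=value`
#' lines. The first map line is the northernmost row (`y = height`); the
#' first character of each line is `x = 1`. Glyphs: `#` impassable, `.`
#' passable, `S` the start, `G` and `H` goal squares. The header assigns the
#' reward of each goal class (`G=1`, `H=2` by default) and optionally
#' `wall_penalty` (default -1).
#'
#' @param text a character scalar (the whole file) or vector of lines.
#' @return `read_maze()` returns a [gridworld()]; `format_maze()` returns a
#'   single string; `write_maze()` writes it to `path` and returns the path
#'   invisibly.
#' @name maze_io
NULL

maze_glyphs <- c("#", ".", "S", "G", "H")

#' @rdname maze_io
#' @export
read_maze <- function(text) {
  if (length(text) == 1 && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else if (length(text) == 1) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  lines <- sub("\r$", "", lines)
  # header = trailing key=value lines
  is_kv <- grepl("^[A-Za-z_]+=", lines)
  n_map <- if (any(!is_kv)) max(which(!is_kv)) else 0L
  map_lines <- lines[seq_len(n_map)]
  map_lines <- map_lines[nzchar(map_lines)]
  kv_lines <- lines[-seq_len(n_map)]
  kv_lines <- kv_lines[nzchar(kv_lines)]

  height <- length(map_lines)
  if (height < 3) stop("maze format error: only ", height, " map lines")
  widths <- nchar(map_lines)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop("maze format error: line ", bad, " has ", widths[bad],
         " columns, expected ", widths[1])
  }
  width <- widths[1]

  rewards <- c(G = 1, H = 2)
  wall_penalty <- -1
  for (kv in kv_lines) {
    key <- sub("=.*", "", kv)
    val <- suppressWarnings(as.numeric(sub("^[^=]*=", "", kv)))
    if (is.na(val)) stop("maze format error: bad header line '", kv, "'")
    if (key %in% c("G", "H")) {
      rewards[key] <- val
    } else if (key == "wall_penalty") {
      wall_penalty <- val
    } else {
      stop("maze format error: unknown header key '", key, "'")
    }
  }

  passable <- matrix(FALSE, width, height)
  start <- NULL
  gx <- integer(0); gy <- integer(0); gr <- numeric(0)
  for (row in seq_len(height)) {
    y <- height - row + 1L
    chars <- strsplit(map_lines[row], "")[[1]]
    for (x in seq_len(width)) {
      ch <- chars[x]
      if (!ch %in% maze_glyphs) {
        stop("maze format error: unknown glyph '", ch,
             "' at line ", row, ", column ", x)
      }
      if (ch != "#") passable[x, y] <- TRUE
      if (ch == "S") {
        if (!is.null(start)) stop("maze format error: multiple 'S' squares")
        start <- c(x, y)
      }
      if (ch %in% c("G", "H")) {
        gx <- c(gx, x); gy <- c(gy, y)
        gr <- c(gr, unname(rewards[ch]))
      }
    }
  }
  if (is.null(start)) stop("maze format error: no 'S' start square")
  if (length(gx) == 0) stop("maze format error: no goal squares")
  gridworld(passable, start,
            tibble::tibble(x = gx, y = gy, reward = gr),
            wall_penalty = wall_penalty)
}

#' @rdname maze_io
#' @param world a [gridworld()].
#' @export
format_maze <- function(world) {
  glyph <- matrix(".", world$width, world$height)
  glyph[!world$passable] <- "#"
  glyph[world$start[1], world$start[2]] <- "S"
  # goal classes: lower reward -> G, higher -> H (at most two distinct rewards)
  distinct <- sort(unique(world$goals$reward))
  if (length(distinct) > 2) {
    stop("ASCII format supports at most two distinct goal rewards")
  }
  rewards <- c(G = distinct[1],
               H = if (length(distinct) == 2) distinct[2] else NA_real_)
  for (i in seq_len(nrow(world$goals))) {
    cls <- if (world$goals$reward[i] == rewards["G"]) "G" else "H"
    glyph[world$goals$x[i], world$goals$y[i]] <- cls
  }
  rows <- vapply(seq_len(world$height), function(row) {
    y <- world$height - row + 1L
    paste(glyph[, y], collapse = "")
  }, character(1))
  header <- character(0)
  if (!is.na(rewards["G"])) header <- c(header, paste0("G=", rewards["G"]))
  if (!is.na(rewards["H"])) header <- c(header, paste0("H=", rewards["H"]))
  header <- c(header, paste0("wall_penalty=", world$wall_penalty))
  paste0(paste(c(rows, header), collapse = "\n"), "\n")
}

#' @rdname maze_io
#' @param path file path.
#' @export
write_maze <- function(world, path) {
  cat(format_maze(world), file = path)
  invisible(path)
}

#' Built-in maze fixtures
#'
#' Two hand-coded 20x20 layouts shipped with the package.
#' `"painful"` has a 3-wide corridor with the start at the west end and a
#' reward-1 goal at the east end, plus a 1-wide narrow passage branching
#' south to a reward-2 goal; walls are painful (penalty -1). It realises the
#' "safe low-reward goal vs risky high-reward goal" trade-off. `"painless"`
#' is an open arena with four reward-1 goals near the corners and painless
#' walls, used by the disturbed-agent protocol. Both are documented
#' approximations of the layouts the protocols were designed around.
#'
#' @param name `"painful"` or `"painless"`.
#' @return A [gridworld()].
#' @export
maze_fixture <- function(name = c("painful", "painless")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("maze_", name, ".txt"),
                      package = "ovarlap", mustWork = TRUE)
  read_maze(path)
}
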