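#' Arena configuration
#'
#' Describes the vertical display wall on which the six stimulus discs are
#' presented: a 3x2 grid of discs (three columns spaced 14 cm apart, two rows
#' spaced 9.3 cm apart), three of which carry the rewarded stimulus class in
#' any one bout. `max_choices_per_bout` is a safety bound on bout length for
#' non-terminating agents.
#'
#' @param n_discs Total number of discs (default 6).
#' @param n_rewarded Number of discs carrying the rewarded size class
#'   (default 3). Must satisfy `0 < n_rewarded < n_discs`.
#' @param disc_diameter Disc diameter in cm (default 7).
#' @param grid_columns,grid_rows Grid dimensions; their product must equal
#'   `n_discs`.
#' @param horizontal_spacing,vertical_spacing Centre-to-centre spacing of the
#'   grid in cm (defaults 14 and 9.3).
#' @param max_choices_per_bout Hard cap on landings within one bout
#'   (default 20).
#' @return An object of class `arena_config`.
#' @export
arena_config <- function(n_discs = 6L, n_rewarded = 3L, disc_diameter = 7,
                         grid_columns = 3L, grid_rows = 2L,
                         horizontal_spacing = 14, vertical_spacing = 9.3,
                         max_choices_per_bout = 20L) {
  n_discs <- as.integer(n_discs)
  n_rewarded <- as.integer(n_rewarded)
  grid_columns <- as.integer(grid_columns)
  grid_rows <- as.integer(grid_rows)
  max_choices_per_bout <- as.integer(max_choices_per_bout)
  if (n_rewarded < 1L || n_rewarded >= n_discs)
    stop("`n_rewarded` must satisfy 0 < n_rewarded < n_discs", call. = FALSE)
  if (grid_columns * grid_rows != n_discs)
    stop("`n_discs` must equal grid_columns * grid_rows", call. = FALSE)
  if (horizontal_spacing <= 0 || vertical_spacing <= 0 || disc_diameter <= 0)
    stop("spacings and disc diameter must be positive", call. = FALSE)
  if (max_choices_per_bout < n_rewarded)
    stop("`max_choices_per_bout` must be at least `n_rewarded`", call. = FALSE)
  structure(
    list(n_discs = n_discs, n_rewarded = n_rewarded,
         disc_diameter = disc_diameter,
         grid_columns = grid_columns, grid_rows = grid_rows,
         horizontal_spacing = horizontal_spacing,
         vertical_spacing = vertical_spacing,
         max_choices_per_bout = max_choices_per_bout),
    class = "arena_config")
}

#' Disc centre coordinates
#'
#' Grid convention: x increases rightward, y increases upward, origin at the
#' bottom-left disc; discs are numbered row-major from the bottom-left
#' (disc 1 = bottom-left, disc `grid_columns` = bottom-right, last disc =
#' top-right). Units are cm.
#'
#' @param arena An [arena_config()].
#' @return A data.frame with columns `disc_id`, `x`, `y`.
#' @export
disc_positions <- function(arena = arena_config()) {
  stopifnot(inherits(arena, "arena_config"))
  col <- rep(seq_len(arena$grid_columns), times = arena$grid_rows)
  row <- rep(seq_len(arena$grid_rows), each = arena$grid_columns)
  data.frame(
    disc_id = seq_len(arena$n_discs),
    x = (col - 1L) * arena$horizontal_spacing,
    y = (row - 1L) * arena$vertical_spacing)
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("Arena: %d discs (%d rewarded), %dx%d grid, spacing %g x %g cm\n",
              x$n_discs, x$n_rewarded, x$grid_columns, x$grid_rows,
              x$horizontal_spacing, x$vertical_spacing))
  invisible(x)
}
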