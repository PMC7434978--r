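# Stimulus geometry: the training/test catalogue and planar areas of the
# four shape families. Dimensions are in cm, areas in cm^2.

.shape_kinds <- c("circle", "rectangle", "cross", "star")
.size_classes <- c("small", "medium", "large")
.training_colors <- c("black", "green", "purple")
.all_colors <- c(.training_colors, "yellow")

#' Catalogue of stimulus dimensions
#'
#' The printed dimensions of every stimulus used in training and in the
#' unrewarded tests. Circles are given by their diameter; rectangles by
#' width x height; crosses by the common bar width and bar length of their
#' two orthogonal bars; five-pointed stars by the side length of one point.
#'
#' @return A data.frame with columns `shape_kind`, `size_class`, `dim1`,
#'   `dim2` (NA where a single length parameterises the shape) and `phase_use`
#'   (`"training"` or `"test"`).
#' @export
stimulus_catalogue <- function() {
  data.frame(
    shape_kind = c(rep("circle", 3), rep("rectangle", 3), rep("cross", 3),
                   rep("star", 2)),
    size_class = c(rep(c("small", "medium", "large"), 3), c("small", "large")),
    dim1 = c(1.07, 1.97, 2.87,        # circle diameter
             0.93, 1.79, 2.30,        # rectangle width
             0.46, 0.60, 0.96,        # cross bar width
             0.50, 1.23),             # star point side
    dim2 = c(NA, NA, NA,
             1.18, 2.92, 3.94,        # rectangle height
             1.30, 2.15, 2.87,        # cross bar length
             NA, NA),
    phase_use = c(rep("training", 9), rep("test", 2)),
    stringsAsFactors = FALSE)
}

#' Construct a stimulus specification
#'
#' Looks dimensions up in [stimulus_catalogue()] unless explicitly supplied.
#'
#' @param shape_kind One of `"circle"`, `"rectangle"`, `"cross"`, `"star"`.
#' @param size_class One of `"small"`, `"medium"`, `"large"`.
#' @param color One of `"black"`, `"green"`, `"purple"`, `"yellow"`.
#' @param dimensions Optional numeric vector of shape-specific lengths in cm
#'   (circle: diameter; rectangle: width, height; cross: bar_width,
#'   bar_length; star: point side length).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(shape_kind, size_class, color = "black",
                          dimensions = NULL) {
  shape_kind <- match.arg(shape_kind, .shape_kinds)
  size_class <- match.arg(size_class, .size_classes)
  color <- match.arg(color, .all_colors)
  if (is.null(dimensions)) {
    cat <- stimulus_catalogue()
    row <- cat[cat$shape_kind == shape_kind & cat$size_class == size_class, ]
    if (nrow(row) == 0L)
      stop(sprintf("no catalogue entry for %s %s", size_class, shape_kind),
           call. = FALSE)
    dimensions <- c(row$dim1, row$dim2)
    dimensions <- dimensions[!is.na(dimensions)]
  }
  dimensions <- as.numeric(dimensions)
  n_expected <- switch(shape_kind, circle = 1L, rectangle = 2L,
                       cross = 2L, star = 1L)
  if (length(dimensions) != n_expected)
    stop(sprintf("%s requires %d dimension(s), got %d", shape_kind,
                 n_expected, length(dimensions)), call. = FALSE)
  if (any(!is.finite(dimensions)) || any(dimensions <= 0))
    stop("all stimulus dimensions must be positive and finite", call. = FALSE)
  structure(list(shape_kind = shape_kind, size_class = size_class,
                 color = color, dimensions = dimensions),
            class = "stimulus_spec")
}

#' Planar area of a stimulus
#'
#' Closed forms: circle `pi (d/2)^2`; rectangle `w h`; cross (two orthogonal
#' bars of equal width `w` and length `L` crossing at their centres)
#' `2 L w - w^2` (the overlap square counted once); five-pointed star: a
#' regular pentagram outline built from the point side length `s` — an inner
#' regular pentagon of side `b = 2 s sin(18°)` plus five isosceles point
#' triangles with apex angle 36° and equal sides `s`, giving
#' `5 s^2 sin(36°)/2 + 5 b^2 / (4 tan(36°))`. This construction (one reading
#' of "length of the side of point") is the package's documented convention.
#'
#' @param spec A [stimulus_spec()].
#' @return Area in cm^2.
#' @examples
#' shape_area(stimulus_spec("rectangle", "medium"))  # 1.79 x 2.92 = 5.2268
#' @export
shape_area <- function(spec) {
  if (!inherits(spec, "stimulus_spec"))
    stop("`spec` must be a stimulus_spec", call. = FALSE)
  d <- spec$dimensions
  switch(spec$shape_kind,
    circle = pi * (d[1] / 2)^2,
    rectangle = d[1] * d[2],
    cross = 2 * d[2] * d[1] - d[1]^2,
    star = {
      s <- d[1]
      b <- 2 * s * sin(pi / 10)                  # inner pentagon side
      5 * s^2 * sin(pi / 5) / 2 + 5 * b^2 / (4 * tan(pi / 5))
    },
    stop(sprintf("unknown shape_kind '%s'", spec$shape_kind), call. = FALSE))
}

#' Assign a 3+3 stimulus set to the arena discs
#'
#' Builds one bout's display: `n_rewarded` discs carry one size class of the
#' pair and the remaining discs the other, with positions drawn uniformly at
#' random. Which size class is rewarded follows the contingency: under
#' `"larger"` the relatively larger class of the pair is rewarded, under
#' `"smaller"` the relatively smaller one. Uses R's global RNG (seed with
#' `set.seed()`).
#'
#' @param shape_kind,color Stimulus family and colour for the bout (one of
#'   each per bout).
#' @param size_pair Character vector of two distinct size classes, e.g.
#'   `c("small", "large")`.
#' @param contingency `"larger"` or `"smaller"`: which relative size class is
#'   rewarded.
#' @param arena An [arena_config()].
#' @return A data.frame with one row per disc: `disc_id`, `x`, `y`,
#'   `size_class` (catalogue class), `relative_class` (`"smaller"` /
#'   `"larger"` within the pair), `rewarded` (logical), plus `shape_kind` and
#'   `color`.
#' @export
build_stimulus_set <- function(shape_kind, color, size_pair,
                               contingency = c("larger", "smaller"),
                               arena = arena_config()) {
  contingency <- match.arg(contingency)
  shape_kind <- match.arg(shape_kind, .shape_kinds)
  color <- match.arg(color, .all_colors)
  size_pair <- as.character(size_pair)
  if (length(size_pair) != 2L || size_pair[1] == size_pair[2])
    stop("`size_pair` must be two distinct size classes", call. = FALSE)
  if (!all(size_pair %in% .size_classes))
    stop("`size_pair` entries must be in the size-class catalogue",
         call. = FALSE)
  cat <- stimulus_catalogue()
  for (sz in size_pair)
    if (!any(cat$shape_kind == shape_kind & cat$size_class == sz))
      stop(sprintf("no catalogue entry for %s %s", sz, shape_kind),
           call. = FALSE)

  ord <- order(match(size_pair, .size_classes))
  smaller_class <- size_pair[ord][1]
  larger_class <- size_pair[ord][2]
  rewarded_class <- if (contingency == "larger") larger_class else smaller_class

  pos <- disc_positions(arena)
  n <- arena$n_discs
  k <- arena$n_rewarded
  # discs carrying the rewarded class, placed uniformly at random
  rewarded_discs <- sample.int(n, k)
  size_class <- rep(setdiff(size_pair, rewarded_class), n)
  size_class[rewarded_discs] <- rewarded_class
  out <- pos
  out$size_class <- size_class
  out$relative_class <- ifelse(size_class == larger_class, "larger", "smaller")
  out$rewarded <- seq_len(n) %in% rewarded_discs
  out$shape_kind <- shape_kind
  out$color <- color
  out
}
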