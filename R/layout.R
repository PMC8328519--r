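#' Screen definition
#'
#' @param width,height Screen dimensions in pixels (> 0). The default
#'   1366 x 768 laptop screen comfortably contains the 573-px outlier
#'   offset used by the eight-item design (half-diagonal ~ 783 px).
#' @return A `screen` object (list with `width`, `height`).
#' @export
screen_def <- function(width = 1366, height = 768) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0 ||
      !is.finite(width) || !is.finite(height)) {
    stop("screen dimensions must be positive finite numbers", call. = FALSE)
  }
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "screen")
}

#' @rdname screen_def
#' @param screen A `screen` object.
#' @export
screen_center <- function(screen) c(screen$width / 2, screen$height / 2)

#' Is each point within the screen bounds?
#'
#' @param points Point or n x 2 matrix.
#' @param screen A `screen` object.
#' @return Logical vector.
#' @export
in_bounds <- function(points, screen) {
  m <- as_point_matrix(points, "points")
  m[, 1] >= 0 & m[, 1] <= screen$width & m[, 2] >= 0 & m[, 2] <= screen$height
}

#' Encoded landmark layout
#'
#' The set of encoded landmark locations on a screen, optionally with one
#' item designated as the spatial outlier. The layout is the source of all
#' "true" centres and chance baselines; coordinates use the standard screen
#' convention (origin top-left, y downward), which no published quantity
#' depends on since all outputs are distances.
#'
#' @param items Data frame with columns `label` (unique character), `x`, `y`
#'   (finite pixels, in bounds).
#' @param screen A `screen` object.
#' @param outlier_label Optional label of the designated outlier item.
#' @return A `spatial_layout` object.
#' @export
spatial_layout <- function(items, screen = screen_def(), outlier_label = NULL) {
  items <- as.data.frame(items)
  if (!all(c("label", "x", "y") %in% names(items))) {
    stop("`items` needs columns label, x, y", call. = FALSE)
  }
  items$label <- as.character(items$label)
  items$x <- as.numeric(items$x)
  items$y <- as.numeric(items$y)
  if (anyDuplicated(items$label)) stop("item labels must be unique", call. = FALSE)
  check_finite(as.matrix(items[, c("x", "y")]), "items")
  if (!all(in_bounds(as.matrix(items[, c("x", "y")]), screen))) {
    stop("all encoded locations must lie within the screen", call. = FALSE)
  }
  if (!is.null(outlier_label)) {
    outlier_label <- as.character(outlier_label)
    if (!outlier_label %in% items$label) {
      stop("`outlier_label` is not one of the item labels", call. = FALSE)
    }
  }
  structure(
    list(screen = screen, items = items[, c("label", "x", "y")],
         outlier_label = outlier_label),
    class = "spatial_layout"
  )
}

#' @export
print.spatial_layout <- function(x, ...) {
  cat(sprintf("<spatial_layout> %d items on a %g x %g screen%s\n",
              nrow(x$items), x$screen$width, x$screen$height,
              if (is.null(x$outlier_label)) ""
              else sprintf(", outlier = '%s'", x$outlier_label)))
  print(x$items, row.names = FALSE)
  invisible(x)
}

#' Layout accessors
#'
#' `layout_points()` returns the encoded coordinates as a labelled matrix;
#' `layout_labels()` the item labels; `n_items()` the item count;
#' `encoded_centroid()` the true (global) centre; `local_center()` the
#' centre excluding the outlier; `outlier_point()` the outlier's encoded
#' location.
#'
#' @param layout A `spatial_layout`.
#' @return See each description.
#' @export
layout_points <- function(layout) {
  m <- as.matrix(layout$items[, c("x", "y")])
  rownames(m) <- layout$items$label
  m
}

#' @rdname layout_points
#' @export
layout_labels <- function(layout) layout$items$label

#' @rdname layout_points
#' @export
n_items <- function(layout) nrow(layout$items)

#' @rdname layout_points
#' @export
encoded_centroid <- function(layout) centroid(layout_points(layout))

outlier_index <- function(layout) {
  if (is.null(layout$outlier_label)) {
    stop("layout has no designated outlier item", call. = FALSE)
  }
  match(layout$outlier_label, layout$items$label)
}

#' @rdname layout_points
#' @export
local_center <- function(layout) {
  local_centroid(layout_points(layout), outlier_index(layout))
}

#' @rdname layout_points
#' @export
outlier_point <- function(layout) {
  unname(layout_points(layout)[outlier_index(layout), ])
}

#' Read / write a layout as JSON
#'
#' Serialisation format:
#' `{"screen": {"width", "height"}, "items": [{"label", "x", "y"}, ...],
#'   "outlier_label": <optional>}`.
#'
#' @param layout A `spatial_layout`.
#' @param path File path.
#' @return `write_layout_json()` returns `path` invisibly;
#'   `read_layout_json()` returns a `spatial_layout`.
#' @export
write_layout_json <- function(layout, path) {
  obj <- list(
    screen = list(width = layout$screen$width, height = layout$screen$height),
    items = layout$items
  )
  if (!is.null(layout$outlier_label)) obj$outlier_label <- layout$outlier_label
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spatial_layout(
    items = obj$items,
    screen = screen_def(obj$screen$width, obj$screen$height),
    outlier_label = obj$outlier_label
  )
}
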