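#' Construct a matrix of bounding boxes
#'
#' Boxes are axis-aligned rectangles in continuous pixel coordinates with the
#' origin at the top-left corner, x increasing rightward and y downward. The
#' canonical representation throughout the package is a numeric matrix with
#' one row per box and columns \code{xmin, ymin, xmax, ymax}.
#'
#' @param xmin,ymin,xmax,ymax numeric vectors of equal length (recycled by
#'   the usual rules). Degenerate boxes (zero width or height) are rejected:
#'   the correspondence relation and IoU are ill-defined for them.
#' @return a numeric matrix with columns \code{xmin, ymin, xmax, ymax}.
#' @export
#' @examples
#' boxes(0, 0, 10, 10)
#' boxes(c(0, 5), c(0, 5), c(10, 15), c(10, 15))
boxes <- function(xmin = numeric(), ymin = numeric(),
                  xmax = numeric(), ymax = numeric()) {
  m <- cbind(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
             xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  if (nrow(m) == 0) {
    m <- matrix(numeric(), ncol = 4,
                dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax")))
  }
  validate_boxes(m)
  m
}

#' An empty box collection
#' @return a 0-row box matrix.
#' @export
empty_boxes <- function() boxes()

#' Validate a box matrix
#'
#' @param b numeric matrix with columns xmin, ymin, xmax, ymax.
#' @param where optional context string used in error messages
#'   (e.g., an image id).
#' @return the validated matrix, invisibly.
#' @export
validate_boxes <- function(b, where = NULL) {
  ctx <- if (is.null(where)) "" else sprintf(" [%s]", where)
  if (!is.matrix(b) || ncol(b) != 4 || !is.numeric(b))
    stop("boxes must be a numeric matrix with 4 columns", ctx, call. = FALSE)
  if (nrow(b) > 0) {
    if (anyNA(b))
      stop("box coordinates contain NA", ctx, call. = FALSE)
    bad <- b[, 3] <= b[, 1] | b[, 4] <= b[, 2]
    if (any(bad))
      stop(sprintf("degenerate box (xmax <= xmin or ymax <= ymin) at row %d%s",
                   which(bad)[1], ctx), call. = FALSE)
  }
  invisible(b)
}

#' Box areas
#' @param b box matrix.
#' @return numeric vector of areas, one per row.
#' @export
box_area <- function(b) {
  if (nrow(b) == 0) return(numeric())
  (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
}

#' Box centroids
#' @param b box matrix.
#' @return a 2-column matrix (x, y) of centroids.
#' @export
box_centroid <- function(b) {
  cbind(x = (b[, 1] + b[, 3]) / 2, y = (b[, 2] + b[, 4]) / 2)
}

# Intersection area of one box against each row of a box matrix.
# Intervals are treated as closed; a zero-width overlap contributes 0 area.
intersection_area <- function(b1, b2) {
  if (nrow(b2) == 0) return(numeric())
  w <- pmin(b1[3], b2[, 3]) - pmax(b1[1], b2[, 1])
  h <- pmin(b1[4], b2[, 4]) - pmax(b1[2], b2[, 2])
  pmax(w, 0) * pmax(h, 0)
}

#' Intersection over union of two boxes
#'
#' @param b,b2 single boxes: numeric vectors (xmin, ymin, xmax, ymax) or
#'   1-row box matrices.
#' @return the IoU ratio in \[0, 1\]; 0 for disjoint boxes.
#' @export
#' @examples
#' iou(c(0, 0, 10, 10), c(1, 1, 11, 11))  # 81 / 119
iou <- function(b, b2) {
  b <- as_box_vector(b); b2 <- as_box_vector(b2)
  inter <- intersection_area(b, matrix(b2, nrow = 1))
  a1 <- (b[3] - b[1]) * (b[4] - b[2])
  a2 <- (b2[3] - b2[1]) * (b2[4] - b2[2])
  inter / (a1 + a2 - inter)
}

#' Centroid-containment correspondence between two boxes
#'
#' Two boxes are deemed to mark the same lesion when the centroid of one
#' lies inside the other, or vice versa. Containment is inclusive of the
#' boundary. The relation is reflexive and symmetric but not transitive.
#'
#' @param b,b2 single boxes (vectors or 1-row matrices).
#' @return logical.
#' @export
#' @examples
#' boxes_correspond(c(0, 0, 10, 10), c(4, 4, 20, 20))  # TRUE
boxes_correspond <- function(b, b2) {
  b <- as_box_vector(b); b2 <- as_box_vector(b2)
  c1 <- c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)
  c2 <- c((b2[1] + b2[3]) / 2, (b2[2] + b2[4]) / 2)
  point_in_box(c1, b2) || point_in_box(c2, b)
}

point_in_box <- function(p, b) {
  p[1] >= b[1] && p[1] <= b[3] && p[2] >= b[2] && p[2] <= b[4]
}

as_box_vector <- function(b) {
  if (is.matrix(b)) {
    stopifnot(nrow(b) == 1)
    b <- b[1, ]
  }
  stopifnot(length(b) == 4)
  unname(as.numeric(b))
}

# Which rows of box matrix `cand` correspond (centroid rule) to box b?
# Vectorized form of boxes_correspond used by the matchers.
corresponding_rows <- function(b, cand) {
  if (nrow(cand) == 0) return(logical())
  cb <- c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)
  cc <- box_centroid(cand)
  in_cand <- cb[1] >= cand[, 1] & cb[1] <= cand[, 3] &
             cb[2] >= cand[, 2] & cb[2] <= cand[, 4]
  in_b <- cc[, 1] >= b[1] & cc[, 1] <= b[3] &
          cc[, 2] >= b[2] & cc[, 2] <= b[4]
  in_cand | in_b
}
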