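#' Per-annotator annotation set
#'
#' Bundles one annotator's boxes for a collection of images. An image with no
#' boxes is an explicit negative finding: the annotator examined it and found
#' nothing, so missing entries are treated as empty collections wherever the
#' set is evaluated.
#'
#' @param annotator_id opaque string identifying the annotator.
#' @param boxes_by_image named list mapping image id to a box matrix
#'   (see [boxes()]); entries may be 0-row.
#' @return an object of class \code{annotation_set}.
#' @export
annotation_set <- function(annotator_id, boxes_by_image = list()) {
  stopifnot(is.character(annotator_id), length(annotator_id) == 1,
            nzchar(annotator_id))
  if (length(boxes_by_image) > 0 && is.null(names(boxes_by_image)))
    stop("boxes_by_image must be a named list (names are image ids)",
         call. = FALSE)
  boxes_by_image <- lapply(boxes_by_image, function(b) {
    if (is.null(b)) return(empty_boxes())
    if (!is.matrix(b)) b <- matrix(as.numeric(b), ncol = 4, byrow = TRUE)
    colnames(b) <- c("xmin", "ymin", "xmax", "ymax")
    validate_boxes(b)
    b
  })
  structure(list(annotator_id = annotator_id,
                 boxes_by_image = boxes_by_image),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  n <- sum(vapply(x$boxes_by_image, nrow, integer(1)))
  cat(sprintf("<annotation_set> annotator '%s': %d boxes on %d images\n",
              x$annotator_id, n, length(x$boxes_by_image)))
  invisible(x)
}

# Boxes of an annotation set on one image; absent image => empty collection.
set_boxes <- function(set, image_id) {
  b <- set$boxes_by_image[[image_id]]
  if (is.null(b)) empty_boxes() else b
}

n_boxes <- function(set) {
  sum(vapply(set$boxes_by_image, nrow, integer(1)))
}

#' Multi-annotator annotation dataset
#'
#' @param frames data.frame with columns \code{image_id}, \code{width},
#'   \code{height} (pixels). Every box of every annotator must lie within
#'   its image frame.
#' @param sets list of [annotation_set()] objects with distinct annotator ids.
#' @return an object of class \code{annotation_dataset}.
#' @export
annotation_dataset <- function(frames, sets) {
  stopifnot(is.data.frame(frames),
            all(c("image_id", "width", "height") %in% names(frames)))
  frames$image_id <- as.character(frames$image_id)
  if (anyDuplicated(frames$image_id))
    stop("duplicate image_id in frames", call. = FALSE)
  if (any(frames$width <= 0) || any(frames$height <= 0))
    stop("frame dimensions must be positive", call. = FALSE)
  if (inherits(sets, "annotation_set")) sets <- list(sets)
  ids <- vapply(sets, function(s) s$annotator_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate annotator ids: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  names(sets) <- ids
  for (s in sets) {
    unknown <- setdiff(names(s$boxes_by_image), frames$image_id)
    if (length(unknown) > 0)
      stop(sprintf("annotator '%s' references unknown image '%s'",
                   s$annotator_id, unknown[1]), call. = FALSE)
    for (img in names(s$boxes_by_image)) {
      b <- s$boxes_by_image[[img]]
      if (nrow(b) == 0) next
      fr <- frames[frames$image_id == img, ]
      if (any(b[, 1] < 0) || any(b[, 2] < 0) ||
          any(b[, 3] > fr$width) || any(b[, 4] > fr$height))
        stop(sprintf("annotator '%s': box outside frame on image '%s'",
                     s$annotator_id, img), call. = FALSE)
    }
  }
  structure(list(frames = frames, annotations = sets),
            class = "annotation_dataset")
}

#' @export
print.annotation_dataset <- function(x, ...) {
  cat(sprintf("<annotation_dataset> %d images, %d annotators (%s)\n",
              nrow(x$frames), length(x$annotations),
              paste(names(x$annotations), collapse = ", ")))
  invisible(x)
}

#' List the annotator ids of a dataset
#' @param dataset an [annotation_dataset()].
#' @return character vector.
#' @export
annotators <- function(dataset) names(dataset$annotations)

get_set <- function(dataset, annotator_id) {
  s <- dataset$annotations[[annotator_id]]
  if (is.null(s))
    stop(sprintf("unknown annotator '%s'", annotator_id), call. = FALSE)
  s
}

#' Descriptive statistics of an annotation set
#'
#' Reports the total box count and the mean and standard deviation of the
#' rectangle side lengths. Widths and heights are pooled into a single sample
#' (2 values per box), which yields one mean and one sd per annotator.
#'
#' @param set an [annotation_set()].
#' @param sd_type \code{"population"} (divide by n, the default) or
#'   \code{"sample"} (divide by n-1).
#' @return a one-row data.frame with columns \code{annotator_id},
#'   \code{n_boxes}, \code{mean_side}, \code{std_side}; mean and sd are
#'   \code{NA} for an empty set, never 0.
#' @export
annotation_stats <- function(set, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  sides <- unlist(lapply(set$boxes_by_image, function(b) {
    if (nrow(b) == 0) numeric() else c(b[, 3] - b[, 1], b[, 4] - b[, 2])
  }), use.names = FALSE)
  n <- length(sides) / 2
  if (n == 0) {
    m <- s <- NA_real_
  } else {
    m <- mean(sides)
    s <- sqrt(sum((sides - m)^2) /
              (if (sd_type == "population") length(sides)
               else max(length(sides) - 1, 1)))
  }
  out <- data.frame(annotator_id = set$annotator_id, n_boxes = as.integer(n),
                    mean_side = m, std_side = s, stringsAsFactors = FALSE)
  attr(out, "side_pooling") <- "widths and heights pooled"
  attr(out, "sd_type") <- sd_type
  out
}
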