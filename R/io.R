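#' Read annotations from a CVAT "for images 1.1" XML file
#'
#' Parses \code{<image id name width height>} elements with \code{<box>}
#' children carrying \code{xtl, ytl, xbr, ybr} attributes. Coordinates are
#' passed through unmodified. One annotation set is produced per file.
#'
#' @param path path to the XML file.
#' @param annotator_id id for the resulting set; defaults to the task name
#'   stored in the file if present, else the file name without extension.
#' @return list with \code{annotations} (an [annotation_set()]) and
#'   \code{frames} (data.frame image_id/width/height).
#' @export
read_cvat_xml <- function(path, annotator_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("malformed CVAT XML in '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  if (is.null(annotator_id)) {
    task <- xml2::xml_find_first(doc, ".//meta/task/name")
    annotator_id <- if (!inherits(task, "xml_missing") &&
                        nzchar(xml2::xml_text(task)))
      xml2::xml_text(task)
    else sub("\\.[^.]*$", "", basename(path))
  }
  images <- xml2::xml_find_all(doc, ".//image")
  if (length(images) == 0)
    stop(sprintf("no <image> elements found in '%s'", path), call. = FALSE)
  frames <- data.frame(image_id = character(), width = numeric(),
                       height = numeric(), stringsAsFactors = FALSE)
  by_image <- list()
  for (img in images) {
    id <- xml2::xml_attr(img, "name")
    if (is.na(id)) id <- xml2::xml_attr(img, "id")
    w <- as.numeric(xml2::xml_attr(img, "width"))
    h <- as.numeric(xml2::xml_attr(img, "height"))
    if (is.na(w) || is.na(h))
      stop(sprintf("<image> element '%s' lacks width/height", id),
           call. = FALSE)
    frames <- rbind(frames, data.frame(image_id = id, width = w, height = h,
                                       stringsAsFactors = FALSE))
    bx <- xml2::xml_find_all(img, ".//box")
    if (length(bx) == 0) {
      by_image[[id]] <- empty_boxes()
    } else {
      xtl <- as.numeric(xml2::xml_attr(bx, "xtl"))
      ytl <- as.numeric(xml2::xml_attr(bx, "ytl"))
      xbr <- as.numeric(xml2::xml_attr(bx, "xbr"))
      ybr <- as.numeric(xml2::xml_attr(bx, "ybr"))
      if (anyNA(c(xtl, ytl, xbr, ybr)))
        stop(sprintf("<box> with missing coordinate attribute on image '%s'", id),
             call. = FALSE)
      if (any(xbr <= xtl) || any(ybr <= ytl))
        stop(sprintf("degenerate box (xbr <= xtl or ybr <= ytl) on image '%s'", id),
             call. = FALSE)
      by_image[[id]] <- boxes(xtl, ytl, xbr, ybr)
    }
  }
  list(annotations = annotation_set(annotator_id, by_image), frames = frames)
}

#' Write an annotation set to CVAT "for images 1.1" XML
#'
#' @param set an [annotation_set()].
#' @param frames data.frame with image_id/width/height covering every image
#'   of the set.
#' @param path output path.
#' @param label box label written to every box (single-class annotations).
#' @return \code{path}, invisibly.
#' @export
write_cvat_xml <- function(set, frames, path, label = "lesion") {
  doc <- xml2::xml_new_root("annotations")
  xml2::xml_add_child(doc, "version", "1.1")
  meta <- xml2::xml_add_child(doc, "meta")
  task <- xml2::xml_add_child(meta, "task")
  xml2::xml_add_child(task, "name", set$annotator_id)
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  for (k in seq_len(nrow(frames))) {
    img <- xml2::xml_add_child(doc, "image",
                               id = as.character(k - 1),
                               name = frames$image_id[k],
                               width = fmt(frames$width[k]),
                               height = fmt(frames$height[k]))
    b <- set_boxes(set, frames$image_id[k])
    for (r in seq_len(nrow(b))) {
      xml2::xml_add_child(img, "box", label = label, occluded = "0",
                          xtl = fmt(b[r, 1]), ytl = fmt(b[r, 2]),
                          xbr = fmt(b[r, 3]), ybr = fmt(b[r, 4]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read annotations from a COCO detection JSON file
#'
#' Boxes are stored as \code{[x, y, w, h]} and converted to corner form
#' \code{(x, y, x + w, y + h)}. Annotator identity is not part of the COCO
#' dialect, so a grouping rule is required: by default each category is one
#' annotator; alternatively a custom per-annotation field can carry the
#' annotator id, or the whole file can be a single annotator.
#'
#' @param path path to the JSON file.
#' @param annotator_by \code{"category"} (default), \code{"attribute"}
#'   (read ids from \code{attribute_field}), or \code{"file"} (one set,
#'   id = \code{annotator_id}).
#' @param attribute_field field name holding the annotator id when
#'   \code{annotator_by = "attribute"}.
#' @param annotator_id set id when \code{annotator_by = "file"}.
#' @return list with \code{annotations} (list of [annotation_set()]) and
#'   \code{frames}.
#' @export
read_coco_json <- function(path, annotator_by = c("category", "attribute", "file"),
                           attribute_field = "annotator",
                           annotator_id = NULL) {
  annotator_by <- match.arg(annotator_by)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$images))
    stop(sprintf("'%s' has no images[] section", path), call. = FALSE)
  frames <- do.call(rbind, lapply(j$images, function(im)
    data.frame(image_id = as.character(if (!is.null(im$file_name)) im$file_name else im$id),
               width = as.numeric(im$width), height = as.numeric(im$height),
               coco_id = as.character(im$id), stringsAsFactors = FALSE)))
  cat_names <- list()
  for (ct in j$categories)
    cat_names[[as.character(ct$id)]] <- ct$name
  groups <- list()  # annotator -> image -> list of coord rows
  for (an in j$annotations) {
    im <- match(as.character(an$image_id), frames$coco_id)
    if (is.na(im))
      stop(sprintf("annotation references missing image id '%s'", an$image_id),
           call. = FALSE)
    bb <- as.numeric(unlist(an$bbox))
    if (length(bb) != 4 || bb[3] <= 0 || bb[4] <= 0)
      stop(sprintf("invalid bbox [%s] on image '%s' (w and h must be > 0)",
                   paste(bb, collapse = ", "), frames$image_id[im]),
           call. = FALSE)
    who <- switch(annotator_by,
      category = {
        nm <- cat_names[[as.character(an$category_id)]]
        if (is.null(nm)) as.character(an$category_id) else nm
      },
      attribute = {
        v <- an[[attribute_field]]
        if (is.null(v))
          stop(sprintf("annotation lacks the '%s' field", attribute_field),
               call. = FALSE)
        as.character(v)
      },
      file = if (is.null(annotator_id))
        sub("\\.[^.]*$", "", basename(path)) else annotator_id)
    img <- frames$image_id[im]
    groups[[who]][[img]] <- c(groups[[who]][[img]],
                              list(c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4])))
  }
  frames$coco_id <- NULL
  sets <- lapply(names(groups), function(who) {
    by_image <- lapply(groups[[who]], function(rows)
      do.call(rbind, lapply(rows, function(v) boxes(v[1], v[2], v[3], v[4]))))
    annotation_set(who, by_image)
  })
  if (length(sets) == 0 && annotator_by == "file")
    sets <- list(annotation_set(
      if (is.null(annotator_id)) sub("\\.[^.]*$", "", basename(path))
      else annotator_id, list()))
  list(annotations = sets, frames = frames)
}

#' Write annotation sets to COCO detection JSON
#'
#' Each annotator becomes one COCO category; corner coordinates are
#' converted back to \code{[x, y, w, h]}.
#'
#' @param sets a list of [annotation_set()] (or a single one).
#' @param frames data.frame image_id/width/height.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_coco_json <- function(sets, frames, path) {
  if (inherits(sets, "annotation_set")) sets <- list(sets)
  images <- lapply(seq_len(nrow(frames)), function(k)
    list(id = k, file_name = frames$image_id[k],
         width = frames$width[k], height = frames$height[k]))
  cats <- lapply(seq_along(sets), function(k)
    list(id = k, name = sets[[k]]$annotator_id, supercategory = "annotator"))
  anns <- list(); aid <- 0L
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    for (img in names(s$boxes_by_image)) {
      im <- match(img, frames$image_id)
      b <- s$boxes_by_image[[img]]
      for (r in seq_len(nrow(b))) {
        aid <- aid + 1L
        anns[[aid]] <- list(id = aid, image_id = im, category_id = k,
                            bbox = c(b[r, 1], b[r, 2],
                                     b[r, 3] - b[r, 1], b[r, 4] - b[r, 2]),
                            area = (b[r, 3] - b[r, 1]) * (b[r, 4] - b[r, 2]),
                            iscrowd = 0)
      }
    }
  }
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Write a dataset to the canonical JSON dump
#'
#' The package's internal interchange format: frames plus a nested mapping
#' annotator -> image -> list of \code{[xmin, ymin, xmax, ymax]} rows.
#' Coordinates are serialized at full precision so that a read of a write is
#' bit-exact.
#'
#' @param dataset an [annotation_dataset()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotations_json <- function(dataset, path) {
  annotators <- lapply(dataset$annotations, function(s)
    lapply(s$boxes_by_image, function(b)
      lapply(seq_len(nrow(b)), function(r) as.numeric(b[r, ]))))
  frames <- lapply(seq_len(nrow(dataset$frames)), function(k)
    list(image_id = dataset$frames$image_id[k],
         width = dataset$frames$width[k],
         height = dataset$frames$height[k]))
  jsonlite::write_json(list(frames = frames, annotators = annotators),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a canonical JSON dump back into a dataset
#'
#' @param path path written by [write_annotations_json()].
#' @return an [annotation_dataset()].
#' @export
read_annotations_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  frames <- do.call(rbind, lapply(j$frames, function(f)
    data.frame(image_id = f$image_id, width = as.numeric(f$width),
               height = as.numeric(f$height), stringsAsFactors = FALSE)))
  sets <- lapply(names(j$annotators), function(who) {
    by_image <- lapply(j$annotators[[who]], function(rows) {
      if (length(rows) == 0) return(empty_boxes())
      do.call(rbind, lapply(rows, function(v)
        boxes(v[[1]], v[[2]], v[[3]], v[[4]])))
    })
    annotation_set(who, by_image)
  })
  annotation_dataset(frames, sets)
}

#' Write a consensus standard to JSON
#'
#' Majority and minority (tentative) boxes per image, with the supporter
#' count of each tentative lesion retained for audit.
#'
#' @param std a [build_consensus()] standard.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_consensus_json <- function(std, path) {
  per_image <- lapply(std$per_image, function(p)
    list(majority = lapply(seq_len(nrow(p$S)), function(r) as.numeric(p$S[r, ])),
         minority = lapply(seq_len(nrow(p$S_prime)), function(r)
           as.numeric(p$S_prime[r, ])),
         minority_support = as.integer(p$s_prime_support)))
  jsonlite::write_json(list(panel = std$panel,
                            excluded = std$excluded,
                            images = per_image),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a consensus standard written by [write_consensus_json()]
#' @param path input path.
#' @return a \code{consensus_standard}.
#' @export
read_consensus_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  per_image <- lapply(j$images, function(p) {
    tomat <- function(rows) {
      if (length(rows) == 0) return(empty_boxes())
      do.call(rbind, lapply(rows, function(v)
        boxes(v[[1]], v[[2]], v[[3]], v[[4]])))
    }
    list(S = tomat(p$majority), S_prime = tomat(p$minority),
         s_prime_support = as.integer(unlist(p$minority_support)))
  })
  structure(list(panel = as.character(unlist(j$panel)),
                 excluded = if (is.null(j$excluded)) NULL else j$excluded,
                 per_image = per_image),
            class = "consensus_standard")
}
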