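#' Generate a ground-truth lesion layout
#'
#' Seeded generator of synthetic "true" lesion sites on a set of image
#' frames, used as the unobservable gold standard when validating the
#' agreement machinery. Per image the lesion count is Poisson, box side
#' lengths are log-normal (truncated to a plausible range by rejection), and
#' placement is uniform within the frame. By default same-image lesions are
#' kept mutually non-corresponding under the centroid rule, so that every
#' simulated annotation can be attributed to a unique site.
#'
#' Defaults mirror a bitewing-radiograph setting: 896x1024 px frames, about
#' 3 lesions per image, and side lengths centered near 55 px within
#' \[8, 160\] px.
#'
#' @param n_images number of frames.
#' @param frame_width,frame_height frame size in pixels.
#' @param lesion_rate expected lesions per image (Poisson mean).
#' @param side_meanlog,side_sdlog log-normal parameters of box side lengths.
#' @param side_range inclusive truncation bounds on side lengths (pixels).
#' @param min_separation keep same-image lesions pairwise non-corresponding.
#' @param seed integer seed; the layout is fully reproducible from it.
#' @param max_tries rejection-sampling budget per lesion.
#' @return an object of class \code{ground_truth_layout}: list with
#'   \code{frames}, \code{lesions} (image id -> box matrix), \code{params},
#'   \code{seed}.
#' @export
generate_layout <- function(n_images = 100, frame_width = 896,
                            frame_height = 1024, lesion_rate = 3,
                            side_meanlog = log(55), side_sdlog = 0.35,
                            side_range = c(8, 160), min_separation = TRUE,
                            seed = 1, max_tries = 1000) {
  stopifnot(n_images >= 1, lesion_rate >= 0, all(side_range > 0),
            side_range[1] < side_range[2])
  set.seed(seed)
  ids <- sprintf("img_%04d", seq_len(n_images))
  frames <- data.frame(image_id = ids, width = frame_width,
                       height = frame_height, stringsAsFactors = FALSE)
  lesions <- list()
  for (img in ids) {
    k <- stats::rpois(1, lesion_rate)
    placed <- empty_boxes()
    for (j in seq_len(k)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        w <- rlnorm_trunc(side_meanlog, side_sdlog, side_range)
        h <- rlnorm_trunc(side_meanlog, side_sdlog, side_range)
        if (w >= frame_width || h >= frame_height) next
        x <- stats::runif(1, 0, frame_width - w)
        y <- stats::runif(1, 0, frame_height - h)
        b <- c(x, y, x + w, y + h)
        if (min_separation && nrow(placed) > 0 &&
            any(corresponding_rows(b, placed))) next
        placed <- rbind(placed, matrix(b, nrow = 1))
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf("could not place lesion %d on image %s within %d tries; lower lesion_rate or disable min_separation",
                     j, img, max_tries), call. = FALSE)
    }
    colnames(placed) <- c("xmin", "ymin", "xmax", "ymax")
    lesions[[img]] <- placed
  }
  structure(list(frames = frames, lesions = lesions,
                 params = list(lesion_rate = lesion_rate,
                               side_meanlog = side_meanlog,
                               side_sdlog = side_sdlog,
                               side_range = side_range,
                               min_separation = min_separation),
                 seed = seed),
            class = "ground_truth_layout")
}

rlnorm_trunc <- function(meanlog, sdlog, range, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    v <- stats::rlnorm(1, meanlog, sdlog)
    if (v >= range[1] && v <= range[2]) return(v)
  }
  stop("truncated log-normal rejection budget exhausted", call. = FALSE)
}

#' @export
print.ground_truth_layout <- function(x, ...) {
  n <- sum(vapply(x$lesions, nrow, integer(1)))
  cat(sprintf("<ground_truth_layout> %d images, %d lesions (seed %d)\n",
              nrow(x$frames), n, x$seed))
  invisible(x)
}

#' View a ground-truth layout as an annotation set
#'
#' Useful for scoring simulated annotators directly against the true sites.
#'
#' @param layout a [generate_layout()] result.
#' @param annotator_id id for the resulting set.
#' @return an [annotation_set()].
#' @export
layout_as_set <- function(layout, annotator_id = "GT") {
  annotation_set(annotator_id, layout$lesions)
}

#' Define a simulated annotator profile
#'
#' @param annotator_id opaque id.
#' @param sensitivity probability that a true lesion is annotated.
#' @param fp_per_image expected spurious boxes per image (Poisson mean).
#' @param center_jitter_sd Gaussian jitter of box centers, pixels.
#' @param scale_factor multiplicative box-size bias (2 = draws boxes twice
#'   as large as the true extent).
#' @param size_noise_sd log-scale sd of the multiplicative size noise.
#' @param seed optional per-annotator seed; when absent, [simulate_panel()]
#'   derives one from its master seed and the annotator id.
#' @return an object of class \code{annotator_profile}.
#' @export
annotator_profile <- function(annotator_id, sensitivity = 0.9,
                              fp_per_image = 0.5, center_jitter_sd = 3,
                              scale_factor = 1, size_noise_sd = 0.1,
                              seed = NULL) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_per_image >= 0,
            center_jitter_sd >= 0, scale_factor > 0, size_noise_sd >= 0)
  structure(list(annotator_id = annotator_id, sensitivity = sensitivity,
                 fp_per_image = fp_per_image,
                 center_jitter_sd = center_jitter_sd,
                 scale_factor = scale_factor, size_noise_sd = size_noise_sd,
                 seed = seed),
            class = "annotator_profile")
}

#' Simulate one annotator reading a layout
#'
#' Each true lesion is annotated with probability \code{sensitivity}. An
#' annotated box inherits the lesion's center and size, then the center is
#' jittered (isotropic Gaussian) and both sides are multiplied by
#' \code{scale_factor * exp(N(0, size_noise_sd))} (one multiplier per box,
#' preserving aspect ratio). Boxes are clipped to the frame. Spurious boxes
#' are added with a Poisson(\code{fp_per_image}) count per image, with sizes
#' drawn from the layout's size distribution; by default they are rejected
#' if they correspond to a true lesion, so that the sensitivity and
#' false-positive accounting stay identifiable.
#'
#' @param layout a [generate_layout()] result.
#' @param profile an [annotator_profile()].
#' @param seed seed for this run; defaults to \code{profile$seed}, which
#'   must then be set.
#' @param fp_avoid_lesions reject spurious boxes corresponding to a true
#'   lesion (default TRUE).
#' @param max_tries rejection budget for spurious-box placement.
#' @return an [annotation_set()].
#' @export
simulate_annotator <- function(layout, profile, seed = profile$seed,
                               fp_avoid_lesions = TRUE, max_tries = 1000) {
  stopifnot(inherits(layout, "ground_truth_layout"),
            inherits(profile, "annotator_profile"))
  if (is.null(seed))
    stop("no seed: set profile$seed or pass seed=", call. = FALSE)
  set.seed(seed)
  p <- layout$params
  W <- layout$frames$width[1]; H <- layout$frames$height[1]
  by_image <- list()
  for (img in layout$frames$image_id) {
    truth <- layout$lesions[[img]]
    out <- empty_boxes()
    if (nrow(truth) > 0) {
      keep <- stats::runif(nrow(truth)) < profile$sensitivity
      for (r in which(keep)) {
        b <- truth[r, ]
        cx <- (b[1] + b[3]) / 2 + stats::rnorm(1, 0, profile$center_jitter_sd)
        cy <- (b[2] + b[4]) / 2 + stats::rnorm(1, 0, profile$center_jitter_sd)
        mult <- profile$scale_factor *
          exp(stats::rnorm(1, 0, profile$size_noise_sd))
        w <- (b[3] - b[1]) * mult; h <- (b[4] - b[2]) * mult
        out <- rbind(out, clip_box(cx, cy, w, h, W, H))
      }
    }
    nfp <- stats::rpois(1, profile$fp_per_image)
    for (j in seq_len(nfp)) {
      for (try in seq_len(max_tries)) {
        w <- rlnorm_trunc(p$side_meanlog, p$side_sdlog, p$side_range) *
          profile$scale_factor
        h <- rlnorm_trunc(p$side_meanlog, p$side_sdlog, p$side_range) *
          profile$scale_factor
        w <- min(w, W - 1); h <- min(h, H - 1)
        x <- stats::runif(1, 0, W - w)
        y <- stats::runif(1, 0, H - h)
        b <- c(x, y, x + w, y + h)
        if (fp_avoid_lesions && nrow(truth) > 0 &&
            any(corresponding_rows(b, truth))) next
        out <- rbind(out, matrix(b, nrow = 1))
        break
      }
    }
    colnames(out) <- c("xmin", "ymin", "xmax", "ymax")
    by_image[[img]] <- out
  }
  annotation_set(profile$annotator_id, by_image)
}

# Clip a center/size box into the frame, keeping at least 1 px of extent.
clip_box <- function(cx, cy, w, h, W, H) {
  x1 <- max(0, cx - w / 2); y1 <- max(0, cy - h / 2)
  x2 <- min(W, cx + w / 2); y2 <- min(H, cy + h / 2)
  if (x2 - x1 < 1) { x1 <- max(0, min(x2, W - 1)); x2 <- x1 + 1 }
  if (y2 - y1 < 1) { y1 <- max(0, min(y2, H - 1)); y2 <- y1 + 1 }
  matrix(c(x1, y1, x2, y2), nrow = 1)
}

#' Simulate a full annotator panel
#'
#' Runs [simulate_annotator()] once per profile. Each annotator draws from
#' an independent stream seeded by a stable hash of the master seed and the
#' annotator id, so adding or removing an annotator never perturbs the
#' others' annotations.
#'
#' @param layout a [generate_layout()] result.
#' @param profiles list of [annotator_profile()] with distinct ids.
#' @param seed master seed.
#' @param ... passed to [simulate_annotator()].
#' @return an [annotation_dataset()] over the layout's frames.
#' @export
simulate_panel <- function(layout, profiles, seed = 1, ...) {
  ids <- vapply(profiles, function(p) p$annotator_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate annotator ids in profiles", call. = FALSE)
  sets <- lapply(profiles, function(p) {
    s <- if (!is.null(p$seed)) p$seed else derive_seed(seed, p$annotator_id)
    simulate_annotator(layout, p, seed = s, ...)
  })
  annotation_dataset(layout$frames, sets)
}

# Stable 31-bit seed from a master seed and a string id.
derive_seed <- function(seed, id) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(id)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Annotator profiles emulating a bitewing annotation panel
#'
#' Nine profiles qualitatively mimicking an observed panel of one automatic
#' method, five experts and three novices reading 100 bitewings with about
#' 3 true lesions per image: per-annotator counts spanning roughly 240-430,
#' one over-caller with many extra detections, one expert drawing boxes
#' about twice as large as the rest, and novices with noisier localization
#' and higher false-positive rates.
#'
#' @return named list of [annotator_profile()]; each element carries an
#'   \code{expected_count} attribute with its expected number of boxes on a
#'   100-image, rate-3 layout.
#' @export
bitewing_panel_profiles <- function() {
  spec <- list(
    #            sens   fp   jit scale  noise  expected ~ 300*sens + 100*fp
    M  = list(0.80, 0.05, 2.5, 0.85, 0.10),
    E0 = list(0.85, 0.15, 3.0, 0.95, 0.12),
    E1 = list(0.95, 1.40, 3.5, 1.10, 0.15),  # over-caller
    E2 = list(0.82, 0.18, 3.5, 0.90, 0.15),
    E3 = list(0.90, 0.25, 3.0, 1.25, 0.12),
    E4 = list(0.78, 0.08, 3.5, 1.80, 0.12),  # double-size boxes
    N1 = list(0.90, 1.15, 6.0, 0.95, 0.20),
    N2 = list(0.85, 1.10, 6.0, 1.05, 0.22),
    N3 = list(0.88, 0.78, 5.0, 1.00, 0.20))
  out <- lapply(names(spec), function(id) {
    v <- spec[[id]]
    p <- annotator_profile(id, sensitivity = v[[1]], fp_per_image = v[[2]],
                           center_jitter_sd = v[[3]], scale_factor = v[[4]],
                           size_noise_sd = v[[5]])
    attr(p, "expected_count") <- 300 * v[[1]] + 100 * v[[2]]
    p
  })
  names(out) <- names(spec)
  out
}
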