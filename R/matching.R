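#' Greedy one-to-one matching of two box collections
#'
#' Finds a matching between two collections of boxes on one image such that
#' every matched pair satisfies the centroid correspondence relation
#' ([boxes_correspond()]) and each box is used at most once. The algorithm is
#' greedy: boxes from the union of both collections are processed in order of
#' decreasing area; the current seed is paired with the corresponding box on
#' the other side that maximizes the intersection area, breaking ties first
#' by the larger candidate, then lexicographically by coordinates. A seed
#' with no available partner is set aside but remains eligible as a partner
#' for seeds processed later, so after termination no unmatched box on one
#' side corresponds to an unmatched box on the other.
#'
#' "Largest" is interpreted as largest area; residual ties in the seed order
#' are broken lexicographically by coordinates and then side-a-first, which
#' cannot affect the error count or the pooled IoU.
#'
#' @param a_boxes,b_boxes box matrices (see [boxes()]); may be 0-row.
#' @return an object of class \code{match_result}: a list with
#'   \item{pairs_a, pairs_b}{parallel index vectors into the two inputs;}
#'   \item{iou}{IoU of each matched pair;}
#'   \item{unmatched_a, unmatched_b}{indices of leftover boxes;}
#'   \item{a_boxes, b_boxes}{the inputs, for downstream accounting.}
#' @export
#' @examples
#' m <- greedy_match(boxes(0, 0, 10, 10), boxes(1, 1, 11, 11))
#' count_errors(m)  # 0
greedy_match <- function(a_boxes, b_boxes) {
  validate_boxes(a_boxes); validate_boxes(b_boxes)
  na <- nrow(a_boxes); nb <- nrow(b_boxes)
  side <- c(rep(1L, na), rep(2L, nb))
  idx <- c(seq_len(na), seq_len(nb))
  all_boxes <- rbind(a_boxes, b_boxes)
  matched_a <- rep(FALSE, na); matched_b <- rep(FALSE, nb)
  pairs_a <- integer(); pairs_b <- integer(); pair_iou <- numeric()

  if (na + nb > 0) {
    ord <- order(-box_area(all_boxes), all_boxes[, 1], all_boxes[, 2],
                 all_boxes[, 3], all_boxes[, 4], side)
    for (k in ord) {
      s <- side[k]; i <- idx[k]
      if (if (s == 1L) matched_a[i] else matched_b[i]) next
      seed <- all_boxes[k, ]
      other <- if (s == 1L) b_boxes else a_boxes
      avail <- which(!(if (s == 1L) matched_b else matched_a))
      if (length(avail) == 0) next
      cand <- avail[corresponding_rows(seed, other[avail, , drop = FALSE])]
      if (length(cand) == 0) next
      j <- pick_candidate(seed, other, cand)
      ai <- if (s == 1L) i else j
      bi <- if (s == 1L) j else i
      matched_a[ai] <- TRUE; matched_b[bi] <- TRUE
      pairs_a <- c(pairs_a, ai); pairs_b <- c(pairs_b, bi)
      pair_iou <- c(pair_iou, iou(a_boxes[ai, ], b_boxes[bi, ]))
    }
  }
  structure(list(pairs_a = pairs_a, pairs_b = pairs_b, iou = pair_iou,
                 unmatched_a = which(!matched_a),
                 unmatched_b = which(!matched_b),
                 a_boxes = a_boxes, b_boxes = b_boxes),
            class = "match_result")
}

# Choose among candidate rows `cand` of `other`: max intersection with seed,
# then largest area, then lexicographic (xmin, ymin, xmax, ymax).
pick_candidate <- function(seed, other, cand) {
  inter <- intersection_area(seed, other[cand, , drop = FALSE])
  cand <- cand[inter == max(inter)]
  if (length(cand) > 1) {
    ar <- box_area(other[cand, , drop = FALSE])
    cand <- cand[ar == max(ar)]
  }
  if (length(cand) > 1) {
    cb <- other[cand, , drop = FALSE]
    cand <- cand[order(cb[, 1], cb[, 2], cb[, 3], cb[, 4])]
  }
  cand[1]
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs, %d + %d unmatched (e = %d)\n",
              length(x$pairs_a), length(x$unmatched_a), length(x$unmatched_b),
              count_errors(x)))
  invisible(x)
}

#' Number of errors of a matching
#'
#' The unmatched boxes of both sides, i.e., both missed lesions (false
#' negatives) and spurious detections (false positives). Equals
#' \eqn{|B| + |B'| - 2|\Omega|}.
#'
#' @param m a [greedy_match()] result.
#' @return integer error count.
#' @export
count_errors <- function(m) {
  length(m$unmatched_a) + length(m$unmatched_b)
}

#' Pairwise agreement between two annotators over a dataset
#'
#' Runs [greedy_match()] on every image and aggregates: the total error count
#' is the sum of per-image unmatched boxes; the IoU is pooled, i.e., the sum
#' of all matched-pair IoUs across the whole dataset divided by the total
#' number of matches (not a mean of per-image means).
#'
#' @param dataset an [annotation_dataset()].
#' @param a,b annotator ids.
#' @return an object of class \code{pairwise_agreement}: list with
#'   \code{e_total}, \code{iou_mean} (\code{NA} when there are no matches
#'   anywhere), \code{n_matches}, and \code{per_image} (per image:
#'   \code{e} and the vector of matched IoUs).
#' @export
pairwise_agreement <- function(dataset, a, b) {
  sa <- get_set(dataset, a); sb <- get_set(dataset, b)
  per_image <- list()
  e_total <- 0L; iou_sum <- 0; n_match <- 0L
  for (img in dataset$frames$image_id) {
    m <- greedy_match(set_boxes(sa, img), set_boxes(sb, img))
    e_total <- e_total + count_errors(m)
    iou_sum <- iou_sum + sum(m$iou)
    n_match <- n_match + length(m$iou)
    per_image[[img]] <- list(e = count_errors(m), iou = m$iou)
  }
  structure(list(annotator_a = a, annotator_b = b, e_total = e_total,
                 iou_mean = if (n_match > 0) iou_sum / n_match else NA_real_,
                 n_matches = n_match, per_image = per_image),
            class = "pairwise_agreement")
}

#' @export
print.pairwise_agreement <- function(x, ...) {
  cat(sprintf("<pairwise_agreement> %s vs %s: e = %d, pooled IoU = %s (%d matches)\n",
              x$annotator_a, x$annotator_b, x$e_total,
              ifelse(is.na(x$iou_mean), "undefined", sprintf("%.3f", x$iou_mean)),
              x$n_matches))
  invisible(x)
}

#' Pairwise error and IoU matrices for a set of annotators
#'
#' @param dataset an [annotation_dataset()].
#' @param ids annotator ids (default: all annotators of the dataset);
#'   at least 2.
#' @return list with symmetric matrices \code{e} (diagonal 0) and \code{iou}
#'   (diagonal 1, \code{NA} where a pair has no matches at all).
#' @export
pairwise_matrix <- function(dataset, ids = annotators(dataset)) {
  if (length(ids) < 2) stop("need at least 2 annotators", call. = FALSE)
  n <- length(ids)
  e <- matrix(0, n, n, dimnames = list(ids, ids))
  ij <- matrix(1, n, n, dimnames = list(ids, ids))
  for (p in seq_len(n - 1)) for (q in (p + 1):n) {
    pa <- pairwise_agreement(dataset, ids[p], ids[q])
    e[p, q] <- e[q, p] <- pa$e_total
    ij[p, q] <- ij[q, p] <- pa$iou_mean
  }
  list(e = e, iou = ij)
}

#' Combined agreement table (IoU above the diagonal, errors below)
#'
#' Formats a [pairwise_matrix()] result as a single square character table
#' with pooled IoU above the diagonal, error counts below, and the
#' per-annotator means over the other annotators appended as a final
#' column (IoU) and row (errors). Undefined IoU cells are rendered empty.
#'
#' @param pm result of [pairwise_matrix()].
#' @param digits decimal places for IoU entries.
#' @return a character matrix suitable for \code{write.csv}.
#' @export
agreement_table <- function(pm, digits = 2) {
  ids <- rownames(pm$e); n <- length(ids)
  out <- matrix("", n + 1, n + 1,
                dimnames = list(c(ids, "e_a"), c(ids, "IoU_a")))
  fm <- function(x) ifelse(is.na(x), "", formatC(x, digits = digits, format = "f"))
  for (p in seq_len(n)) for (q in seq_len(n)) {
    out[p, q] <- if (p < q) fm(pm$iou[p, q])
                 else if (p > q) as.character(pm$e[p, q])
                 else "."
  }
  for (p in seq_len(n)) {
    out[p, n + 1] <- fm(mean(pm$iou[p, -p], na.rm = TRUE))
    out[n + 1, p] <- formatC(mean(pm$e[p, -p]), digits = 1, format = "f")
  }
  out[n + 1, n + 1] <- "."
  out
}
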