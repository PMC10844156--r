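#' Build a majority consensus standard from a panel of experts
#'
#' Per image, panel annotations are fused by a greedy vote. Repeatedly the
#' largest remaining box \code{b} (area, ties broken lexicographically by
#' coordinates, then by panel order) is taken from its annotator's set; every
#' other panel member contributes at most one corresponding box (chosen by
#' maximal intersection, then largest, then lexicographic) into a supporter
#' set \code{B'}; \code{b} and all supporters are removed. If
#' \code{|B'| + 1 > |panel| / 2} — a strict majority of the panel — the
#' coordinate-wise mean of the supporting boxes together with \code{b} is
#' added to the majority set S; otherwise \code{b} is added to the minority
#' (tentative) set S'. With a panel of two, unanimity is therefore required
#' for a lesion to enter S.
#'
#' At most one supporting box per panel member enters \code{B'} because the
#' vote counts supporting experts, not boxes. Supporters removed alongside a
#' minority seed are discarded, not re-seeded; the number of supporters of
#' each tentative lesion is recorded for audit.
#'
#' @param dataset an [annotation_dataset()].
#' @param panel character vector of at least 2 annotator ids forming the
#'   expert panel.
#' @return an object of class \code{consensus_standard}: list with
#'   \code{panel}, and \code{per_image} mapping each image id to
#'   \code{S} (majority box matrix), \code{S_prime} (tentative box matrix),
#'   and the supporter counts \code{s_support} / \code{s_prime_support}
#'   of each majority / tentative box (the seed itself not counted).
#' @export
build_consensus <- function(dataset, panel) {
  if (length(panel) < 2)
    stop("consensus panel must have at least 2 annotators", call. = FALSE)
  sets <- lapply(panel, function(id) get_set(dataset, id))
  per_image <- list()
  for (img in dataset$frames$image_id) {
    pool <- lapply(sets, set_boxes, image_id = img)
    S <- empty_boxes(); Sp <- empty_boxes()
    s_support <- integer(); sp_support <- integer()
    repeat {
      counts <- vapply(pool, nrow, integer(1))
      if (sum(counts) == 0) break
      seat <- pick_global_seed(pool)
      seed <- pool[[seat$member]][seat$row, ]
      pool[[seat$member]] <- pool[[seat$member]][-seat$row, , drop = FALSE]
      support <- empty_boxes()
      for (m in seq_along(pool)) {
        if (m == seat$member || nrow(pool[[m]]) == 0) next
        cand <- which(corresponding_rows(seed, pool[[m]]))
        if (length(cand) == 0) next
        j <- pick_candidate(seed, pool[[m]], cand)
        support <- rbind(support, pool[[m]][j, , drop = FALSE])
        pool[[m]] <- pool[[m]][-j, , drop = FALSE]
      }
      if (nrow(support) + 1 > length(panel) / 2) {
        S <- rbind(S, colMeans(rbind(support, matrix(seed, nrow = 1))))
        s_support <- c(s_support, nrow(support))
      } else {
        Sp <- rbind(Sp, matrix(seed, nrow = 1))
        sp_support <- c(sp_support, nrow(support))
      }
    }
    colnames(S) <- colnames(Sp) <- c("xmin", "ymin", "xmax", "ymax")
    per_image[[img]] <- list(S = S, S_prime = Sp,
                             s_support = s_support,
                             s_prime_support = sp_support)
  }
  structure(list(panel = panel, per_image = per_image),
            class = "consensus_standard")
}

# Globally largest remaining box across the panel pool: area desc, then
# lexicographic coordinates, then panel position.
pick_global_seed <- function(pool) {
  best <- NULL
  for (m in seq_along(pool)) {
    b <- pool[[m]]
    if (nrow(b) == 0) next
    ord <- order(-box_area(b), b[, 1], b[, 2], b[, 3], b[, 4])
    r <- ord[1]
    key <- c(-box_area(b[r, , drop = FALSE]), b[r, ])
    if (is.null(best) || lex_less(key, best$key))
      best <- list(member = m, row = r, key = key)
  }
  best
}

lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' @export
print.consensus_standard <- function(x, ...) {
  ns <- sum(vapply(x$per_image, function(p) nrow(p$S), integer(1)))
  np <- sum(vapply(x$per_image, function(p) nrow(p$S_prime), integer(1)))
  cat(sprintf("<consensus_standard> panel {%s}: %d majority, %d tentative lesions on %d images\n",
              paste(x$panel, collapse = ", "), ns, np, length(x$per_image)))
  invisible(x)
}

#' Count majority and tentative lesions of a consensus standard
#' @param std a [build_consensus()] result.
#' @return named vector with elements \code{majority} and \code{minority}.
#' @export
consensus_counts <- function(std) {
  c(majority = sum(vapply(std$per_image, function(p) nrow(p$S), integer(1))),
    minority = sum(vapply(std$per_image, function(p) nrow(p$S_prime), integer(1))))
}

#' Leave-one-out consensus standards
#'
#' Builds one consensus standard per evaluated expert, in each case excluding
#' that expert from the panel so that nobody is compared against a standard
#' they helped create. An optional annotator can be excluded from every panel
#' (e.g., the reference annotator of a training set, or an outlier expert in
#' a reduced variant).
#'
#' @param dataset an [annotation_dataset()].
#' @param experts character vector of expert ids from which panels are drawn.
#' @param exclude_always optional id never admitted to any panel.
#' @return named list of [build_consensus()] standards; each element is named
#'   after the left-out expert and carries that id in \code{$excluded}.
#' @export
leave_one_out_standards <- function(dataset, experts, exclude_always = NULL) {
  pool <- setdiff(experts, exclude_always)
  if (length(pool) < 3)
    stop("leave-one-out needs at least 3 available experts", call. = FALSE)
  stds <- list()
  for (x in pool) {
    panel <- setdiff(pool, x)
    if (length(panel) < 2)
      stop("panel would shrink below 2 experts", call. = FALSE)
    std <- build_consensus(dataset, panel)
    std$excluded <- x
    stds[[x]] <- std
  }
  stds
}

#' Evaluate an annotator against a consensus standard
#'
#' Per image the annotator's boxes are first matched (greedily) against the
#' majority set S; the remaining annotator boxes are then matched against the
#' tentative set S' and any that match are discarded — a detection of a
#' tentative lesion is neither a true positive nor a false positive. The
#' error count sums unmatched S boxes (missed confirmed lesions) and
#' annotator boxes matched by neither S nor S' (spurious detections). The
#' pooled IoU is computed over S-matches only; S' matches contribute nothing.
#'
#' @param set the annotator's [annotation_set()]; must not belong to the
#'   standard's panel.
#' @param std a [build_consensus()] standard.
#' @return list with \code{annotator_id}, \code{e}, \code{iou_mean}
#'   (\code{NA} when no S-matches exist), \code{n_matches},
#'   \code{n_tentative_discarded}, and \code{per_image} detail.
#' @export
evaluate_against_consensus <- function(set, std) {
  if (set$annotator_id %in% std$panel)
    stop(sprintf("annotator '%s' is in the standard's panel; evaluating against a standard built from one's own annotations is biased",
                 set$annotator_id), call. = FALSE)
  e_total <- 0L; iou_sum <- 0; n_match <- 0L; n_tent <- 0L
  per_image <- list()
  for (img in names(std$per_image)) {
    ab <- set_boxes(set, img)
    ref <- std$per_image[[img]]
    mS <- greedy_match(ab, ref$S)
    leftover <- ab[mS$unmatched_a, , drop = FALSE]
    mSp <- greedy_match(leftover, ref$S_prime)
    e_i <- length(mS$unmatched_b) + length(mSp$unmatched_a)
    e_total <- e_total + e_i
    iou_sum <- iou_sum + sum(mS$iou)
    n_match <- n_match + length(mS$iou)
    n_tent <- n_tent + length(mSp$pairs_a)
    per_image[[img]] <- list(e = e_i, iou = mS$iou)
  }
  list(annotator_id = set$annotator_id, e = e_total,
       iou_mean = if (n_match > 0) iou_sum / n_match else NA_real_,
       n_matches = n_match, n_tentative_discarded = n_tent,
       per_image = per_image)
}

#' Evaluate a whole panel and its peers against leave-one-out standards
#'
#' Each expert is evaluated only on the standard that excludes them; every
#' other annotator is evaluated on all standards; per-annotator results are
#' averaged (arithmetic mean) over the applicable standards.
#'
#' @param dataset an [annotation_dataset()].
#' @param experts expert ids forming the leave-one-out panels.
#' @param others annotator ids evaluated on every standard; defaults to all
#'   dataset annotators outside \code{experts}.
#' @param exclude_always optional id never admitted to any panel (it may
#'   still appear in \code{others}).
#' @return an object of class \code{consensus_evaluation}: list with
#'   \code{results} (long data.frame: annotator, standard, e, iou),
#'   \code{summary} (per-annotator averages), and \code{standards}.
#' @export
evaluate_all_against_standards <- function(dataset, experts,
                                           others = NULL,
                                           exclude_always = NULL) {
  stds <- leave_one_out_standards(dataset, experts, exclude_always)
  pool <- setdiff(experts, exclude_always)
  if (is.null(others))
    others <- setdiff(annotators(dataset), pool)
  rows <- list()
  for (x in pool) {
    ev <- evaluate_against_consensus(get_set(dataset, x), stds[[x]])
    rows[[length(rows) + 1]] <- data.frame(
      annotator = x, standard = x, e = ev$e, iou = ev$iou_mean,
      stringsAsFactors = FALSE)
  }
  for (a in others) for (x in names(stds)) {
    ev <- evaluate_against_consensus(get_set(dataset, a), stds[[x]])
    rows[[length(rows) + 1]] <- data.frame(
      annotator = a, standard = x, e = ev$e, iou = ev$iou_mean,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$annotator), function(d)
    data.frame(annotator = d$annotator[1], n_standards = nrow(d),
               e_avg = mean(d$e), iou_avg = mean(d$iou, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, standards = stds),
            class = "consensus_evaluation")
}

#' @export
print.consensus_evaluation <- function(x, ...) {
  cat("<consensus_evaluation>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Wide table of a consensus evaluation, with dashes for non-applicable cells
#'
#' @param ev a [evaluate_all_against_standards()] result.
#' @param digits decimal places for IoU entries.
#' @return a character data.frame with one row per annotator, an IoU and e
#'   column per standard, and the averaged columns.
#' @export
consensus_table <- function(ev, digits = 3) {
  std_ids <- names(ev$standards)
  anns <- unique(ev$results$annotator)
  fm <- function(x) ifelse(is.na(x), "-", formatC(x, digits = digits, format = "f"))
  out <- data.frame(annotator = anns, stringsAsFactors = FALSE)
  for (x in std_ids) {
    sub <- ev$results[ev$results$standard == x, ]
    i <- match(anns, sub$annotator)
    out[[paste0("IoU_excl_", x)]] <- ifelse(is.na(i), "-", fm(sub$iou[i]))
    out[[paste0("e_excl_", x)]] <- ifelse(is.na(i), "-", as.character(sub$e[i]))
  }
  i <- match(anns, ev$summary$annotator)
  out$IoU_avg <- fm(ev$summary$iou_avg[i])
  out$e_avg <- formatC(ev$summary$e_avg[i], digits = 1, format = "f")
  out
}

#' F1 score from precision and recall
#'
#' @param precision,recall ratios in \[0, 1\].
#' @return the harmonic mean \code{2 * P * R / (P + R)}; \code{NA} when both
#'   are zero.
#' @export
#' @examples
#' round(f1_score(0.78, 0.73), 2)
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, NA_real_,
         2 * precision * recall / (precision + recall))
}

#' Detection errors expressed as a surface classification error
#'
#' Converts a detection error count into the equivalent per-surface
#' classification error rate, given the average number of scoreable surfaces
#' per image (for bitewing radiographs, around 13 proximal surfaces).
#'
#' @param e error count.
#' @param n_images number of images in the dataset.
#' @param surfaces_per_image average scoreable surfaces per image (default 13).
#' @return the percentage \code{100 * e / (n_images * surfaces_per_image)},
#'   rounded to 1 decimal place.
#' @export
#' @examples
#' classification_error(83, 100, 13)  # 6.4
classification_error <- function(e, n_images, surfaces_per_image = 13) {
  round(100 * e / (n_images * surfaces_per_image), 1)
}

#' Compare an annotator with a designated reference annotator
#'
#' Greedy matching per image against the reference; matches are true
#' positives, unmatched annotator boxes false positives, unmatched reference
#' boxes false negatives.
#'
#' @param dataset an [annotation_dataset()].
#' @param annotator,reference distinct annotator ids.
#' @param surfaces_per_image see [classification_error()].
#' @return an object of class \code{reference_comparison}: list with
#'   \code{tp}, \code{fp}, \code{fn}, \code{precision}, \code{recall},
#'   \code{f1}, \code{e} (\code{= fp + fn}), \code{iou_mean} (pooled) and
#'   \code{classification_error} (percent).
#' @export
compare_to_reference <- function(dataset, annotator, reference,
                                 surfaces_per_image = 13) {
  if (identical(annotator, reference))
    stop("annotator and reference must differ", call. = FALSE)
  sa <- get_set(dataset, annotator); sr <- get_set(dataset, reference)
  tp <- fp <- fn <- 0L; iou_sum <- 0; n_match <- 0L
  for (img in dataset$frames$image_id) {
    m <- greedy_match(set_boxes(sa, img), set_boxes(sr, img))
    tp <- tp + length(m$pairs_a)
    fp <- fp + length(m$unmatched_a)
    fn <- fn + length(m$unmatched_b)
    iou_sum <- iou_sum + sum(m$iou); n_match <- n_match + length(m$iou)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  structure(list(
    annotator_id = annotator, reference_id = reference,
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall,
    f1 = f1_score(precision, recall),
    e = fp + fn,
    iou_mean = if (n_match > 0) iou_sum / n_match else NA_real_,
    classification_error = classification_error(fp + fn,
                                                nrow(dataset$frames),
                                                surfaces_per_image),
    surfaces_per_image = surfaces_per_image),
    class = "reference_comparison")
}

#' @export
print.reference_comparison <- function(x, ...) {
  cat(sprintf("<reference_comparison> %s vs reference %s\n",
              x$annotator_id, x$reference_id))
  cat(sprintf("  TP %d  FP %d  FN %d  (e = %d)\n", x$tp, x$fp, x$fn, x$e))
  cat(sprintf("  precision %.2f  recall %.2f  F1 %.2f  pooled IoU %s\n",
              x$precision, x$recall, x$f1,
              ifelse(is.na(x$iou_mean), "undefined", sprintf("%.3f", x$iou_mean))))
  cat(sprintf("  classification error %.1f%% (%d surfaces/image)\n",
              x$classification_error, x$surfaces_per_image))
  invisible(x)
}
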