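#' Per-image paired difference series between two annotators
#'
#' For each image, the difference in disagreement with a set of reference
#' annotators: \eqn{\Delta^i = \sum_c [ m(B_{ia}, B_{ic}) - m(B_{ib}, B_{ic}) ]}
#' where m is either the per-image error count or the per-image pooled
#' matched IoU. A negative error difference (or positive IoU difference)
#' means annotator \code{a} is closer to the references on that image.
#' With a single reference the series reduces to the plain per-image
#' difference against that one annotator.
#'
#' For the IoU metric, an image where any involved pairing has no matched
#' boxes is dropped from the series (the per-image pooled IoU is undefined
#' there); the number of dropped images is recorded.
#'
#' @param dataset an [annotation_dataset()].
#' @param a,b annotator ids under comparison; for the multi-reference mode
#'   neither may belong to \code{reference_set}.
#' @param reference_set nonempty character vector of reference annotator ids.
#' @param metric \code{"errors"} or \code{"iou"}.
#' @return an object of class \code{paired_difference_series}: list with
#'   \code{values} (named by image id), \code{metric}, \code{n_dropped},
#'   and the identities involved.
#' @export
delta_error_series <- function(dataset, a, b, reference_set,
                               metric = c("errors", "iou")) {
  metric <- match.arg(metric)
  if (length(reference_set) == 0)
    stop("reference_set must be nonempty", call. = FALSE)
  if (a %in% reference_set || b %in% reference_set)
    stop("compared annotators must not be in the reference set",
         call. = FALSE)
  imgs <- dataset$frames$image_id
  acc <- matrix(0, nrow = length(imgs), ncol = 1,
                dimnames = list(imgs, NULL))
  defined <- rep(TRUE, length(imgs)); names(defined) <- imgs
  for (cc in reference_set) {
    pa <- pairwise_agreement(dataset, a, cc)
    pb <- pairwise_agreement(dataset, b, cc)
    for (img in imgs) {
      if (metric == "errors") {
        acc[img, 1] <- acc[img, 1] +
          pa$per_image[[img]]$e - pb$per_image[[img]]$e
      } else {
        ia <- pa$per_image[[img]]$iou; ib <- pb$per_image[[img]]$iou
        if (length(ia) == 0 || length(ib) == 0) {
          defined[img] <- FALSE
        } else {
          acc[img, 1] <- acc[img, 1] + mean(ia) - mean(ib)
        }
      }
    }
  }
  values <- acc[defined, 1]
  structure(list(annotator_a = a, annotator_b = b,
                 reference_set = reference_set, metric = metric,
                 values = values, n_dropped = sum(!defined)),
            class = "paired_difference_series")
}

#' Wilcoxon signed-rank test with signed significance score
#'
#' Two-sided signed-rank test on a series of paired differences. Zero
#' differences are discarded before ranking by default (Wilcoxon's original
#' treatment); the Pratt alternative ranks them with the rest and then drops
#' them from the statistic. Ties receive average ranks. The exact null
#' distribution (full distribution of the rank-sum statistic over all sign
#' assignments, computed by dynamic programming and valid under ties) is
#' used when at most \code{exact_limit} nonzero values remain; otherwise a
#' normal approximation with continuity correction is applied, with the
#' variance computed from the actual (tied) ranks.
#'
#' The signed score \eqn{q = \pm(1 - p)} encodes the p-value and the
#' direction: positive when the positive ranks dominate. It is lossless:
#' \eqn{p = 1 - |q|} whenever \eqn{q \neq 0}.
#'
#' @param series a [delta_error_series()] result or a plain numeric vector.
#' @param alpha significance level (default 0.05).
#' @param zeros \code{"discard"} (default) or \code{"pratt"}.
#' @param exact_limit largest nonzero count for which the exact null
#'   distribution is enumerated (default 25).
#' @return an object of class \code{significance_cell}: list with \code{p},
#'   \code{direction} (-1, 0 or 1), \code{q}, \code{significant},
#'   \code{statistic} (the positive rank sum W+), \code{n_nonzero},
#'   \code{method} ("exact", "normal" or "degenerate").
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p  # 2 / 2^5 = 0.0625
wilcoxon_signed_rank <- function(series, alpha = 0.05,
                                 zeros = c("discard", "pratt"),
                                 exact_limit = 25) {
  zeros <- match.arg(zeros)
  x <- if (inherits(series, "paired_difference_series")) series$values
       else as.numeric(series)
  if (length(x) < 1) stop("series must have length >= 1", call. = FALSE)
  nz <- x != 0
  if (!any(nz)) {
    return(structure(list(p = 1, direction = 0, q = 0, significant = FALSE,
                          statistic = 0, n_nonzero = 0L,
                          method = "degenerate", alpha = alpha),
                     class = "significance_cell"))
  }
  r <- if (zeros == "discard") rank(abs(x[nz])) else rank(abs(x))[nz]
  W <- sum(r[x[nz] > 0])
  n <- length(r)
  mu <- sum(r) / 2
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, W)
    method <- "exact"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- if (W == mu) 0 else (W - mu - 0.5 * sign(W - mu)) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  p <- min(p, 1)
  direction <- sign(W - mu)
  structure(list(p = p, direction = direction, q = direction * (1 - p),
                 significant = p < alpha, statistic = W, n_nonzero = n,
                 method = method, alpha = alpha),
            class = "significance_cell")
}

# Exact two-sided p-value of the signed-rank statistic for rank vector r
# (average ranks allowed: doubled ranks are integers). The distribution of
# W+ over the 2^n equiprobable sign assignments is built by dynamic
# programming over achievable doubled sums.
signed_rank_exact_p <- function(r, W) {
  d <- as.integer(round(2 * r))
  total <- sum(d)
  f <- numeric(total + 1)
  f[1] <- 1
  for (di in d) {
    g <- f
    g[(di + 1):(total + 1)] <- g[(di + 1):(total + 1)] + f[1:(total + 1 - di)]
    f <- g
  }
  f <- f / 2^length(d)
  w2 <- as.integer(round(2 * W))
  p_le <- sum(f[seq_len(w2 + 1)])
  p_ge <- sum(f[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.significance_cell <- function(x, ...) {
  cat(sprintf("<significance_cell> W+ = %g, n = %d, p = %.4g (%s), q = %+.4f%s\n",
              x$statistic, x$n_nonzero, x$p, x$method, x$q,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Significance matrix of pairwise annotator differences
#'
#' For every ordered pair of annotators, tests whether one is closer than
#' the other to a reference — either the expert panel (each pair compared
#' through all experts that are not one of the two) or a single designated
#' reference annotator. Cell (a, b) carries the signed score q: positive
#' when the row annotator a is on average closer to the reference than the
#' column annotator b.
#'
#' @param dataset an [annotation_dataset()].
#' @param ids annotators forming the rows and columns of the grid.
#' @param mode \code{"experts"} (reference set = \code{experts} minus the
#'   two compared) or \code{"reference"} (a single reference annotator).
#' @param metric \code{"errors"} or \code{"iou"}.
#' @param experts expert ids; required for mode \code{"experts"}.
#' @param reference reference id; required for mode \code{"reference"}.
#' @param alpha significance level.
#' @param ... passed to [wilcoxon_signed_rank()].
#' @return an object of class \code{significance_matrix}: list with square
#'   matrices \code{q} and \code{p} (diagonal \code{NA}) and the grid of
#'   \code{cells}.
#' @export
significance_matrix <- function(dataset, ids,
                                mode = c("experts", "reference"),
                                metric = c("errors", "iou"),
                                experts = NULL, reference = NULL,
                                alpha = 0.05, ...) {
  mode <- match.arg(mode); metric <- match.arg(metric)
  if (mode == "experts" && is.null(experts))
    stop("mode 'experts' requires the experts argument", call. = FALSE)
  if (mode == "reference" && is.null(reference))
    stop("mode 'reference' requires the reference argument", call. = FALSE)
  n <- length(ids)
  q <- p <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  cells <- vector("list", n * n)
  dim(cells) <- c(n, n); dimnames(cells) <- list(ids, ids)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- ids[i]; b <- ids[j]
    ref <- if (mode == "experts") setdiff(experts, c(a, b)) else reference
    if (length(ref) == 0)
      stop(sprintf("empty reference set for pair (%s, %s)", a, b),
           call. = FALSE)
    ser <- delta_error_series(dataset, a, b, ref, metric = metric)
    # an IoU series can lose every image to the no-match drop rule;
    # report such a cell as degenerate rather than failing
    cell <- if (length(ser$values) == 0)
      structure(list(p = 1, direction = 0, q = 0, significant = FALSE,
                     statistic = 0, n_nonzero = 0L, method = "degenerate",
                     alpha = alpha), class = "significance_cell")
    else wilcoxon_signed_rank(ser, alpha = alpha, ...)
    # for errors, smaller is better: closer-to-reference means negative
    # differences, so flip the sign so green (positive q) = row is closer
    flip <- if (metric == "errors") -1 else 1
    q[i, j] <- flip * cell$q
    p[i, j] <- cell$p
    cells[[i, j]] <- cell
  }
  structure(list(q = q, p = p, cells = cells, mode = mode, metric = metric,
                 alpha = alpha),
            class = "significance_matrix")
}

#' @export
print.significance_matrix <- function(x, ...) {
  cat(sprintf("<significance_matrix> mode '%s', metric '%s' — signed scores q = ±(1-p):\n",
              x$mode, x$metric))
  print(round(x$q, 3))
  invisible(x)
}

#' Heatmap of a significance matrix
#'
#' Renders the signed scores q as a red/green tile grid: green cells mean
#' the row annotator is closer to the reference than the column annotator,
#' red the opposite; colors saturate where the difference is significant
#' (|q| > 1 - alpha).
#'
#' @param sm a [significance_matrix()] result.
#' @return a ggplot object.
#' @export
plot_significance <- function(sm) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_significance requires ggplot2", call. = FALSE)
  ids <- rownames(sm$q)
  df <- expand.grid(row = ids, col = ids, stringsAsFactors = FALSE)
  df$q <- as.vector(sm$q)
  df <- df[!is.na(df$q), ]
  thr <- 1 - sm$alpha
  ggplot2::ggplot(df, ggplot2::aes(x = factor(col, levels = ids),
                                   y = factor(row, levels = rev(ids)),
                                   fill = q)) +
    ggplot2::geom_tile(color = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%+.2f", q)), size = 3) +
    ggplot2::scale_fill_gradientn(
      colours = c("#7f0000", "#ff9999", "white", "#99dd99", "#006400"),
      values = c(0, (1 - thr) / 2 + 0.0, 0.5, 1 - ((1 - thr) / 2), 1),
      limits = c(-1, 1)) +
    ggplot2::labs(x = "column annotator", y = "row annotator",
                  fill = "q = ±(1-p)",
                  title = sprintf("Signed significance (%s, vs %s)",
                                  sm$metric, sm$mode)) +
    ggplot2::theme_minimal()
}

#' Mean agreement of one annotator with a set of peers
#'
#' Arithmetic means of the pairwise error count and the pairwise pooled IoU
#' over all peers other than the annotator itself.
#'
#' @param dataset an [annotation_dataset()].
#' @param a annotator id.
#' @param peer_set character vector of peer ids; \code{a} itself is excluded,
#'   and the remainder must be nonempty.
#' @return an object of class \code{mean_agreement}: list with \code{e_mean},
#'   \code{iou_mean_over_peers} and \code{peers}. Peers whose pairwise IoU is
#'   undefined (no matches anywhere) are excluded from the IoU mean with a
#'   warning.
#' @export
mean_agreement <- function(dataset, a, peer_set) {
  peers <- setdiff(peer_set, a)
  if (length(peers) == 0)
    stop("peer set (excluding the annotator itself) must be nonempty",
         call. = FALSE)
  pas <- lapply(peers, function(p) pairwise_agreement(dataset, a, p))
  e_vals <- vapply(pas, function(x) as.numeric(x$e_total), numeric(1))
  iou_vals <- vapply(pas, function(x) x$iou_mean, numeric(1))
  if (anyNA(iou_vals)) {
    warning(sprintf("%d peer(s) with undefined pairwise IoU excluded from the mean",
                    sum(is.na(iou_vals))))
  }
  structure(list(annotator_id = a, peers = peers,
                 e_mean = mean(e_vals),
                 iou_mean_over_peers = mean(iou_vals, na.rm = TRUE)),
            class = "mean_agreement")
}

#' @export
print.mean_agreement <- function(x, ...) {
  cat(sprintf("<mean_agreement> %s over {%s}: e = %.1f, IoU = %.3f\n",
              x$annotator_id, paste(x$peers, collapse = ", "),
              x$e_mean, x$iou_mean_over_peers))
  invisible(x)
}
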