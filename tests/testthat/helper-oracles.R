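# Independent oracles and fixture generators. The matcher oracle and the
# signed-rank oracle are deliberately written as literal, slow enumerations
# that share no code with the package implementations.

# --- brute-force greedy matcher ------------------------------------------

bf_centroid <- function(b) c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)

bf_inside <- function(p, b) {
  p[1] >= b[1] && p[1] <= b[3] && p[2] >= b[2] && p[2] <= b[4]
}

bf_correspond <- function(b1, b2) {
  bf_inside(bf_centroid(b1), b2) || bf_inside(bf_centroid(b2), b1)
}

bf_inter_area <- function(b1, b2) {
  w <- min(b1[3], b2[3]) - max(b1[1], b2[1])
  h <- min(b1[4], b2[4]) - max(b1[2], b2[2])
  if (w <= 0 || h <= 0) 0 else w * h
}

bf_area <- function(b) (b[3] - b[1]) * (b[4] - b[2])

# Literal enumeration of the greedy steps: seeds taken from the union in
# order of decreasing area (ties: lexicographic coordinates, then side a);
# partner = corresponding box on the other side maximizing the intersection,
# ties by larger area, then lexicographic; matched boxes removed; an
# unmatched seed stays available as a partner for later seeds.
bf_greedy_match <- function(A, B) {
  rows <- list()
  for (i in seq_len(nrow(A))) rows[[length(rows) + 1]] <-
    list(side = "a", idx = i, box = as.numeric(A[i, ]))
  for (i in seq_len(nrow(B))) rows[[length(rows) + 1]] <-
    list(side = "b", idx = i, box = as.numeric(B[i, ]))
  matched <- rep(FALSE, length(rows))
  considered <- rep(FALSE, length(rows))
  pairs <- list()
  repeat {
    seed_k <- NA
    for (k in seq_along(rows)) {
      if (matched[k] || considered[k]) next
      if (is.na(seed_k)) { seed_k <- k; next }
      a <- rows[[k]]; s <- rows[[seed_k]]
      ka <- c(-bf_area(a$box), a$box, if (a$side == "a") 1 else 2)
      ks <- c(-bf_area(s$box), s$box, if (s$side == "a") 1 else 2)
      for (f in seq_along(ka)) {
        if (ka[f] < ks[f]) { seed_k <- k; break }
        if (ka[f] > ks[f]) break
      }
    }
    if (is.na(seed_k)) break
    considered[seed_k] <- TRUE
    seed <- rows[[seed_k]]
    best <- NA
    for (k in seq_along(rows)) {
      if (matched[k] || rows[[k]]$side == seed$side) next
      if (!bf_correspond(seed$box, rows[[k]]$box)) next
      if (is.na(best)) { best <- k; next }
      ic <- bf_inter_area(seed$box, rows[[k]]$box)
      ib <- bf_inter_area(seed$box, rows[[best]]$box)
      if (ic > ib) { best <- k; next }
      if (ic < ib) next
      ac <- bf_area(rows[[k]]$box); ab <- bf_area(rows[[best]]$box)
      if (ac > ab) { best <- k; next }
      if (ac < ab) next
      kc <- rows[[k]]$box; kb <- rows[[best]]$box
      for (f in 1:4) {
        if (kc[f] < kb[f]) { best <- k; break }
        if (kc[f] > kb[f]) break
      }
    }
    if (!is.na(best)) {
      matched[seed_k] <- TRUE; matched[best] <- TRUE
      pa <- if (seed$side == "a") seed$idx else rows[[best]]$idx
      pb <- if (seed$side == "a") rows[[best]]$idx else seed$idx
      pairs[[length(pairs) + 1]] <- c(pa, pb)
    }
  }
  ua <- ub <- integer()
  for (k in seq_along(rows)) {
    if (matched[k]) next
    if (rows[[k]]$side == "a") ua <- c(ua, rows[[k]]$idx)
    else ub <- c(ub, rows[[k]]$idx)
  }
  list(pairs = pairs, unmatched_a = sort(ua), unmatched_b = sort(ub))
}

# --- signed-rank exact p by full enumeration ------------------------------

enum_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  stopifnot(n >= 1, n <= 15)
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(ws <= W + 1e-9)
  p_ge <- mean(ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# --- fixture generators ---------------------------------------------------

random_box <- function(frame = c(100, 100), max_side = 40) {
  w <- runif(1, 2, max_side); h <- runif(1, 2, max_side)
  x <- runif(1, 0, frame[1] - w); y <- runif(1, 0, frame[2] - h)
  boxes(x, y, x + w, y + h)
}

random_box_matrix <- function(n, frame = c(100, 100), max_side = 40,
                              integer_coords = FALSE) {
  if (n == 0) return(empty_boxes())
  b <- do.call(rbind, lapply(seq_len(n), function(i)
    random_box(frame, max_side)))
  if (integer_coords) {
    b <- floor(b)
    b[, 3] <- pmax(b[, 3], b[, 1] + 1)
    b[, 4] <- pmax(b[, 4], b[, 2] + 1)
  }
  b
}

# A tiny dataset with the given per-image box lists.
# spec: list(annotator = list(image_id = matrix, ...), ...)
make_dataset <- function(spec, width = 100, height = 100) {
  imgs <- unique(unlist(lapply(spec, names)))
  frames <- data.frame(image_id = imgs, width = width, height = height,
                       stringsAsFactors = FALSE)
  sets <- lapply(names(spec), function(a) annotation_set(a, spec[[a]]))
  annotation_dataset(frames, sets)
}

expect_valid_matching <- function(m) {
  # conservation
  expect_equal(2 * length(m$pairs_a) +
                 length(m$unmatched_a) + length(m$unmatched_b),
               nrow(m$a_boxes) + nrow(m$b_boxes))
  # no box used twice
  expect_false(anyDuplicated(m$pairs_a) > 0)
  expect_false(anyDuplicated(m$pairs_b) > 0)
  # every pair satisfies the correspondence relation
  for (k in seq_along(m$pairs_a))
    expect_true(boxes_correspond(m$a_boxes[m$pairs_a[k], ],
                                 m$b_boxes[m$pairs_b[k], ]))
  # maximality: no unmatched cross-pair corresponds
  for (i in m$unmatched_a) for (j in m$unmatched_b)
    expect_false(boxes_correspond(m$a_boxes[i, ], m$b_boxes[j, ]))
}
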