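test_that("layouts are reproducible from their seed", {
  l1 <- generate_layout(n_images = 10, lesion_rate = 2, seed = 7)
  l2 <- generate_layout(n_images = 10, lesion_rate = 2, seed = 7)
  expect_identical(l1$lesions, l2$lesions)
  l3 <- generate_layout(n_images = 10, lesion_rate = 2, seed = 8)
  expect_false(identical(l1$lesions, l3$lesions))
})

test_that("lesion_rate 0 yields empty images; boxes stay in frame and apart", {
  l0 <- generate_layout(n_images = 5, lesion_rate = 0, seed = 1)
  expect_true(all(vapply(l0$lesions, nrow, integer(1)) == 0))

  l <- generate_layout(n_images = 30, lesion_rate = 4, seed = 3)
  for (img in names(l$lesions)) {
    b <- l$lesions[[img]]
    if (nrow(b) == 0) next
    expect_true(all(b[, 1] >= 0 & b[, 2] >= 0 &
                    b[, 3] <= 896 & b[, 4] <= 1024))
    sides <- c(b[, 3] - b[, 1], b[, 4] - b[, 2])
    expect_true(all(sides >= 8 & sides <= 160))
    # min-separation: no same-image pair corresponds
    if (nrow(b) > 1) {
      for (i in seq_len(nrow(b) - 1))
        expect_false(any(corresponding_rows(b[i, ],
                                            b[-seq_len(i), , drop = FALSE])))
    }
  }
})

test_that("per-image lesion counts follow the Poisson rate", {
  l <- generate_layout(n_images = 1000, lesion_rate = 3, seed = 5)
  counts <- vapply(l$lesions, nrow, integer(1))
  expect_lt(abs(mean(counts) - 3), 0.2)
})

test_that("a perfect annotator reproduces the layout exactly", {
  layout <- generate_layout(n_images = 15, lesion_rate = 3, seed = 9)
  perfect <- simulate_annotator(layout, annotator_profile(
    "P", sensitivity = 1, fp_per_image = 0, center_jitter_sd = 0,
    scale_factor = 1, size_noise_sd = 0), seed = 1)
  ds <- annotation_dataset(layout$frames,
                           list(perfect, layout_as_set(layout)))
  pa <- pairwise_agreement(ds, "P", "GT")
  expect_equal(pa$e_total, 0L)
  expect_equal(pa$iou_mean, 1)
})

test_that("a blind annotator misses every lesion", {
  layout <- generate_layout(n_images = 15, lesion_rate = 3, seed = 10)
  blind <- simulate_annotator(layout, annotator_profile(
    "Z", sensitivity = 0, fp_per_image = 0), seed = 1)
  expect_equal(sum(vapply(blind$boxes_by_image, nrow, integer(1))), 0)
  ds <- annotation_dataset(layout$frames, list(blind, layout_as_set(layout)))
  pa <- pairwise_agreement(ds, "Z", "GT")
  expect_equal(pa$e_total, sum(vapply(layout$lesions, nrow, integer(1))))
  expect_true(is.na(pa$iou_mean))
})

test_that("scale_factor 2 doubles the mean box side", {
  layout <- generate_layout(n_images = 120, lesion_rate = 3, seed = 12)
  doubler <- simulate_annotator(layout, annotator_profile(
    "D", sensitivity = 1, fp_per_image = 0, center_jitter_sd = 0,
    scale_factor = 2, size_noise_sd = 0), seed = 2)
  ref_stats <- annotation_stats(layout_as_set(layout))
  d_stats <- annotation_stats(doubler)
  expect_gt(d_stats$n_boxes, 300)
  expect_lt(abs(d_stats$mean_side / ref_stats$mean_side - 2), 2 * 0.05)
})

test_that("panel simulation is seed-stable and id-keyed", {
  layout <- generate_layout(n_images = 10, lesion_rate = 2, seed = 14)
  p <- list(annotator_profile("A", seed = NULL),
            annotator_profile("B", fp_per_image = 1, seed = NULL))
  ds1 <- simulate_panel(layout, p, seed = 3)
  ds2 <- simulate_panel(layout, p, seed = 3)
  expect_identical(ds1$annotations$A$boxes_by_image,
                   ds2$annotations$A$boxes_by_image)
  # adding an annotator does not perturb the others
  ds3 <- simulate_panel(layout, c(p, list(annotator_profile("C"))), seed = 3)
  expect_identical(ds3$annotations$A$boxes_by_image,
                   ds1$annotations$A$boxes_by_image)
  expect_identical(ds3$annotations$B$boxes_by_image,
                   ds1$annotations$B$boxes_by_image)
  expect_error(simulate_panel(layout, list(annotator_profile("A"),
                                           annotator_profile("A"))),
               "duplicate")
})

test_that("identical deterministic profiles agree perfectly pairwise", {
  layout <- generate_layout(n_images = 10, lesion_rate = 2, seed = 15)
  mk <- function(id) simulate_annotator(layout, annotator_profile(
    id, sensitivity = 1, fp_per_image = 0, center_jitter_sd = 0,
    scale_factor = 1, size_noise_sd = 0), seed = 99)
  ds <- annotation_dataset(layout$frames, list(mk("A"), mk("B")))
  pa <- pairwise_agreement(ds, "A", "B")
  expect_equal(pa$e_total, 0L)
})

test_that("the bitewing preset lands near its per-annotator count targets", {
  layout <- generate_layout(n_images = 100, lesion_rate = 3, seed = 16)
  profiles <- bitewing_panel_profiles()
  ds <- simulate_panel(layout, profiles, seed = 16)
  for (id in names(profiles)) {
    n <- sum(vapply(ds$annotations[[id]]$boxes_by_image, nrow, integer(1)))
    target <- attr(profiles[[id]], "expected_count")
    expect_gt(n, 0.75 * target)
    expect_lt(n, 1.25 * target)
  }
  # qualitative panel features: an over-caller and a double-size expert
  stats <- do.call(rbind, lapply(ds$annotations, annotation_stats))
  expect_equal(stats$annotator_id[which.max(stats$n_boxes)], "E1")
  expect_equal(stats$annotator_id[which.max(stats$mean_side)], "E4")
})

test_that("more center jitter means lower mean pairwise IoU", {
  ious <- vapply(c(1, 8, 20), function(jit) {
    vals <- vapply(1:10, function(s) {
      layout <- generate_layout(n_images = 8, lesion_rate = 3, seed = 100 + s)
      a <- simulate_annotator(layout, annotator_profile(
        "A", sensitivity = 1, fp_per_image = 0, center_jitter_sd = jit,
        size_noise_sd = 0), seed = 200 + s)
      ds <- annotation_dataset(layout$frames, list(a, layout_as_set(layout)))
      pairwise_agreement(ds, "A", "GT")$iou_mean
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(ious) < 0))
})

test_that("the flawless annotator dominates degraded ones in mean error", {
  for (s in 1:3) {
    layout <- generate_layout(n_images = 12, lesion_rate = 3, seed = 300 + s)
    profiles <- list(
      annotator_profile("perfect", sensitivity = 1, fp_per_image = 0,
                        center_jitter_sd = 0, size_noise_sd = 0),
      annotator_profile("meh", sensitivity = 0.8, fp_per_image = 1,
                        center_jitter_sd = 5),
      annotator_profile("bad", sensitivity = 0.6, fp_per_image = 2,
                        center_jitter_sd = 8))
    ds <- simulate_panel(layout, profiles, seed = s)
    gt <- layout_as_set(layout)
    ds <- annotation_dataset(layout$frames, c(ds$annotations["perfect"],
                                              ds$annotations["meh"],
                                              ds$annotations["bad"],
                                              list(gt)))
    peers <- c("perfect", "meh", "bad", "GT")
    e_perfect <- mean_agreement(ds, "perfect", peers)$e_mean
    for (other in c("meh", "bad"))
      expect_lte(e_perfect, mean_agreement(ds, other, peers)$e_mean)
  }
})
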