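# Panels of well-separated synthetic sites: site k is annotated (with small
# deterministic offsets) by a chosen subset of the panel.
separated_sites_dataset <- function(support_sets, panel, img = "i1") {
  # site k centered at (60 + 200*k, 60), side 40
  spec <- lapply(panel, function(a) {
    b <- empty_boxes()
    for (k in seq_along(support_sets)) {
      if (!(a %in% support_sets[[k]])) next
      off <- 2 * match(a, panel)  # small per-annotator shift, keeps overlap
      x <- 40 + 200 * (k - 1) + off
      b <- rbind(b, boxes(x, 40 + off, x + 40, 80 + off))
    }
    stats::setNames(list(b), img)
  })
  names(spec) <- panel
  make_dataset(spec, width = 200 * length(support_sets) + 100, height = 200)
}

test_that("unanimous boxes enter S as their coordinate-wise mean", {
  b <- boxes(10, 10, 30, 30)
  ds <- make_dataset(list(E1 = list(i1 = b), E2 = list(i1 = b),
                          E3 = list(i1 = b)))
  std <- build_consensus(ds, c("E1", "E2", "E3"))
  expect_equal(unname(std$per_image$i1$S), unname(b))
  expect_equal(nrow(std$per_image$i1$S_prime), 0)
})

test_that("a box marked by 1 of 4 experts is tentative", {
  ds <- make_dataset(list(
    E1 = list(i1 = boxes(10, 10, 30, 30)),
    E2 = list(i1 = empty_boxes()),
    E3 = list(i1 = empty_boxes()),
    E4 = list(i1 = empty_boxes())))
  std <- build_consensus(ds, c("E1", "E2", "E3", "E4"))
  expect_equal(nrow(std$per_image$i1$S), 0)
  expect_equal(unname(std$per_image$i1$S_prime),
               unname(boxes(10, 10, 30, 30)))
})

test_that("three corresponding boxes out of four experts average into S", {
  ds <- make_dataset(list(
    E1 = list(i1 = boxes(0, 0, 10, 10)),
    E2 = list(i1 = boxes(2, 0, 12, 10)),
    E3 = list(i1 = boxes(1, 3, 11, 13)),
    E4 = list(i1 = empty_boxes())))
  std <- build_consensus(ds, c("E1", "E2", "E3", "E4"))
  expect_equal(unname(std$per_image$i1$S), unname(boxes(1, 1, 11, 11)))
  expect_equal(nrow(std$per_image$i1$S_prime), 0)
})

test_that("with a panel of two, unanimity is required", {
  shared <- boxes(10, 10, 50, 50)
  only1 <- boxes(100, 100, 140, 140)
  ds <- make_dataset(list(
    E1 = list(i1 = rbind(shared, only1)),
    E2 = list(i1 = shared + 2)),  # shifted but still corresponding
    width = 300, height = 300)
  std <- build_consensus(ds, c("E1", "E2"))
  expect_equal(nrow(std$per_image$i1$S), 1)
  expect_equal(unname(std$per_image$i1$S), unname(shared + 1))  # mean
  expect_equal(unname(std$per_image$i1$S_prime), unname(only1))
})

test_that("a site lands in S iff supported by a strict majority", {
  panel4 <- c("E1", "E2", "E3", "E4")
  cases <- list(
    list(k = 1, S = FALSE), list(k = 2, S = FALSE),
    list(k = 3, S = TRUE), list(k = 4, S = TRUE))
  for (cs in cases) {
    ds <- separated_sites_dataset(list(panel4[seq_len(cs$k)]), panel4)
    std <- build_consensus(ds, panel4)
    expect_equal(nrow(std$per_image$i1$S) == 1, cs$S,
                 label = sprintf("4-panel, %d supporters in S", cs$k))
    expect_equal(nrow(std$per_image$i1$S_prime) == 1, !cs$S)
  }
  # panel of 3: majority needs 2
  panel3 <- c("E1", "E2", "E3")
  for (k in 1:3) {
    ds <- separated_sites_dataset(list(panel3[seq_len(k)]), panel3)
    std <- build_consensus(ds, panel3)
    expect_equal(nrow(std$per_image$i1$S) == 1, k >= 2)
  }
})

test_that("every panel box is accounted for exactly once", {
  set.seed(31)
  panel <- c("E1", "E2", "E3", "E4")
  for (rep in 1:20) {
    spec <- lapply(panel, function(a)
      list(i1 = random_box_matrix(sample(0:6, 1))))
    names(spec) <- panel
    ds <- make_dataset(spec)
    std <- build_consensus(ds, panel)
    p <- std$per_image$i1
    accounted <- sum(p$s_support + 1) + nrow(p$S_prime) + sum(p$s_prime_support)
    total <- sum(vapply(spec, function(s) nrow(s$i1), integer(1)))
    expect_equal(accounted, total)
  }
})

test_that("leave-one-out builds one standard per evaluated expert", {
  set.seed(17)
  panel <- c("E1", "E2", "E3", "E4")
  spec <- lapply(panel, function(a) list(i1 = random_box_matrix(3)))
  names(spec) <- panel
  ds <- make_dataset(spec)

  stds <- leave_one_out_standards(ds, panel)
  expect_equal(names(stds), panel)
  for (x in panel) {
    expect_equal(sort(stds[[x]]$panel), sort(setdiff(panel, x)))
    expect_equal(stds[[x]]$excluded, x)
  }
  # reduced variant: E1 never enters a panel, remaining panels have size 2
  red <- leave_one_out_standards(ds, panel, exclude_always = "E1")
  expect_equal(names(red), c("E2", "E3", "E4"))
  for (x in names(red)) expect_equal(length(red[[x]]$panel), 2)
  # 3 experts give 2-expert panels; fewer are refused
  stds3 <- leave_one_out_standards(ds, c("E1", "E2", "E3"))
  expect_equal(length(stds3), 3)
  expect_error(leave_one_out_standards(ds, c("E1", "E2")), "at least 3")
})

test_that("evaluation against a standard honors the tentative rule", {
  ds <- make_dataset(list(
    E1 = list(i1 = boxes(10, 10, 30, 30)),
    E2 = list(i1 = boxes(10, 10, 30, 30)),
    E3 = list(i1 = boxes(100, 100, 120, 120)),
    # candidate annotators
    same = list(i1 = boxes(10, 10, 30, 30)),
    tent = list(i1 = rbind(boxes(10, 10, 30, 30), boxes(100, 100, 120, 120))),
    spur = list(i1 = rbind(boxes(10, 10, 30, 30), boxes(200, 200, 220, 220)))),
    width = 300, height = 300)
  std <- build_consensus(ds, c("E1", "E2", "E3"))
  expect_equal(nrow(std$per_image$i1$S), 1)        # the unanimous-ish box
  expect_equal(nrow(std$per_image$i1$S_prime), 1)  # E3's lone box

  same <- evaluate_against_consensus(ds$annotations$same, std)
  expect_equal(same$e, 0L); expect_equal(same$iou_mean, 1)

  # extra box matching only a tentative lesion: neither TP nor FP
  tent <- evaluate_against_consensus(ds$annotations$tent, std)
  expect_equal(tent$e, 0L)
  expect_equal(tent$n_tentative_discarded, 1L)
  expect_equal(tent$iou_mean, 1)  # S-matches only

  # extra box matching nothing counts as one error
  spur <- evaluate_against_consensus(ds$annotations$spur, std)
  expect_equal(spur$e, 1L)

  expect_error(evaluate_against_consensus(ds$annotations$E1, std), "panel")
})

test_that("tentative exclusion never increases the error count", {
  set.seed(53)
  panel <- c("E1", "E2", "E3", "E4")
  for (rep in 1:15) {
    spec <- lapply(c(panel, "X"), function(a)
      list(i1 = random_box_matrix(sample(0:5, 1)),
           i2 = random_box_matrix(sample(0:5, 1))))
    names(spec) <- c(panel, "X")
    ds <- make_dataset(spec)
    std <- build_consensus(ds, panel)
    with_sp <- evaluate_against_consensus(ds$annotations$X, std)
    no_sp <- std
    for (img in names(no_sp$per_image)) {
      no_sp$per_image[[img]]$S_prime <- empty_boxes()
      no_sp$per_image[[img]]$s_prime_support <- integer()
    }
    without_sp <- evaluate_against_consensus(ds$annotations$X, no_sp)
    expect_lte(with_sp$e, without_sp$e)
  }
})

test_that("experts are scored only on their own left-out standard", {
  set.seed(61)
  panel <- c("E1", "E2", "E3", "E4")
  spec <- lapply(c(panel, "E0", "M"), function(a)
    list(i1 = random_box_matrix(3), i2 = random_box_matrix(2)))
  names(spec) <- c(panel, "E0", "M")
  ds <- make_dataset(spec)
  ev <- evaluate_all_against_standards(ds, panel)
  res <- ev$results
  for (x in panel) {
    expect_equal(res$standard[res$annotator == x], x)
  }
  for (a in c("E0", "M")) {
    expect_equal(sort(res$standard[res$annotator == a]), sort(panel))
  }
  sm <- ev$summary
  expect_equal(sm$e_avg[sm$annotator == "M"],
               mean(res$e[res$annotator == "M"]))
  tab <- consensus_table(ev)
  expect_true(any(tab == "-"))  # dashes where an expert is excluded
})

test_that("identical annotators produce a zero-error consensus evaluation", {
  b <- list(i1 = boxes(5, 5, 25, 25), i2 = empty_boxes())
  spec <- lapply(1:5, function(i) b)
  names(spec) <- c("E1", "E2", "E3", "E4", "M")
  ds <- make_dataset(spec)
  ev <- evaluate_all_against_standards(ds, c("E1", "E2", "E3", "E4"))
  expect_true(all(ev$summary$e_avg == 0))
})

test_that("reference comparison satisfies the count identities", {
  set.seed(71)
  for (rep in 1:10) {
    spec <- list(a = list(), r = list())
    for (img in c("i1", "i2", "i3")) {
      spec$a[[img]] <- random_box_matrix(sample(0:5, 1))
      spec$r[[img]] <- random_box_matrix(sample(0:5, 1))
    }
    ds <- make_dataset(spec)
    rc <- compare_to_reference(ds, "a", "r")
    expect_equal(rc$e, rc$fp + rc$fn)
    expect_equal(rc$tp + rc$fn,
                 sum(vapply(spec$r, nrow, integer(1))))
    expect_equal(rc$tp + rc$fp,
                 sum(vapply(spec$a, nrow, integer(1))))
    if (!is.na(rc$precision) && !is.na(rc$recall)) {
      expect_equal(rc$f1, f1_score(rc$precision, rc$recall))
    }
  }
  expect_error(compare_to_reference(ds, "a", "a"), "differ")
})

test_that("perfect agreement gives P = R = F1 = 1 and zero classification error", {
  b <- list(i1 = boxes(5, 5, 25, 25))
  ds <- make_dataset(list(a = b, r = b))
  rc <- compare_to_reference(ds, "a", "r")
  expect_equal(rc$precision, 1); expect_equal(rc$recall, 1)
  expect_equal(rc$f1, 1)
  expect_equal(rc$classification_error, 0)
})
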