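# Hard-mask evaluation metrics built on explicit confusion counts.

test_that("confusion tallies and validates", {
  ones <- matrix(1L, 4, 4); zeros <- matrix(0L, 4, 4)
  cc <- confusion(ones, ones)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 16L, tn = 0L, fp = 0L, fn = 0L))
  cc2 <- confusion(ones, zeros)
  expect_equal(cc2$fp, 16)
  expect_equal(cc2$tp + cc2$tn + cc2$fn, 0)
  expect_error(confusion(matrix(0L, 3, 3), zeros), "mismatch")
  expect_error(confusion(matrix(2L, 4, 4), zeros), "labels")
})

test_that("confusion matches a per-pixel counting loop", {
  for (seed in 1:20) {
    pred <- seeded_mask(seed, 8)
    truth <- seeded_mask(seed + 500, 8)
    got <- confusion(pred, truth)
    ref <- oracle_confusion(pred, truth)
    expect_identical(unclass(got)[names(ref)], ref)
    expect_identical(got$tp + got$tn + got$fp + got$fn, 64L)
  }
})

test_that("miou, acc, dice_coef examples and conventions", {
  y <- matrix(0L, 4, 4); y[2:3, 2:3] <- 1L
  perfect <- confusion(y, y)
  expect_equal(miou(perfect), 100)
  expect_equal(acc(perfect), 100)
  expect_equal(dice_coef(perfect), 100)
  wrong <- confusion(matrix(1L, 4, 4), matrix(0L, 4, 4))
  expect_equal(miou(wrong), 0)
  expect_equal(acc(wrong), 0)
  expect_equal(dice_coef(wrong), 0)
  counts <- structure(list(tp = 3, tn = 5, fp = 1, fn = 1),
                      class = "confusion_counts")
  expect_equal(acc(counts), 80)
  counts2 <- structure(list(tp = 4, tn = 0, fp = 2, fn = 2),
                       class = "confusion_counts")
  expect_equal(dice_coef(counts2), 100 * 8 / 12, tolerance = 1e-12)
  # class absent from both masks contributes IoU 1 / Dice 100
  empty <- confusion(matrix(0L, 4, 4), matrix(0L, 4, 4))
  expect_equal(miou(empty), 100)
  expect_equal(dice_coef(empty), 100)
  expect_error(miou(structure(list(tp = 0, tn = 0, fp = 0, fn = 0),
                              class = "confusion_counts")), "zero")
})

test_that("miou matches brute-force per-class set arithmetic", {
  for (seed in 1:20) {
    pred <- seeded_mask(seed + 40, 8)
    truth <- seeded_mask(seed + 900, 8)
    expect_equal(miou(confusion(pred, truth)), oracle_miou(pred, truth),
                 tolerance = 1e-9)
  }
})

test_that("100 - dice_coef equals 100 * unsmoothed hard dice_loss", {
  for (seed in 1:50) {
    pred <- seeded_mask(seed, 8, p = 0.45)
    truth <- seeded_mask(seed + 1000, 8, p = 0.45)
    if (sum(pred) + sum(truth) == 0) next
    dl <- dice_loss(matrix(as.numeric(pred), 8, 8), truth, smooth = 0)
    expect_equal(100 - dice_coef(confusion(pred, truth)), 100 * dl,
                 tolerance = 1e-6)
  }
})

test_that("per-class IoU never exceeds Dice", {
  for (seed in 1:20) {
    pred <- seeded_mask(seed + 7, 8)
    truth <- seeded_mask(seed + 77, 8)
    cc <- confusion(pred, truth)
    if (cc$tp + cc$fp + cc$fn == 0) next
    iou_pos <- cc$tp / (cc$tp + cc$fp + cc$fn)
    dice_pos <- 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
    expect_lte(iou_pos, dice_pos + 1e-12)
  }
})

test_that("metrics are invariant under identical pixel shuffles", {
  set.seed(4)
  pred <- seeded_mask(12, 8); truth <- seeded_mask(13, 8)
  perm <- sample(64)
  pred2 <- matrix(pred[perm], 8, 8)
  truth2 <- matrix(truth[perm], 8, 8)
  a <- confusion(pred, truth); b <- confusion(pred2, truth2)
  expect_equal(miou(a), miou(b))
  expect_equal(acc(a), acc(b))
  expect_equal(dice_coef(a), dice_coef(b))
})

test_that("macro and micro aggregation are both reported and labeled", {
  # construct images where the conventions disagree
  p1 <- matrix(0L, 4, 4); t1 <- matrix(0L, 4, 4); t1[1, 1] <- 1L
  p2 <- matrix(1L, 4, 4); t2 <- matrix(1L, 4, 4)
  rep <- metric_report(list(p1, p2), list(t1, t2))
  expect_identical(rep$aggregate, "macro")
  expect_false(isTRUE(all.equal(rep$macro["dice"], rep$micro["dice"])))
  expect_identical(rep$dice, unname(rep$macro["dice"]))
  rep2 <- metric_report(list(p1, p2), list(t1, t2), aggregate = "micro")
  expect_identical(rep2$dice, unname(rep2$micro["dice"]))
  expect_identical(nrow(rep$per_image), 2L)
})

test_that("metric reports serialize to CSV and JSON", {
  pred <- lapply(1:3, function(i) seeded_mask(i, 6))
  truth <- lapply(1:3, function(i) seeded_mask(i + 5, 6))
  rep <- metric_report(pred, truth)
  csvf <- file.path(tempdir(), "per_image.csv")
  jsf <- file.path(tempdir(), "summary.json")
  write_metric_report(rep, csv_path = csvf, json_path = jsf)
  back <- read.csv(csvf)
  expect_identical(nrow(back), 3L)
  expect_true(all(c("miou", "acc", "dice") %in% names(back)))
  js <- jsonlite::read_json(jsf)
  expect_equal(js$macro$dice, unname(rep$macro["dice"]), tolerance = 1e-9)
  expect_identical(js$aggregate, "macro")
})
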