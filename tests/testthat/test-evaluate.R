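test_that("normalized errors follow the width/height percentage definition", {
  truth <- toy_landmarks()
  expect_equal(sum(normalized_errors(truth, truth)$e_x), 0)
  # 5 px x-shift on a 100 px wide vertebra is a 5% error
  wide <- list(L3 = rect_corners(0, 0, 100, 40))
  pred <- list(L3 = rect_corners(5, 0, 100, 40))
  rec <- normalized_errors(pred, wide)
  expect_equal(rec$e_x, rep(5, 4))
  expect_equal(rec$e_y, rep(0, 4))
  expect_equal(rec$euclid, rep(5, 4))
  expect_equal(rec$width, rep(100, 4))
})

test_that("S1 contributes exactly its two upper-endplate records", {
  truth <- toy_landmarks()["S1"]
  # a prediction offering all four S1 corners still yields 2 records
  pred <- list(S1 = rect_corners(42, 100, 30, 20))
  rec <- normalized_errors(pred, truth)
  expect_identical(nrow(rec), 2L)
  expect_setequal(rec$corner, c("UA", "UP"))
})

test_that("misses produce no error records and lower detection accuracy", {
  truth <- toy_landmarks()
  pred <- truth[c("L1", "L2")]  # L5 and S1 missed
  rec <- normalized_errors(pred, truth)
  expect_setequal(unique(rec$level), c("L1", "L2"))
  acc <- detection_accuracy(pred, truth)
  expect_equal(as.numeric(acc), 0.5)
  expect_setequal(attr(acc, "misses")$level, c("L5", "S1"))
})

test_that("relative errors are invariant to scene translation and scaling", {
  truth <- toy_landmarks()
  pred <- shift_landmarks(truth, 2, -1)
  r0 <- normalized_errors(pred, truth)
  # translate both
  r1 <- normalized_errors(shift_landmarks(pred, 30, 40),
                          shift_landmarks(truth, 30, 40))
  expect_equal(r1$e_x, r0$e_x)
  expect_equal(r1$e_y, r0$e_y)
  # uniform scaling of the whole scene
  scale_lm <- function(lm, f) {
    lapply(lm, function(cs) corner_set(cs$points * f, cs$valid))
  }
  r2 <- normalized_errors(scale_lm(pred, 3), scale_lm(truth, 3))
  expect_equal(r2$e_x, r0$e_x)
  expect_equal(r2$e_y, r0$e_y)
})

test_that("per-level medians agree with a sort-based oracle", {
  expect_equal(median_by_level(data.frame(
    image_id = "a", level = "L1", corner = "UA",
    e_x = c(1, 3), e_y = c(2, 2), euclid = 1, width = 10, height = 10))$median_x, 2)
  set.seed(55)
  e <- runif(101, 0, 20)
  sort_median <- sort(e)[51]
  rec <- data.frame(image_id = "a", level = "L2", corner = "UA",
                    e_x = e, e_y = e, euclid = e, width = 10, height = 10)
  m <- median_by_level(rec)
  expect_equal(m$median_x, sort_median)
  expect_identical(m$n, 101L)
  # single observation: the median is the value itself
  expect_equal(median_by_level(rec[3, ])$median_x, e[3])
})

test_that("the weighted summary collapses level medians by their counts", {
  expect_equal(weighted_median_summary(5, 17), 5)
  expect_equal(weighted_median_summary(c(2, 4), c(1, 3)), 3.5)
  expect_error(weighted_median_summary(numeric(0), numeric(0)), "undefined")
})

test_that("PCK curves count strict hits and never decrease", {
  zero <- data.frame(image_id = "a", level = "L1", corner = "UA",
                     e_x = 0, e_y = 0, euclid = rep(0, 8), width = 50, height = 30)
  expect_true(all(pck_curve(zero)$pck == 1))
  two <- data.frame(image_id = "a", level = "L4", corner = "UA",
                    e_x = 0, e_y = 0, euclid = c(0.04, 0.06) * 80, width = 80,
                    height = 40)
  p5 <- pck_curve(two)
  expect_equal(p5$pck[p5$threshold == 5], 0.5)
  expect_identical(nrow(p5), 20L)
  set.seed(60)
  rnd <- data.frame(image_id = "a", level = "L2", corner = "UA", e_x = 0,
                    e_y = 0, euclid = rexp(200, 1 / 20), width = 30, height = 20)
  curve <- pck_curve(rnd)
  expect_true(all(diff(curve$pck) >= 0))
  expect_true(all(curve$pck >= 0 & curve$pck <= 1))
})

test_that("spurious detections are reported but do not change accuracy", {
  truth <- list(img = toy_landmarks()[c("L1", "L2")])
  pred <- list(img = toy_landmarks())  # L5, S1 are false positives
  acc <- detection_accuracy(pred, truth)
  expect_equal(as.numeric(acc), 1)
  expect_identical(attr(acc, "false_positives"), 2L)
  expect_error(detection_accuracy(list(img = list()), list(img = list())),
               "no truth")
})

test_that("angle agreement reproduces constructed statistics", {
  mk <- function(v) data.frame(L1_L5 = v, L1_S1 = v, SS = v)
  truth <- mk(c(10, 20, 30, 40, 50, 25, 35, 45, 15, 55))
  # perfect agreement
  agg <- angle_agreement(truth, truth)
  expect_equal(agg$median_abs_error, rep(0, 3))
  expect_equal(agg$r_squared, rep(1, 3))
  expect_equal(agg$sd_diff, rep(0, 3))
  # errors 2, 4, 6, 8: half exceed the 5-degree threshold
  t2 <- mk(c(10, 20, 30, 40))
  p2 <- mk(c(12, 24, 36, 48))
  agg2 <- angle_agreement(p2, t2)
  expect_equal(agg2$frac_above_5deg, rep(0.5, 3))
  expect_equal(agg2$median_abs_error, rep(5, 3))
  # constant +3 degree bias: Bland-Altman mean 3, SD 0, perfect correlation
  p3 <- mk(truth$L1_L5 + 3)
  agg3 <- angle_agreement(p3, truth)
  expect_equal(agg3$bland_altman_mean, rep(3, 3))
  expect_equal(agg3$sd_diff, rep(0, 3))
  expect_equal(agg3$r_squared, rep(1, 3))
  expect_equal(agg3$ba_lower, rep(3, 3))
  # too few pairs: statistics flagged unavailable
  few <- angle_agreement(mk(c(1, 2)), mk(c(2, 3)))
  expect_true(all(is.na(few$r_squared)))
  expect_equal(few$median_abs_error, rep(1, 3))
})

test_that("the full report ties the metrics together", {
  truth <- list(a = toy_landmarks(), b = toy_landmarks())
  pred <- list(a = shift_landmarks(toy_landmarks(), 1.5, 0.6),
               b = toy_landmarks()[c("L1", "L2", "L5")])
  rep <- evaluate_landmarks(pred, truth)
  expect_s3_class(rep, "eval_report")
  expect_equal(as.numeric(rep$detection_accuracy), 7 / 8)
  expect_true(rep$weighted_median_x >= min(rep$per_level$median_x) - 1e-12 &&
                rep$weighted_median_x <= max(rep$per_level$median_x) + 1e-12)
  expect_true(all(rep$pck$pck >= 0 & rep$pck$pck <= 1))
})

test_that("the shipped reference table matches its published structure", {
  tab <- reference_median_errors()
  expect_identical(tab$level, c("T9", "T10", "T11", "T12", "L1", "L2", "L3",
                                "L4", "L5", "S1"))
  expect_identical(tab$n[tab$level == "T9"], 15L)
  expect_true(all(tab$median_x_step2[tab$level %in% c("T10", "T12", "L1", "L2",
                                                      "L4", "L5", "S1")] <
                    tab$median_x_step1[tab$level %in% c("T10", "T12", "L1", "L2",
                                                        "L4", "L5", "S1")]))
})
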