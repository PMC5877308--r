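make_pairs <- function(ref, pred) data.frame(reference = ref, prediction = pred,
                                             stringsAsFactors = FALSE)

test_that("the cross tabulation matches a brute-force tally and rejects idle references", {
  perfect <- make_pairs(rep(reference_labels(), 4), rep(reference_labels(), 4))
  ct <- cross_tab(perfect)
  expect_equal(sum(ct), 12L)
  expect_equal(sum(diag(ct[, 1:3])), 12L)

  # idle predictions are tallied in the reference row's idle column
  ct2 <- cross_tab(make_pairs("walking", "idle"))
  expect_equal(ct2["walking", "idle"], 1L)
  expect_equal(sum(ct2), 1L)

  expect_error(cross_tab(make_pairs("idle", "sitting")), "invalid reference")

  set.seed(5)
  for (i in 1:25) {
    n <- sample(1:200, 1)
    ref <- sample(reference_labels(), n, TRUE)
    pred <- sample(activity_labels(), n, TRUE)
    expect_equal(unclass(cross_tab(make_pairs(ref, pred))),
                 unclass(oracle_tally(ref, pred)), ignore_attr = TRUE)
  }
})

test_that("cross_tab restricted to windows only counts epochs inside them", {
  start <- grid_time(seq(0, by = 30, length.out = 10))
  pairs <- data.frame(start = start, reference = rep("sitting", 10),
                      prediction = rep(c("sitting", "walking"), 5))
  p <- lab_protocol("part1", data.frame(activity = "sitting", planned_seconds = 180),
                    start = grid_time(0))
  w <- windows_part1(p)  # [60, 120): epochs 3 and 4
  ct <- cross_tab(pairs, windows = w)
  expect_equal(sum(ct), 2L)
})

test_that("one-vs-rest counts satisfy the marginal identities", {
  set.seed(9)
  for (i in 1:25) {
    m <- matrix(sample(0:30, 12, TRUE), 3, 4,
                dimnames = list(reference_labels(), activity_labels()))
    ct <- postureval:::as_cross_tab(m)
    for (a in reference_labels()) {
      cc <- one_vs_rest(ct, a)
      expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, sum(m))
      expect_equal(cc$TP, m[a, a])
      expect_equal(cc$TP + cc$FN, sum(m[a, ]))   # row: reference positives
      expect_equal(cc$TP + cc$FP, sum(m[, a]))   # column: detections
    }
    # each epoch has exactly one reference label
    tot <- sum(vapply(reference_labels(),
                      function(a) { cc <- one_vs_rest(ct, a); cc$TP + cc$FN },
                      numeric(1)))
    expect_equal(tot, sum(m))
  }
})

test_that("performance values follow the four formulas with NA for empty denominators", {
  pv <- performance(list(TP = 1, FN = 1, FP = 0, TN = 2))
  expect_equal(unname(pv["sensitivity"]), 50)
  expect_equal(unname(pv["specificity"]), 100)
  expect_equal(unname(pv["ppr"]), 100)
  expect_equal(report_round(unname(pv["npr"])), 66.7)

  degenerate <- performance(list(TP = 0, FN = 0, FP = 2, TN = 3))
  expect_true(is.na(degenerate[["sensitivity"]]))
  expect_false(is.na(degenerate[["specificity"]]))
  expect_true(is.na(performance(list(TP = 0, FN = 1, FP = 0, TN = 0))[["ppr"]]))

  set.seed(13)
  for (i in 1:50) {
    cc <- as.list(stats::setNames(sample(0:40, 4, TRUE), c("TP", "FP", "FN", "TN")))
    pv <- performance(cc)
    direct <- c(100 * cc$TP / (cc$TP + cc$FN), 100 * cc$TN / (cc$TN + cc$FP),
                100 * cc$TP / (cc$TP + cc$FP), 100 * cc$TN / (cc$TN + cc$FN))
    direct[!is.finite(direct)] <- NA_real_
    expect_equal(unname(pv), direct)
  }
})

test_that("performance is invariant under permutation of the non-target labels", {
  m <- matrix(c(40, 5, 3, 2,
                7, 30, 6, 1,
                2, 4, 25, 3), 3, 4, byrow = TRUE,
              dimnames = list(reference_labels(), activity_labels()))
  ct <- postureval:::as_cross_tab(m)
  base <- performance(one_vs_rest(ct, "sitting"))
  # swap standing and walking in both margins
  perm <- m[c(1, 3, 2), c(1, 3, 2, 4)]
  ct_p <- postureval:::as_cross_tab(perm)
  expect_equal(performance(one_vs_rest(ct_p, "sitting")), base)
})

test_that("misdetection decomposition splits false positives by actual activity", {
  m <- matrix(0L, 3, 4, dimnames = list(reference_labels(), activity_labels()))
  diag(m[, 1:3]) <- c(50L, 40L, 30L)
  m["standing", "sitting"] <- 6L   # standing misdetected as sitting
  m["walking", "sitting"] <- 7L
  m["standing", "walking"] <- 4L   # all walking FPs are actual standing
  prof <- misdetection_decomposition(postureval:::as_cross_tab(m))
  expect_equal(report_round(prof$split["standing", "sitting"]), 46.2)
  expect_equal(report_round(prof$split["walking", "sitting"]), 53.8)
  expect_equal(prof$split["standing", "walking"], 100)
  # standing column has no FPs -> undefined split
  expect_true(all(is.na(prof$split[, "standing"])))
  # PPRs agree with one_vs_rest + performance
  expect_equal(prof$ppr[["sitting"]],
               performance(one_vs_rest(postureval:::as_cross_tab(m), "sitting"))[["ppr"]])

  diag_only <- matrix(0L, 3, 4, dimnames = dimnames(m))
  diag(diag_only[, 1:3]) <- 10L
  expect_true(all(is.na(misdetection_decomposition(
    postureval:::as_cross_tab(diag_only))$split)))
})

test_that("sensitivity decomposition splits false negatives by wrong prediction", {
  m <- matrix(0L, 3, 4, dimnames = list(reference_labels(), activity_labels()))
  diag(m[, 1:3]) <- c(100L, 80L, 60L)
  m["sitting", "standing"] <- 13L
  m["sitting", "walking"] <- 5L
  m["walking", "standing"] <- 2L
  m["walking", "idle"] <- 1L
  sd <- sensitivity_decomposition(postureval:::as_cross_tab(m))
  expect_equal(report_round(sd["sitting", "standing"]), 72.2)
  expect_equal(report_round(sd["sitting", "walking"]), 27.8)
  # walking misses split across standing and idle
  expect_equal(report_round(sd["walking", "standing"]), 66.7)
  expect_equal(report_round(sd["walking", "idle"]), 33.3)
  expect_true(all(is.na(sd["standing", ])))
})

test_that("pooled reports sum counts across parts rather than averaging percentages", {
  m1 <- matrix(c(9L, 1L, 0L, 0L,
                 0L, 10L, 0L, 0L,
                 0L, 0L, 10L, 0L), 3, 4, byrow = TRUE,
               dimnames = list(reference_labels(), activity_labels()))
  m2 <- matrix(c(90L, 0L, 0L, 0L,
                 0L, 80L, 10L, 0L,
                 0L, 0L, 100L, 0L), 3, 4, byrow = TRUE,
               dimnames = list(reference_labels(), activity_labels()))
  ct1 <- postureval:::as_cross_tab(m1); ct2 <- postureval:::as_cross_tab(m2)

  single <- pooled_report(list(part1 = ct1))
  expect_equal(unique(single$part), "part1")
  expect_equal(single$value[single$activity == "sitting" & single$metric == "sensitivity"],
               90)

  rep2 <- pooled_report(list(part1 = ct1, part2 = ct2))
  pooled_sens <- rep2$value[rep2$part == "all" & rep2$activity == "sitting" &
                              rep2$metric == "sensitivity"]
  # 99/100 pooled, not mean(90, 100)
  expect_equal(pooled_sens, 99)
  expect_equal(nrow(rep2), 3 * 3 * 4)
})

test_that("reporting rounds one decimal half away from zero", {
  expect_equal(report_round(85.65), 85.7)
  expect_equal(report_round(85.7499), 85.7)
  expect_equal(report_round(97.25), 97.3)
  expect_equal(report_round(-1.25), -1.3)
  expect_equal(report_round(14.949, 1), 14.9)
})
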