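test_that("dominance reduction picks the longest activity, ties go by priority", {
  w <- c(rep("sitting", 8), rep("standing", 11), rep("walking", 11))
  expect_equal(as.character(reduce_seconds_to_epoch(w)), "standing")
  expect_true(attr(reduce_seconds_to_epoch(w), "ambivalent"))

  three_way <- rep(c("sitting", "standing", "walking"), each = 10)
  expect_equal(as.character(reduce_seconds_to_epoch(three_way)), "sitting")

  expect_equal(as.character(reduce_seconds_to_epoch(rep("sitting", 30))), "sitting")
  expect_false(attr(reduce_seconds_to_epoch(rep("sitting", 30)), "ambivalent"))

  expect_error(reduce_seconds_to_epoch(rep("sitting", 29)), "malformed window")
  expect_error(reduce_seconds_to_epoch(c(rep("sitting", 29), "hopping")),
               "unknown activity label")
})

test_that("idle wins only by strict majority over every activity and loses ties", {
  expect_equal(as.character(reduce_seconds_to_epoch(rep("off", 30))), "idle")
  # 11 off vs 10 best activity: strict majority
  w <- c(rep("off", 11), rep("walking", 10), rep("sitting", 9))
  expect_equal(as.character(reduce_seconds_to_epoch(w)), "idle")
  # 15 off ties 15 walking: activity wins
  w <- c(rep("off", 15), rep("walking", 15))
  expect_equal(as.character(reduce_seconds_to_epoch(w)), "walking")
})

test_that("reduction is permutation-invariant and dominant against the oracle", {
  set.seed(42)
  for (i in 1:300) {
    w <- sample(second_labels(), 30, replace = TRUE)
    got <- as.character(reduce_seconds_to_epoch(w))
    expect_equal(got, oracle_reduce(w))
    expect_equal(as.character(reduce_seconds_to_epoch(sample(w))), got)
    if (got != "idle") {
      cnt <- vapply(reference_labels(), function(l) sum(w == l), integer(1))
      expect_true(all(cnt[got] >= cnt))
    }
  }
})

test_that("stream reduction emits only fully covered epochs", {
  st <- second_stream(grid_time(0:59), rep("standing", 60))
  red <- reduce_stream(st)
  expect_equal(nrow(red), 2L)
  expect_equal(unique(red$label), "standing")

  # trailing 15 s dropped
  st45 <- second_stream(grid_time(0:44), rep("sitting", 45))
  expect_equal(nrow(reduce_stream(st45)), 1L)

  # unaligned start: leading partial epoch dropped too
  st_off <- second_stream(grid_time(10:69), rep("walking", 60))
  expect_equal(nrow(reduce_stream(st_off)), 1L)

  # an interior one-second gap voids that epoch
  tt <- grid_time(c(0:28, 30:89))
  stg <- second_stream(tt, rep("sitting", length(tt)))
  expect_equal(nrow(reduce_stream(stg)), 2L)

  empty <- second_stream(as.POSIXct(character(), tz = "UTC"), character())
  expect_equal(nrow(reduce_stream(empty)), 0L)
})

test_that("stream reduction is idempotent on epoch-constant streams and compositional", {
  set.seed(7)
  # epoch-constant stream returns exactly those labels
  labs <- sample(reference_labels(), 40, replace = TRUE)
  st <- second_stream(grid_time(0:(40 * 30 - 1)), rep(labs, each = 30))
  expect_equal(reduce_stream(st)$label, labs)

  # mixed stream equals window-wise reduction
  per_sec <- sample(second_labels(), 50 * 30, replace = TRUE)
  st <- second_stream(grid_time(seq_along(per_sec) - 1), per_sec)
  red <- reduce_stream(st)
  oracle <- vapply(split(per_sec, rep(1:50, each = 30)),
                   function(w) as.character(reduce_seconds_to_epoch(w)),
                   character(1))
  expect_equal(unname(red$label), unname(oracle))
})

test_that("ambivalent epochs are counted and reported as a percentage", {
  unanimous <- second_stream(grid_time(0:119), rep("sitting", 120))
  expect_equal(count_ambivalent(unanimous),
               list(count = 0L, total = 4L, percent = 0))

  # one 15/15 tie among 4 epochs
  labs <- c(rep("sitting", 15), rep("standing", 15), rep("walking", 90))
  one_tie <- second_stream(grid_time(0:119), labs)
  res <- count_ambivalent(one_tie)
  expect_equal(res$count, 1L)
  expect_equal(res$percent, 25)

  # 13 tied epochs among 1789 -> 0.73%
  n <- 1789L
  labs <- rep(rep("walking", 30), n)
  labs <- matrix(labs, nrow = 30)
  labs[1:15, 1:13] <- "sitting"
  labs[16:30, 1:13] <- "standing"
  big <- second_stream(grid_time(0:(30 * n - 1)), as.vector(labs))
  res <- count_ambivalent(big)
  expect_equal(res$count, 13L)
  expect_equal(res$total, 1789L)
  expect_equal(report_round(res$percent, 2), 0.73)
})

test_that("merging keeps exactly the epochs both sources registered", {
  a <- epoch_series(grid_time(seq(0, by = 30, length.out = 10)),
                    rep("sitting", 10), source = "A")
  b <- epoch_series(grid_time(seq(60, by = 30, length.out = 8)),
                    rep("standing", 8), source = "B")
  m <- align_and_merge(a, b)
  expect_equal(nrow(m), 8L)
  expect_equal(attr(m, "drop_report"), list(a_only = 2L, b_only = 0L))

  ident <- align_and_merge(a, a)
  expect_equal(nrow(ident), 10L)

  # random gap patterns: merged starts equal set intersection, symmetric
  set.seed(11)
  for (i in 1:20) {
    sa <- sort(sample(0:60, sample(5:40, 1))) * 30
    sb <- sort(sample(0:60, sample(5:40, 1))) * 30
    ea <- epoch_series(grid_time(sa), rep("walking", length(sa)))
    eb <- epoch_series(grid_time(sb), rep("sitting", length(sb)))
    m_ab <- align_and_merge(ea, eb)
    expect_equal(as.numeric(m_ab$start),
                 as.numeric(grid_time(0)) + sort(intersect(sa, sb)))
    expect_equal(as.numeric(m_ab$start), as.numeric(align_and_merge(eb, ea)$start))
  }
})

test_that("wear filter retains exactly-5-h days and drops shorter ones", {
  day_epochs <- function(day, n) grid_time(86400 * day + seq(0, by = 30, length.out = n))
  # day 0: 600 epochs = 300 min (kept, boundary); day 1: 599 epochs = 299.5 min
  starts <- c(day_epochs(0, 600), day_epochs(1, 599))
  es <- epoch_series(starts, rep("sitting", 1199))
  m <- align_and_merge(es, es)
  wf <- wear_filter(m)
  expect_equal(wf$days$wear_minutes, c(300, 299.5))
  expect_equal(wf$days$retained, c(TRUE, FALSE))
  expect_equal(nrow(wf$retained), 600L)

  # a typical full wearing day of 774 min is retained
  long_day <- epoch_series(day_epochs(3, 774 * 2), rep("standing", 1548))
  wf2 <- wear_filter(align_and_merge(long_day, long_day))
  expect_true(all(wf2$days$retained))

  # timezone offset moves epochs across the local midnight
  near_mid <- epoch_series(day_epochs(0, 10) + 86370, rep("sitting", 10))
  mm <- align_and_merge(near_mid, near_mid)
  d_utc <- wear_filter(mm, min_wear_minutes = 0)$days
  d_shift <- wear_filter(mm, min_wear_minutes = 0, tz_offset_minutes = -60)$days
  expect_equal(nrow(d_utc), 2L)
  expect_equal(nrow(d_shift), 1L)
})

test_that("series constructors enforce grid, ordering and label invariants", {
  expect_error(epoch_series(grid_time(c(0, 10)), c("sitting", "sitting")), "grid")
  expect_error(epoch_series(grid_time(c(0, 0)), c("sitting", "sitting")), "duplicate")
  expect_error(epoch_series(grid_time(c(30, 0)), c("sitting", "sitting")), "increasing")
  expect_error(second_stream(grid_time(c(0, 0)), c("off", "off")), "increasing")
  expect_error(second_stream(grid_time(0), "unknownlabel"), "unknown activity label")
  # case-insensitive ingest
  es <- epoch_series(grid_time(0), "Sitting")
  expect_equal(es$label, "sitting")
  expect_error(align_and_merge(es, epoch_series(grid_time(0), "idle", subject_id = "other")),
               "different subjects")
})
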