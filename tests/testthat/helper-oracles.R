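# Independent brute-force oracles and shared fixture builders.

# Sequential count-and-compare reduction oracle: the highest-count activity
# wins, earlier activities keep ties (a later label must be strictly
# greater); "off" must strictly beat the best activity to yield idle.
oracle_reduce <- function(labels) {
  cnt <- vapply(c("sitting", "standing", "walking", "off"),
                function(l) sum(labels == l), integer(1))
  best <- "sitting"
  if (cnt[["standing"]] > cnt[[best]]) best <- "standing"
  if (cnt[["walking"]] > cnt[[best]]) best <- "walking"
  if (cnt[["off"]] > cnt[[best]]) "idle" else best
}

# Nested-loop contingency tally oracle.
oracle_tally <- function(ref, pred) {
  m <- matrix(0L, 3, 4, dimnames = list(reference_labels(), activity_labels()))
  for (i in seq_along(ref)) {
    m[ref[i], pred[i]] <- m[ref[i], pred[i]] + 1L
  }
  m
}

# The published ActiGraph sub-study misallocation profile (PPRs and
# false-positive splits per detected activity).
substudy_profile <- function() {
  acts <- reference_labels()
  split <- matrix(NA_real_, 3, 3, dimnames = list(acts, acts))
  split["standing", "sitting"] <- 46.2
  split["walking", "sitting"] <- 53.8
  split["sitting", "standing"] <- 33.3
  split["walking", "standing"] <- 66.6
  split["sitting", "walking"] <- 0
  split["standing", "walking"] <- 100
  misallocation_profile(c(sitting = 88.7, standing = 84.6, walking = 98.8),
                        split)
}

# A plausible thigh-worn-device confusion matrix used across simulation
# tests (rows: true sitting/standing/walking/idle; idle truth never occurs
# in simulated wear time but the row must be stochastic).
test_confusion <- function() {
  m <- rbind(c(.887, .080, .033, 0),
             c(.120, .846, .034, 0),
             c(.010, .050, .930, .010),
             c(0, 0, 0, 1))
  dimnames(m) <- list(activity_labels(), activity_labels())
  m
}

grid_time <- function(s) as.POSIXct("2018-01-01 00:00:00", tz = "UTC") + s

# Pool merged truth/device epoch pairs over several simulated days.
pool_days <- function(bm, em, day_seeds, wear_minutes = 774) {
  ref <- character(0); pred <- character(0)
  for (s in day_seeds) {
    day <- simulate_free_living_day(bm, wear_minutes = wear_minutes, seed = s)
    truth <- reduce_stream(day)
    dev <- observe_with_device(day, em, seed = s + 50000L)
    m <- align_and_merge(truth, dev)
    ref <- c(ref, m$label_a); pred <- c(pred, m$label_b)
  }
  data.frame(reference = ref, prediction = pred, stringsAsFactors = FALSE)
}
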