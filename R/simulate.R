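#' Bout model for free-living activity simulation
#'
#' Free-living truth is generated as alternating bouts: a maximal run of one
#' activity whose duration is drawn from a per-activity distribution. The
#' defaults use lognormal durations — heavy-tailed sitting bouts are the
#' stylized fact in sedentary-behavior research — with mean bouts of 20, 8
#' and 3 min for sitting, standing and walking, and a stationary mix of
#' 57 / 28 / 15% of wear time, the neighborhood of typical adult
#' free-living days.
#'
#' @param shares named target shares of wear time (sum to 1).
#' @param mean_bout_seconds named mean bout durations (> 0).
#' @param family `"lognormal"` or `"exponential"`.
#' @param sdlog lognormal dispersion on the log scale (ignored for
#'   exponential).
#' @return an object of class `bout_model`.
#' @export
bout_model <- function(shares = c(sitting = 0.57, standing = 0.28, walking = 0.15),
                       mean_bout_seconds = c(sitting = 1200, standing = 480,
                                             walking = 180),
                       family = c("lognormal", "exponential"), sdlog = 0.8) {
  family <- match.arg(family)
  acts <- reference_labels()
  stopifnot(all(acts %in% names(shares)), all(acts %in% names(mean_bout_seconds)))
  shares <- as.numeric(shares[acts]); names(shares) <- acts
  mb <- as.numeric(mean_bout_seconds[acts]); names(mb) <- acts
  stopifnot(abs(sum(shares) - 1) < 1e-8, all(shares >= 0), all(mb > 0))
  structure(list(shares = shares, mean_bout_seconds = mb, family = family,
                 sdlog = sdlog), class = "bout_model")
}

#' Device error model for simulated observation
#'
#' @param confusion 4 x 4 row-stochastic matrix `C[true, reported]` over
#'   sitting / standing / walking / idle: the probability an epoch truly in
#'   the row label is reported as the column label. Defaults to identity.
#' @param transition_blur probability that an epoch overlapping a truth
#'   change is misreported (uniformly as one of the other two activities).
#'   Transitions are where posture classifiers degrade most; the default of
#'   0.5 is a deliberately harsh stress setting — pass 0 for an error-free
#'   device.
#' @param dropout probability an epoch goes unregistered (technical lapse).
#' @return an object of class `device_error_model`.
#' @export
device_error_model <- function(confusion = diag(4), transition_blur = 0.5,
                               dropout = 0) {
  stopifnot(is.matrix(confusion), all(dim(confusion) == c(4, 4)),
            all(confusion >= 0),
            all(abs(rowSums(confusion) - 1) < 1e-8),
            transition_blur >= 0, transition_blur <= 1,
            dropout >= 0, dropout <= 1)
  dimnames(confusion) <- list(true = activity_labels(),
                              reported = activity_labels())
  structure(list(confusion = confusion, transition_blur = transition_blur,
                 dropout = dropout), class = "device_error_model")
}

draw_bout_seconds <- function(bm, activity, rng) {
  mean_s <- bm$mean_bout_seconds[[activity]]
  d <- if (bm$family == "exponential") {
    rng$rexp(1, rate = 1 / mean_s)
  } else {
    # meanlog chosen so the lognormal mean equals mean_s
    rng$rlnorm(1, meanlog = log(mean_s) - bm$sdlog^2 / 2, sdlog = bm$sdlog)
  }
  max(1L, as.integer(round(d)))
}

draw_residual_bout_seconds <- function(bm, activity, rng) {
  # residual life of the bout in progress at a stationary time point:
  # a uniform fraction of a length-biased duration (for the lognormal the
  # length-biased law is lognormal with meanlog shifted by sdlog^2; the
  # exponential is memoryless)
  mean_s <- bm$mean_bout_seconds[[activity]]
  d <- if (bm$family == "exponential") {
    rng$rexp(1, rate = 1 / mean_s)
  } else {
    lb <- rng$rlnorm(1, meanlog = log(mean_s) + bm$sdlog^2 / 2, sdlog = bm$sdlog)
    rng$runif(1) * lb
  }
  max(1L, as.integer(round(d)))
}

bout_transition_matrix <- function(bm) {
  # Bout types form a 3-state chain with no self-transitions. The target
  # bout-type frequencies are q_i proportional to share_i / mean_bout_i
  # (time shares are q_i * mean_i). A reversible chain with stationary q has
  # pairwise flows f_ij solving f_12 + f_13 = q_1 etc.; all flows are
  # nonnegative iff every q_i <= 1/2 (a no-repeat sequence cannot exceed
  # half its bouts in one type). Infeasible targets are clamped to the
  # nearest feasible chain.
  acts <- reference_labels()
  q <- bm$shares / bm$mean_bout_seconds
  if (sum(q) == 0) q <- rep(1, 3)
  q <- q / sum(q)
  f <- matrix(0, 3, 3, dimnames = list(acts, acts))
  f[1, 2] <- f[2, 1] <- (q[1] + q[2] - q[3]) / 2
  f[1, 3] <- f[3, 1] <- (q[1] + q[3] - q[2]) / 2
  f[2, 3] <- f[3, 2] <- (q[2] + q[3] - q[1]) / 2
  f[f < 0] <- 0
  P <- f / rowSums(f)
  P[is.nan(P)] <- 0
  list(q = stats::setNames(as.numeric(q), acts), P = P)
}

#' Simulate a free-living truth day
#'
#' Bouts alternate between activities along a reversible three-state chain
#' whose stationary bout-type frequencies are chosen so the long-run *time*
#' shares equal the model's target mix (exactly, for any mix in which no
#' activity would need more than half of all bouts). The stream is
#' truncated to exactly `wear_minutes`.
#'
#' @param bm a `bout_model`.
#' @param wear_minutes simulated wear time (> 0; default 774, a typical
#'   matched wearing day).
#' @param seed integer seed; the stream is identical for identical seeds.
#' @param start first second of the day (UTC, on the 30-s grid).
#' @param subject_id subject identifier.
#' @return a `second_stream` of truth labels.
#' @export
simulate_free_living_day <- function(bm, wear_minutes = 774, seed = 1,
                                     start = as.POSIXct("2018-03-05 08:00:00", tz = "UTC"),
                                     subject_id = "sim") {
  stopifnot(inherits(bm, "bout_model"), wear_minutes > 0)
  rng <- local_rng(seed)
  total <- as.integer(round(wear_minutes * 60))
  acts <- reference_labels()
  if (any(bm$shares == 1)) {
    cur <- acts[bm$shares == 1]
    labels <- rep(cur, total)
    t0 <- as.numeric(as_utc(start))
    return(second_stream(as.POSIXct(t0 + seq_len(total) - 1,
                                    origin = "1970-01-01", tz = "UTC"),
                         labels, subject_id = subject_id, source = "truth"))
  }
  chain <- bout_transition_matrix(bm)
  # time-stationary start: the day begins mid-bout, in an activity drawn by
  # time share, with only the bout's residual life remaining — this keeps
  # windowed time shares unbiased despite truncation at both ends
  cur <- acts[rng$sample(3, 1, prob = bm$shares)]
  labels <- rep(cur, draw_residual_bout_seconds(bm, cur, rng))
  p0 <- chain$P[cur, ]
  if (all(p0 == 0)) p0 <- as.numeric(acts != cur)
  cur <- acts[rng$sample(3, 1, prob = p0)]
  while (length(labels) < total) {
    len <- draw_bout_seconds(bm, cur, rng)
    labels <- c(labels, rep(cur, len))
    p <- chain$P[cur, ]
    if (all(p == 0)) p <- as.numeric(acts != cur)  # isolated state: leave uniformly
    cur <- acts[rng$sample(3, 1, prob = p)]
  }
  labels <- labels[seq_len(total)]
  t0 <- as.numeric(as_utc(start))
  second_stream(as.POSIXct(t0 + seq_len(total) - 1, origin = "1970-01-01", tz = "UTC"),
                labels, subject_id = subject_id, source = "truth")
}

#' Simulate the truth stream of a laboratory session
#'
#' Truth follows the protocol's segment activities; at each posture change
#' the old posture persists for a uniform 0..`transition_seconds` into the
#' new segment (posture changes complete within at most 5 s of the planned
#' boundary). For part 3, the change happens within the 30-s transition
#' allotment at the start of each cycle.
#'
#' @param p a `lab_protocol`.
#' @param transition_seconds maximum seconds a posture change may lag the
#'   segment boundary (0..5).
#' @param seed integer seed.
#' @param subject_id subject identifier.
#' @return a `second_stream` covering the whole protocol span.
#' @export
simulate_lab_session <- function(p, transition_seconds = 5, seed = 1,
                                 subject_id = "sim") {
  stopifnot(inherits(p, "lab_protocol"),
            transition_seconds >= 0, transition_seconds <= 5)
  rng <- local_rng(seed)
  b <- segment_bounds(p)
  secs <- seq(min(b$start), max(b$end) - 1)
  idx <- findInterval(secs, b$start)
  labels <- p$segments$activity[idx]
  # lag each true posture change by a uniform 0..transition_seconds
  if (nrow(b) > 1L && transition_seconds > 0) {
    for (i in 2:nrow(b)) {
      if (p$segments$activity[i] != p$segments$activity[i - 1L]) {
        lag <- rng$sample(transition_seconds + 1L, 1L) - 1L
        if (lag > 0) {
          j <- which(secs >= b$start[i] & secs < b$start[i] + lag)
          labels[j] <- p$segments$activity[i - 1L]
        }
      }
    }
  }
  second_stream(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"), labels,
                subject_id = subject_id, source = "truth")
}

#' Observe a truth stream through an imperfect device
#'
#' Reduces the truth to the 30-s grid, then corrupts each epoch through the
#' error model: epochs overlapping a truth change are misreported with
#' probability `transition_blur`; all epochs are then passed through the
#' confusion matrix `C[true, reported]`; finally each epoch is dropped with
#' probability `dropout` (unregistered periods).
#'
#' @param truth a `second_stream` covering at least one full grid epoch.
#' @param em a `device_error_model`.
#' @param seed integer seed.
#' @param source device name recorded on the output.
#' @return an `epoch_series` of reported labels.
#' @export
observe_with_device <- function(truth, em, seed = 1, source = "device") {
  stopifnot(inherits(truth, "second_stream"), inherits(em, "device_error_model"))
  reduced <- reduce_stream(truth)
  n <- nrow(reduced)
  if (n == 0L) stop("truth stream covers no full grid epoch", call. = FALSE)
  rng <- local_rng(seed)
  # epochs overlapping a truth change: >1 distinct label among their seconds
  ep <- as.numeric(floor_to_grid(truth$time))
  n_lab <- vapply(split(truth$label, ep), function(x) length(unique(x)), integer(1))
  changing <- as.numeric(names(n_lab)[n_lab > 1L])
  is_changing <- as.numeric(reduced$start) %in% changing
  labs <- reduced$label
  acts <- reference_labels()
  blur_at <- which(is_changing & labs %in% acts)
  if (em$transition_blur > 0 && length(blur_at) > 0L) {
    hit <- blur_at[rng$runif(length(blur_at)) < em$transition_blur]
    if (length(hit) > 0L) {
      pick <- rng$sample(2, length(hit), replace = TRUE)
      labs[hit] <- vapply(seq_along(hit),
                          function(k) setdiff(acts, labs[hit[k]])[pick[k]],
                          character(1))
    }
  }
  # one inverse-CDF draw per epoch against the label's confusion row
  cum <- t(apply(em$confusion, 1, cumsum))
  u <- rng$runif(n)
  col <- rowSums(u > cum[match(labs, activity_labels()), , drop = FALSE]) + 1L
  labs <- activity_labels()[col]
  keep <- rng$runif(n) >= em$dropout
  epoch_series(reduced$start[keep], labs[keep],
               subject_id = attr(truth, "subject_id"), source = source)
}

expected_cross_tab_probs <- function(truth_epoch_mix, em) {
  # P[a, d] = pi_a * C[a, d]; transition blur ignored (expectation for
  # steady-state epochs)
  acts <- reference_labels()
  pi_a <- truth_epoch_mix[acts] / sum(truth_epoch_mix[acts])
  p <- em$confusion[acts, , drop = FALSE] * as.numeric(pi_a)
  dimnames(p) <- list(reference = acts, prediction = activity_labels())
  p
}

#' Performance values implied by an error model and a truth mix
#'
#' Closed-form expectation of sensitivity / specificity / PPR / NPR per
#' activity for a device whose epochs are independently confused by
#' `C[true, reported]` while the truth occupies the given epoch mix.
#'
#' @param truth_epoch_mix named nonnegative weights over the three reference
#'   activities (normalized internally).
#' @param em a `device_error_model`.
#' @return matrix `[activity, metric]` of implied percentages.
#' @export
implied_performance <- function(truth_epoch_mix, em) {
  p <- expected_cross_tab_probs(truth_epoch_mix, em)
  acts <- reference_labels()
  out <- matrix(NA_real_, 3, 4,
                dimnames = list(acts, c("sensitivity", "specificity", "ppr", "npr")))
  for (a in acts) {
    tp <- p[a, a]; fn <- sum(p[a, ]) - tp
    fp <- sum(p[, a]) - tp; tn <- 1 - tp - fn - fp
    out[a, ] <- 100 * c(tp / (tp + fn), tn / (tn + fp), tp / (tp + fp),
                        tn / (tn + fn))
  }
  out
}

#' Build a fully wired validation scenario
#'
#' Generates truth (a lab session or a free-living day), observes it through
#' two independent device error models (a criterion and a test device), and
#' returns the session together with the analytically expected
#' reference-by-prediction probabilities under the criterion device's error
#' model. Provenance (seed and configuration digest) travels with the
#' fixture.
#'
#' @param scenario `"lab_part1"`, `"lab_part2"`, `"lab_part3"` or
#'   `"free_living"`.
#' @param seed integer seed; device and protocol seeds are derived from it.
#' @param em_criterion,em_test `device_error_model`s for the two devices.
#' @param bm `bout_model` for free-living truth.
#' @param wear_minutes free-living wear time.
#' @return list of class `sim_session`: `truth`, `device_criterion`,
#'   `device_test`, `protocol` (lab scenarios), `windows` (lab scenarios),
#'   `expected_probs`, `provenance`.
#' @export
make_validation_fixture <- function(scenario = c("lab_part1", "lab_part2",
                                                 "lab_part3", "free_living"),
                                    seed = 1,
                                    em_criterion = device_error_model(),
                                    em_test = device_error_model(),
                                    bm = bout_model(), wear_minutes = 774) {
  scenario <- match.arg(scenario)
  rng <- local_rng(seed)
  sub_seeds <- rng$derive(4)
  protocol <- NULL; windows <- NULL
  if (scenario == "free_living") {
    truth <- simulate_free_living_day(bm, wear_minutes, seed = sub_seeds[1])
    mix <- table(factor(reduce_stream(truth)$label, levels = reference_labels()))
  } else {
    part <- sub("lab_", "", scenario)
    protocol <- randomize_protocol(part, seed = sub_seeds[2])
    truth <- simulate_lab_session(protocol, transition_seconds = 5,
                                  seed = sub_seeds[1])
    windows <- switch(part,
                      part1 = windows_part1(protocol),
                      part2 = windows_part2(protocol, include_transitions = FALSE),
                      part3 = windows_part3(protocol))
    mix <- table(factor(protocol_to_reference(protocol, windows)$label,
                        levels = reference_labels()))
  }
  dev_a <- observe_with_device(truth, em_criterion, seed = sub_seeds[3],
                               source = "criterion")
  dev_b <- observe_with_device(truth, em_test, seed = sub_seeds[4],
                               source = "test")
  structure(list(
    truth = truth, device_criterion = dev_a, device_test = dev_b,
    protocol = protocol, windows = windows,
    expected_probs = expected_cross_tab_probs(
      stats::setNames(as.numeric(mix), reference_labels()), em_criterion),
    provenance = list(seed = seed, scenario = scenario,
                      config = utils::capture.output(utils::str(list(
                        em_criterion = em_criterion, em_test = em_test,
                        bm = if (scenario == "free_living") bm else NULL))))
  ), class = "sim_session")
}
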