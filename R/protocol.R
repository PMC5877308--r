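#' Construct a laboratory protocol
#'
#' A protocol is an ordered list of planned activity segments performed from
#' a common start time. Three standardized parts are supported:
#' \describe{
#'   \item{part1}{six 3-min segments (sitting, standing, walking at 80, 100
#'     and 120 bpm, jogging at 140 bpm); only the middle minute of each
#'     segment is analyzed.}
#'   \item{part2}{five 2-min segments (sitting, standing, three self-paced
#'     walking/jogging paces); analyzed either whole ("2a") or with 30-s
#'     margins around posture changes excluded ("2b").}
#'   \item{part3}{twelve cycles of a 30-s transition allotment (sitting down
#'     or getting up in 1, 2 or 3 s) followed by a hold of at least 30 s;
#'     the first 30 s of each hold is analyzed.}
#' }
#'
#' @param part one of `"part1"`, `"part2"`, `"part3"`.
#' @param segments data frame with columns `activity` (reference labels),
#'   `planned_seconds` (> 0) and `pace_note` (free text).
#' @param start protocol start time (`POSIXct` UTC), on the 30-s grid.
#' @return an object of class `lab_protocol`.
#' @export
lab_protocol <- function(part, segments,
                         start = as.POSIXct("2018-01-01 09:00:00", tz = "UTC")) {
  part <- match.arg(part, c("part1", "part2", "part3"))
  stopifnot(is.data.frame(segments),
            all(c("activity", "planned_seconds") %in% names(segments)))
  if (!"pace_note" %in% names(segments)) segments$pace_note <- rep("", nrow(segments))
  if (nrow(segments) > 0L) {
    segments$activity <- normalize_labels(segments$activity,
                                          allowed = reference_labels())
    if (any(segments$planned_seconds <= 0)) {
      stop("planned_seconds must be positive", call. = FALSE)
    }
  }
  start <- as_utc(start)
  if (as.numeric(start) %% EPOCH_SECONDS != 0) {
    stop("protocol start must lie on the 30-s grid", call. = FALSE)
  }
  structure(list(part = part, segments = segments, start = start),
            class = "lab_protocol")
}

segment_bounds <- function(p) {
  ends <- as.numeric(p$start) + cumsum(p$segments$planned_seconds)
  starts <- c(as.numeric(p$start), ends[-length(ends)])
  data.frame(start = starts, end = ends)
}

new_window_set <- function(starts, ends, mode) {
  w <- data.frame(start = as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
                  end = as.POSIXct(ends, origin = "1970-01-01", tz = "UTC"))
  structure(w, class = c("analysis_windows", "data.frame"), mode = mode)
}

#' Total analyzed time of a window set, in minutes
#' @param w an `analysis_windows` object.
#' @export
window_minutes <- function(w) {
  if (nrow(w) == 0L) return(0)
  sum(as.numeric(w$end) - as.numeric(w$start)) / 60
}

#' Analysis windows for protocol part 1
#'
#' In each 3-min segment the first and last minute serve as transition or
#' recovery; only the middle minute is analyzed, yielding 6 min for the
#' canonical six-segment protocol.
#'
#' @param p a `lab_protocol` with `part == "part1"`.
#' @return an `analysis_windows` set (one 60-s window per segment).
#' @export
windows_part1 <- function(p) {
  stopifnot(inherits(p, "lab_protocol"))
  if (p$part != "part1") stop("protocol mismatch: expected part1", call. = FALSE)
  if (nrow(p$segments) == 0L) return(new_window_set(numeric(), numeric(), "part1_middle"))
  b <- segment_bounds(p)
  new_window_set(b$start + 60, b$start + 120, "part1_middle")
}

#' Analysis windows for protocol part 2
#'
#' With `include_transitions = TRUE` ("2a") the whole span is analyzed:
#' 10 min for the canonical five 2-min segments. Otherwise ("2b") a 60-s
#' margin — 30 s before and 30 s after — is excluded around every posture
#' change. A posture change occurs only where the posture *class* changes:
#' consecutive walking paces (jogging included) share class walking and do
#' not create a transition, so the canonical protocol yields
#' `10 - (number of posture-class changes)` minutes, between 6 and 8. No
#' margin is applied before the first or after the last segment.
#'
#' @param p a `lab_protocol` with `part == "part2"`.
#' @param include_transitions logical; `TRUE` analyzes the full span.
#' @return an `analysis_windows` set.
#' @export
windows_part2 <- function(p, include_transitions = FALSE) {
  stopifnot(inherits(p, "lab_protocol"))
  if (p$part != "part2") stop("protocol mismatch: expected part2", call. = FALSE)
  if (nrow(p$segments) == 0L) {
    return(new_window_set(numeric(), numeric(),
                          if (include_transitions) "part2_all" else "part2_excl_transitions"))
  }
  b <- segment_bounds(p)
  span <- c(min(b$start), max(b$end))
  if (include_transitions) {
    return(new_window_set(span[1], span[2], "part2_all"))
  }
  cls <- posture_class(p$segments$activity)
  changes <- b$end[-nrow(b)][cls[-1] != cls[-length(cls)]]
  # excluded margins [t-30, t+30); overlapping margins merge (only possible
  # for nonstandard protocols with segments shorter than 60 s)
  cuts <- span[1]
  keep_start <- numeric(); keep_end <- numeric()
  cur <- span[1]
  for (t in sort(changes)) {
    lo <- max(t - 30, span[1]); hi <- min(t + 30, span[2])
    if (lo > cur) { keep_start <- c(keep_start, cur); keep_end <- c(keep_end, lo) }
    cur <- max(cur, hi)
  }
  if (cur < span[2]) { keep_start <- c(keep_start, cur); keep_end <- c(keep_end, span[2]) }
  new_window_set(keep_start, keep_end, "part2_excl_transitions")
}

#' Analysis windows for protocol part 3
#'
#' Each cycle allots up to 30 s for the posture change; the following hold
#' is the object of analysis, restricted to its first 30-s epoch, so the
#' canonical twelve cycles yield 6 min even when holds run long.
#'
#' @param p a `lab_protocol` with `part == "part3"`. Each segment is one
#'   cycle: `planned_seconds` covers the 30-s transition allotment plus the
#'   hold, and `activity` is the held posture.
#' @return an `analysis_windows` set (one 30-s window per cycle).
#' @export
windows_part3 <- function(p) {
  stopifnot(inherits(p, "lab_protocol"))
  if (p$part != "part3") stop("protocol mismatch: expected part3", call. = FALSE)
  if (nrow(p$segments) == 0L) return(new_window_set(numeric(), numeric(), "part3_post_transition"))
  if (any(p$segments$planned_seconds < 60)) {
    stop("part3 cycles need >= 60 s (30-s transition allotment + >= 30-s hold)",
         call. = FALSE)
  }
  b <- segment_bounds(p)
  new_window_set(b$start + 30, b$start + 60, "part3_post_transition")
}

#' Draw a randomized protocol
#'
#' Segment order is uniformly random under the part's constraints and
#' deterministic for a fixed seed. Part 3 alternates sitting down and
#' getting up (a posture change is only possible from the opposite posture);
#' the pace sequence of each transition type is shuffled independently.
#'
#' @param part `"part1"`, `"part2"` or `"part3"`.
#' @param seed integer seed.
#' @param start protocol start time.
#' @param hold_seconds part-3 hold duration (>= 30; default 30).
#' @return a `lab_protocol`.
#' @export
randomize_protocol <- function(part, seed,
                               start = as.POSIXct("2018-01-01 09:00:00", tz = "UTC"),
                               hold_seconds = 30) {
  part <- match.arg(part, c("part1", "part2", "part3"))
  rng <- local_rng(seed)
  if (part == "part1") {
    pool <- data.frame(
      activity = c("sitting", "standing", "walking", "walking", "walking", "walking"),
      planned_seconds = 180,
      pace_note = c("", "", "80 bpm", "100 bpm", "120 bpm", "jog 140 bpm"),
      stringsAsFactors = FALSE
    )
    return(lab_protocol("part1", pool[rng$sample(6), , drop = FALSE], start))
  }
  if (part == "part2") {
    pool <- data.frame(
      activity = c("sitting", "standing", "walking", "walking", "walking"),
      planned_seconds = 120,
      pace_note = c("", "", "own pace slow", "own pace rapid", "own pace jog"),
      stringsAsFactors = FALSE
    )
    return(lab_protocol("part2", pool[rng$sample(5), , drop = FALSE], start))
  }
  stopifnot(hold_seconds >= 30)
  down_paces <- c(1, 2, 3, 1, 2, 3)[rng$sample(6)]
  up_paces <- c(1, 2, 3, 1, 2, 3)[rng$sample(6)]
  seg <- data.frame(
    activity = rep(c("sitting", "standing"), 6),   # sit-down hold, get-up hold
    planned_seconds = 30 + hold_seconds,
    pace_note = paste0(rep(c("sit-down ", "get-up "), 6),
                       as.vector(rbind(down_paces, up_paces)), " s"),
    stringsAsFactors = FALSE
  )
  lab_protocol("part3", seg, start)
}

#' Reference second-stream for a protocol, restricted to analysis windows
#'
#' Emits one per-second reference label for every second of every analysis
#' window, taken from the planned segment activity at that second. Windows
#' lie outside transition margins by construction, so the planned activity
#' is the true posture there.
#'
#' @param p a `lab_protocol`.
#' @param w an `analysis_windows` set within the protocol span.
#' @param subject_id,source passed to [second_stream()].
#' @return a `second_stream`.
#' @export
protocol_to_reference <- function(p, w, subject_id = "s1", source = "observation") {
  stopifnot(inherits(p, "lab_protocol"))
  if (nrow(w) == 0L) {
    return(second_stream(as.POSIXct(character(), tz = "UTC"), character(),
                         subject_id, source))
  }
  b <- segment_bounds(p)
  secs <- unlist(lapply(seq_len(nrow(w)), function(i) {
    seq(as.numeric(w$start[i]), as.numeric(w$end[i]) - 1)
  }))
  if (any(secs < min(b$start)) || any(secs >= max(b$end))) {
    stop("analysis windows outside protocol span", call. = FALSE)
  }
  idx <- findInterval(secs, b$start)
  second_stream(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
                p$segments$activity[idx], subject_id, source)
}
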