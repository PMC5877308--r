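#' Construct a per-second reference stream
#'
#' A `second_stream` is the package's representation of a per-second labeled
#' activity record, e.g. a direct-observation log or an inclinometer-style
#' export. Timestamps must be strictly increasing whole seconds; gaps are
#' allowed and preserved (never interpolated).
#'
#' @param time `POSIXct` (UTC) timestamps, one per labeled second.
#' @param label per-second labels in `second_labels()` (case-insensitive).
#' @param subject_id opaque subject identifier.
#' @param source free-text name of the recording source.
#' @return a data frame of class `second_stream` with columns `time`, `label`.
#' @export
second_stream <- function(time, label, subject_id = "s1", source = "reference") {
  time <- as_utc(time)
  if (length(time) != length(label)) stop("time and label lengths differ", call. = FALSE)
  label <- normalize_labels(label, allowed = second_labels())
  if (length(time) > 0L) {
    secs <- as.numeric(time)
    if (any(secs %% 1 != 0)) stop("second_stream timestamps must be whole seconds", call. = FALSE)
    if (is.unsorted(secs, strictly = TRUE)) {
      stop("second_stream timestamps must be strictly increasing", call. = FALSE)
    }
  }
  out <- data.frame(time = time, label = label, stringsAsFactors = FALSE)
  structure(out, class = c("second_stream", "data.frame"),
            subject_id = subject_id, source = source)
}

#' Construct an epoch series
#'
#' An `epoch_series` holds one activity label per 30-s epoch for one subject
#' and one device. Epochs are half-open intervals `[start, start + 30)` whose
#' starts lie on the UTC 30-s wall-clock grid (hh:mm:00 / hh:mm:30); starts
#' must be strictly increasing, gaps (missing epochs) are allowed.
#'
#' @param start `POSIXct` (UTC) epoch starts on the 30-s grid.
#' @param label epoch labels in `activity_labels()` (case-insensitive).
#' @param subject_id opaque subject identifier.
#' @param source device name.
#' @return a data frame of class `epoch_series` with columns `start`, `label`.
#' @export
epoch_series <- function(start, label, subject_id = "s1", source = "device") {
  start <- as_utc(start)
  if (length(start) != length(label)) stop("start and label lengths differ", call. = FALSE)
  label <- normalize_labels(label, allowed = activity_labels())
  if (length(start) > 0L) {
    secs <- as.numeric(start)
    if (any(secs %% EPOCH_SECONDS != 0)) {
      stop("epoch starts must lie on the 30-s grid", call. = FALSE)
    }
    if (anyDuplicated(secs)) stop("duplicate epoch starts", call. = FALSE)
    if (is.unsorted(secs, strictly = TRUE)) {
      stop("epoch starts must be strictly increasing", call. = FALSE)
    }
  }
  out <- data.frame(start = start, label = label, stringsAsFactors = FALSE)
  structure(out, class = c("epoch_series", "data.frame"),
            subject_id = subject_id, source = source)
}

#' Floor timestamps to the 30-s epoch grid
#'
#' @param time `POSIXct` timestamps.
#' @param grid_origin optional origin; defaults to the UTC wall-clock grid
#'   (multiples of 30 s since the Unix epoch). A supplied origin is itself
#'   floored to that grid first.
#' @return `POSIXct` epoch starts.
#' @export
floor_to_grid <- function(time, grid_origin = NULL) {
  time <- as_utc(time)
  origin <- 0
  if (!is.null(grid_origin)) {
    origin <- floor(as.numeric(as_utc(grid_origin)) / EPOCH_SECONDS) * EPOCH_SECONDS
  }
  secs <- origin + floor((as.numeric(time) - origin) / EPOCH_SECONDS) * EPOCH_SECONDS
  as.POSIXct(secs, origin = "1970-01-01", tz = "UTC")
}

#' Merge two epoch series onto their common epochs
#'
#' Keeps only epochs registered by *both* sources: if one tracker did not
#' register a 30-s period (technical lapse, late initialization), that period
#' is excluded from all downstream comparison. The counts of single-source
#' epochs are kept as a drop report.
#'
#' @param a,b `epoch_series` for the same subject on the same 30-s grid.
#' @return a data frame of class `merged_pair_series` with columns `start`,
#'   `label_a`, `label_b`; attribute `drop_report` is a list with counts
#'   `a_only`, `b_only`; attributes `source_a`, `source_b` name the devices.
#' @export
align_and_merge <- function(a, b) {
  stopifnot(inherits(a, "epoch_series"), inherits(b, "epoch_series"))
  if (!identical(attr(a, "subject_id"), attr(b, "subject_id"))) {
    stop("cannot merge epoch series from different subjects", call. = FALSE)
  }
  sa <- as.numeric(a$start); sb <- as.numeric(b$start)
  if (any(sa %% EPOCH_SECONDS != 0) || any(sb %% EPOCH_SECONDS != 0)) {
    stop("grid mismatch: epoch starts not aligned to the 30-s grid", call. = FALSE)
  }
  common <- intersect(sa, sb)
  common <- sort(common)
  ia <- match(common, sa); ib <- match(common, sb)
  out <- data.frame(
    start = as.POSIXct(common, origin = "1970-01-01", tz = "UTC"),
    label_a = a$label[ia],
    label_b = b$label[ib],
    stringsAsFactors = FALSE
  )
  structure(out, class = c("merged_pair_series", "data.frame"),
            subject_id = attr(a, "subject_id"),
            source_a = attr(a, "source"), source_b = attr(b, "source"),
            drop_report = list(a_only = length(sa) - length(common),
                               b_only = length(sb) - length(common)))
}

#' Retain days with sufficient matched wear time
#'
#' A free-living day enters the comparison only if both trackers registered
#' at least `min_wear_minutes` of matched wear time on that local calendar
#' day (the default, 300 min = 5 h, retains a day of exactly 5 h; "less
#' than 5 h" is excluded). Wear time is counted as 0.5 min per merged epoch.
#'
#' @param merged a `merged_pair_series` possibly spanning several days.
#' @param min_wear_minutes retention threshold in minutes (default 300).
#' @param tz_offset_minutes offset applied before assigning epochs to local
#'   calendar days (timestamps are stored in UTC; default 0).
#' @return list with `retained` (the filtered `merged_pair_series`) and
#'   `days` (per-day data frame: `day`, `wear_minutes`, `retained`).
#' @export
wear_filter <- function(merged, min_wear_minutes = 300, tz_offset_minutes = 0) {
  stopifnot(inherits(merged, "merged_pair_series"))
  local_day <- as.Date(merged$start + tz_offset_minutes * 60, tz = "UTC")
  if (nrow(merged) == 0L) {
    days <- data.frame(day = as.Date(character()), wear_minutes = numeric(),
                       retained = logical())
    return(list(retained = merged, days = days))
  }
  tab <- table(local_day)
  days <- data.frame(
    day = as.Date(names(tab)),
    wear_minutes = as.numeric(tab) * EPOCH_SECONDS / 60,
    stringsAsFactors = FALSE
  )
  days$retained <- days$wear_minutes >= min_wear_minutes
  keep <- local_day %in% days$day[days$retained]
  out <- merged[keep, , drop = FALSE]
  row.names(out) <- NULL
  for (at in c("subject_id", "source_a", "source_b", "drop_report")) {
    attr(out, at) <- attr(merged, at)
  }
  class(out) <- class(merged)
  list(retained = out, days = days)
}
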