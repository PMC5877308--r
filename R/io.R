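# CSV dialects
# - device epochs: timestamp,user_id,sitting,standing,walking  (one-hot
#   booleans; all false encodes an idle epoch)
# - second stream: timestamp,label                (label in sitting/standing/
#   walking/off; gaps are preserved, never interpolated)
# - protocols: JSON {part, start, segments: [{order_index, activity,
#   planned_seconds, pace_note}]} or CSV with those columns plus part
# - misallocation profiles: JSON {ppr: {...}, split: {actual: {detected: x}}}
# All files are comma-separated UTF-8 with a header; timestamps ISO-8601 UTC.

parse_iso_utc <- function(x, path = "<input>") {
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("%s: unparseable timestamp '%s' (row %d)", path, x[bad], bad),
         call. = FALSE)
  }
  out
}

fmt_iso_utc <- function(t) format(as_utc(t), "%Y-%m-%dT%H:%M:%SZ")

parse_flag <- function(x, col, path) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "yes", "1")] <- TRUE
  out[v %in% c("false", "no", "0")] <- FALSE
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("%s: column '%s' has non-boolean value '%s' (row %d)",
                 path, col, x[bad], bad), call. = FALSE)
  }
  out
}

#' Read a device epoch export
#'
#' Expects columns `timestamp`, `user_id`, `sitting`, `standing`, `walking`.
#' Activity flags are one-hot booleans; a row with all three false encodes
#' an idle epoch, more than one true flag is a validation error. Timestamps
#' are floored to the 30-s grid; duplicates after flooring are an error
#' naming the offending row.
#'
#' @param path CSV file path.
#' @param source device name for the resulting series.
#' @return an `epoch_series`.
#' @export
read_device_epochs <- function(path, source = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("timestamp", "user_id", "sitting", "standing", "walking")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: missing columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")), call. = FALSE)
  }
  flags <- cbind(sitting = parse_flag(df$sitting, "sitting", path),
                 standing = parse_flag(df$standing, "standing", path),
                 walking = parse_flag(df$walking, "walking", path))
  n_true <- rowSums(flags)
  if (any(n_true > 1)) {
    bad <- which(n_true > 1)[1L]
    stop(sprintf("%s: more than one activity flag true (row %d)", path, bad),
         call. = FALSE)
  }
  label <- ifelse(n_true == 0, "idle",
                  reference_labels()[max.col(flags, ties.method = "first")])
  start <- floor_to_grid(parse_iso_utc(df$timestamp, path))
  if (anyDuplicated(start)) {
    bad <- which(duplicated(start))[1L]
    stop(sprintf("%s: duplicate 30-s period %s (row %d)", path,
                 fmt_iso_utc(start[bad]), bad), call. = FALSE)
  }
  o <- order(start)
  sid <- unique(df$user_id)
  if (length(sid) != 1L) stop(sprintf("%s: expected a single user_id", path), call. = FALSE)
  epoch_series(start[o], label[o], subject_id = as.character(sid), source = source)
}

#' @rdname read_device_epochs
#' @param es an `epoch_series` to write.
#' @export
write_device_epochs <- function(es, path) {
  stopifnot(inherits(es, "epoch_series"))
  df <- data.frame(
    timestamp = fmt_iso_utc(es$start),
    user_id = attr(es, "subject_id"),
    sitting = es$label == "sitting",
    standing = es$label == "standing",
    walking = es$label == "walking"
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a per-second reference stream
#'
#' CSV with columns `timestamp`, `label` (sitting / standing / walking /
#' off, case-insensitive). Gaps between seconds are preserved. Writing then
#' reading a canonical file is lossless.
#'
#' @param path CSV file path.
#' @param subject_id,source metadata for the resulting stream.
#' @return a `second_stream`.
#' @export
read_second_stream <- function(path, subject_id = "s1", source = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("timestamp", "label") %in% names(df))) {
    stop(sprintf("%s: expected columns timestamp, label", path), call. = FALSE)
  }
  t <- parse_iso_utc(df$timestamp, path)
  lab <- normalize_labels(df$label, allowed = second_labels(), context = path)
  second_stream(t, lab, subject_id = subject_id, source = source)
}

#' @rdname read_second_stream
#' @param stream a `second_stream` to write.
#' @export
write_second_stream <- function(stream, path) {
  stopifnot(inherits(stream, "second_stream"))
  utils::write.csv(data.frame(timestamp = fmt_iso_utc(stream$time),
                              label = stream$label),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a laboratory protocol (JSON)
#'
#' @param path JSON file path.
#' @return a `lab_protocol`.
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- as.data.frame(x$segments, stringsAsFactors = FALSE)
  if ("order_index" %in% names(seg)) seg <- seg[order(seg$order_index), ]
  lab_protocol(x$part,
               seg[, c("activity", "planned_seconds", "pace_note")],
               start = parse_iso_utc(x$start, path))
}

#' @rdname read_protocol
#' @param p a `lab_protocol` to write.
#' @export
write_protocol <- function(p, path) {
  stopifnot(inherits(p, "lab_protocol"))
  seg <- p$segments
  seg$order_index <- seq_len(nrow(seg))
  jsonlite::write_json(list(part = p$part, start = fmt_iso_utc(p$start),
                            segments = seg),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a misallocation profile (JSON)
#'
#' The JSON carries `ppr` (per detected activity, percent) and `split`
#' (nested `actual -> detected -> percent`), so published profiles can be
#' reused without raw epoch data.
#'
#' @param path JSON file path.
#' @return a `misallocation_profile`.
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  acts <- reference_labels()
  ppr <- unlist(x$ppr)[acts]
  split <- matrix(NA_real_, 3, 3, dimnames = list(acts, acts))
  for (a in acts) for (d in acts) {
    v <- x$split[[a]][[d]]
    if (!is.null(v)) split[a, d] <- as.numeric(v)
  }
  misallocation_profile(ppr, split)
}

#' @rdname read_profile
#' @param profile a `misallocation_profile` to write.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "misallocation_profile"))
  acts <- reference_labels()
  split <- lapply(stats::setNames(acts, acts), function(a) {
    row <- profile$split[a, ]
    as.list(row[!is.na(row)])
  })
  jsonlite::write_json(list(ppr = as.list(profile$ppr), split = split),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write a performance report
#'
#' The long table from [pooled_report()] keyed by (part, activity, metric),
#' one-decimal values, as CSV or JSON. Undefined metrics are written as
#' `NA` / `null`, never dropped.
#'
#' @param report data frame from [pooled_report()].
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
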