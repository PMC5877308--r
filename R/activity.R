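#' Activity label vocabulary
#'
#' Epoch-level labels are one of `"sitting"`, `"standing"`, `"walking"` or
#' `"idle"`. Per-second reference streams use `"off"` instead of `"idle"` for
#' seconds in which the device or observer recorded no activity; `"idle"` is a
#' valid *prediction* at the epoch level but never a reference condition.
#'
#' @return `activity_labels()` returns the four epoch-level labels;
#'   `reference_labels()` the three labels a reference stream may carry;
#'   `second_labels()` the per-second vocabulary.
#' @export
activity_labels <- function() c("sitting", "standing", "walking", "idle")

#' @rdname activity_labels
#' @export
reference_labels <- function() c("sitting", "standing", "walking")

#' @rdname activity_labels
#' @export
second_labels <- function() c("sitting", "standing", "walking", "off")

# Normalize label strings: case-insensitive, trimmed. Unknown strings are a
# hard error (never coerced to idle).
#' Normalize activity label strings
#'
#' Labels are matched case-insensitively against `allowed`; anything else is
#' an error naming the offending value (and, if supplied, the input line).
#'
#' @param x character vector of raw labels.
#' @param allowed permitted canonical labels.
#' @param context optional string naming the input source for error messages.
#' @return canonical lower-case labels, same length as `x`.
#' @export
normalize_labels <- function(x, allowed = second_labels(), context = NULL) {
  out <- tolower(trimws(as.character(x)))
  bad <- which(!(out %in% allowed))
  if (length(bad) > 0L) {
    where <- if (is.null(context)) "" else paste0(" in ", context)
    stop(sprintf("unknown activity label%s: '%s' (row %d); allowed: %s",
                 where, x[bad[1L]], bad[1L], paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Posture class of a protocol activity
#'
#' Walking paces (any bpm, jogging included) share the posture class
#' `"walking"`; transitions between two walking paces are therefore not
#' posture changes when deriving analysis windows.
#'
#' @param activity canonical activity labels.
#' @return the posture class, identical to the label for the three postures.
#' @export
posture_class <- function(activity) {
  normalize_labels(activity, allowed = reference_labels())
}

round_half_away <- function(x, digits = 0) {
  # reporting rule: round half away from zero (85.75 -> 85.8), unlike base
  # round()'s round-half-even
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Round for reporting (half away from zero)
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1, the reporting convention).
#' @export
report_round <- function(x, digits = 1) round_half_away(x, digits)

EPOCH_SECONDS <- 30

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}
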