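#' Reduce a 30-s window of per-second labels to one epoch label
#'
#' The epoch label is the activity performed for the longest total time
#' within the window. Ties among the maximal activities are broken by
#' priority: sitting, then standing, then walking — so 8 s sitting, 11 s
#' standing, 11 s walking yields standing, and a 10/10/10 three-way tie
#' yields sitting. Seconds labeled `"off"` produce an `"idle"` epoch only
#' when they strictly outnumber every single activity; idle loses all ties.
#'
#' @param labels character vector of exactly 30 per-second labels
#'   (`second_labels()`).
#' @return the epoch label, with attribute `ambivalent` (`TRUE` when the
#'   activity tie-break was needed).
#' @export
reduce_seconds_to_epoch <- function(labels) {
  if (length(labels) != EPOCH_SECONDS) {
    stop(sprintf("malformed window: expected %d seconds, got %d",
                 EPOCH_SECONDS, length(labels)), call. = FALSE)
  }
  labels <- normalize_labels(labels, allowed = second_labels())
  acts <- reference_labels()
  n <- vapply(acts, function(a) sum(labels == a), integer(1))
  n_off <- sum(labels == "off")
  if (n_off > max(n)) {
    return(structure("idle", ambivalent = FALSE))
  }
  top <- which(n == max(n))          # already in priority order sit>stand>walk
  structure(acts[top[1L]], ambivalent = length(top) > 1L)
}

#' Reduce a per-second stream onto the 30-s epoch grid
#'
#' Emits one labeled epoch per *fully covered* grid epoch (all 30 seconds
#' present in the stream); partially covered boundary epochs — and epochs
#' interrupted by gaps — are dropped.
#'
#' @param stream a `second_stream`.
#' @param grid_origin optional grid origin passed to [floor_to_grid()].
#' @return an `epoch_series`; attribute `ambivalent` is a logical vector
#'   marking epochs whose reduction needed the activity tie-break.
#' @export
reduce_stream <- function(stream, grid_origin = NULL) {
  stopifnot(inherits(stream, "second_stream"))
  if (nrow(stream) == 0L) {
    out <- epoch_series(as.POSIXct(character(), tz = "UTC"), character(),
                        subject_id = attr(stream, "subject_id"),
                        source = attr(stream, "source"))
    attr(out, "ambivalent") <- logical()
    return(out)
  }
  ep <- as.numeric(floor_to_grid(stream$time, grid_origin))
  # vectorized equivalent of applying reduce_seconds_to_epoch window-wise
  counts <- table(ep, factor(stream$label, levels = second_labels()))
  full_row <- rowSums(counts) == EPOCH_SECONDS
  counts <- counts[full_row, , drop = FALSE]
  full <- as.numeric(rownames(counts))
  m <- matrix(as.integer(counts[, reference_labels()]), ncol = 3)
  n_off <- as.integer(counts[, "off"])
  rowmax <- pmax(m[, 1], m[, 2], m[, 3])
  idle <- n_off > rowmax
  winner <- max.col(m, ties.method = "first")  # column order = priority order
  labs <- ifelse(idle, "idle", reference_labels()[winner])
  amb <- !idle & (rowSums(m == rowmax) >= 2L)
  out <- epoch_series(as.POSIXct(full, origin = "1970-01-01", tz = "UTC"), labs,
                      subject_id = attr(stream, "subject_id"),
                      source = attr(stream, "source"))
  attr(out, "ambivalent") <- amb
  out
}

#' Count epochs whose reduction needed the tie-break
#'
#' Ambivalent epochs are those where two or all three activities tied for
#' the maximal second count and priority decided the label.
#'
#' @param stream a `second_stream`.
#' @param grid_origin optional grid origin passed to [reduce_stream()].
#' @return list with `count`, `total` (reduced epochs) and `percent`
#'   (`100 * count / total`; `NaN` for an empty stream).
#' @export
count_ambivalent <- function(stream, grid_origin = NULL) {
  reduced <- reduce_stream(stream, grid_origin)
  amb <- attr(reduced, "ambivalent")
  list(count = sum(amb), total = length(amb),
       percent = 100 * sum(amb) / length(amb))
}
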