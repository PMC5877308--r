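#' Reference-by-prediction contingency table
#'
#' Tallies merged epoch pairs into a 3 x 4 table: reference rows sitting /
#' standing / walking, prediction columns sitting / standing / walking /
#' idle. Idle is a legal prediction (counted in the reference row) but an
#' illegal reference condition.
#'
#' @param pairs a `merged_pair_series` (reference in `label_a`, prediction in
#'   `label_b`) or a data frame with columns `reference` and `prediction`.
#' @param windows optional `analysis_windows`; only epochs whose start falls
#'   in a window are tallied. `NULL` tallies everything.
#' @return an integer matrix of class `cross_tab`.
#' @export
cross_tab <- function(pairs, windows = NULL) {
  if (inherits(pairs, "merged_pair_series")) {
    ref <- pairs$label_a; pred <- pairs$label_b; start <- pairs$start
  } else {
    stopifnot(all(c("reference", "prediction") %in% names(pairs)))
    ref <- pairs$reference; pred <- pairs$prediction
    start <- if ("start" %in% names(pairs)) pairs$start else NULL
  }
  ref <- normalize_labels(ref, allowed = activity_labels())
  pred <- normalize_labels(pred, allowed = activity_labels())
  if (any(ref == "idle")) {
    stop("invalid reference label: idle epochs cannot be a true condition",
         call. = FALSE)
  }
  if (!is.null(windows)) {
    if (is.null(start)) stop("window restriction needs epoch start times", call. = FALSE)
    s <- as.numeric(start)
    keep <- rep(FALSE, length(s))
    for (i in seq_len(nrow(windows))) {
      keep <- keep | (s >= as.numeric(windows$start[i]) & s < as.numeric(windows$end[i]))
    }
    ref <- ref[keep]; pred <- pred[keep]
  }
  m <- table(factor(ref, levels = reference_labels()),
             factor(pred, levels = activity_labels()))
  m <- matrix(as.integer(m), nrow = 3, dimnames = dimnames(m))
  structure(m, class = c("cross_tab", class(m)))
}

as_cross_tab <- function(m) {
  # validate an externally built 3x4 count matrix
  stopifnot(is.matrix(m), nrow(m) == 3, ncol(m) == 4)
  dimnames(m) <- list(reference_labels(), activity_labels())
  storage.mode(m) <- "integer"
  structure(m, class = c("cross_tab", class(m)))
}

#' One-vs-rest confusion counts for a target activity
#'
#' TP are epochs of the target detected as the target; FN are target epochs
#' detected as anything else (idle included); FP are non-target epochs
#' detected as the target; TN is the remainder, so TP + FP + FN + TN equals
#' the grand total.
#'
#' @param ct a `cross_tab`.
#' @param target one of the three reference activities.
#' @return a list with `target`, `TP`, `FP`, `FN`, `TN`.
#' @export
one_vs_rest <- function(ct, target) {
  target <- normalize_labels(target, allowed = reference_labels())
  tp <- ct[target, target]
  fn <- sum(ct[target, ]) - tp
  fp <- sum(ct[, target]) - tp
  tn <- sum(ct) - tp - fn - fp
  list(target = target, TP = as.integer(tp), FP = as.integer(fp),
       FN = as.integer(fn), TN = as.integer(tn))
}

#' Sensitivity, specificity and predictive rates from confusion counts
#'
#' Computes the four standard one-vs-rest percentages:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' rate (PPR, precision) `TP/(TP+FP)` and negative predictive rate (NPR)
#' `TN/(TN+FN)`, each times 100. A zero denominator yields `NA` (the
#' undefined marker) — never 0 or 100.
#'
#' @param cc confusion counts as returned by [one_vs_rest()].
#' @return named numeric vector `sensitivity`, `specificity`, `ppr`, `npr`
#'   (percentages, unrounded).
#' @export
performance <- function(cc) {
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(sensitivity = rate(cc$TP, cc$TP + cc$FN),
    specificity = rate(cc$TN, cc$TN + cc$FP),
    ppr = rate(cc$TP, cc$TP + cc$FP),
    npr = rate(cc$TN, cc$TN + cc$FN))
}

#' Decompose false positives of each detected activity by actual activity
#'
#' For each detected activity, splits its false-positive epochs across the
#' two actual (reference) activities they came from — e.g. among wrongly
#' detected sitting, the share of epochs in which the person was actually
#' standing versus actually walking. Together with the PPRs this forms the
#' misallocation profile that parameterizes [estimate_actual()].
#'
#' @param ct a `cross_tab`.
#' @return a `misallocation_profile`: list with `ppr` (named percentages per
#'   detected activity) and `split` (3 x 3 matrix, `split[actual, detected]`
#'   percentages over the FP epochs of each detected column; diagonal `NA`;
#'   columns with no FP are all-`NA`).
#' @export
misdetection_decomposition <- function(ct) {
  acts <- reference_labels()
  ppr <- vapply(acts, function(a) performance(one_vs_rest(ct, a))[["ppr"]],
                numeric(1))
  split <- matrix(NA_real_, 3, 3, dimnames = list(actual = acts, detected = acts))
  for (d in acts) {
    fp <- ct[setdiff(acts, d), d]
    if (sum(fp) > 0) split[setdiff(acts, d), d] <- 100 * fp / sum(fp)
  }
  misallocation_profile(ppr, split)
}

#' Decompose false negatives of each actual activity by wrong prediction
#'
#' Row-wise mirror of [misdetection_decomposition()]: for each reference
#' activity, the distribution of its missed epochs over the labels the
#' device reported instead (idle included).
#'
#' @param ct a `cross_tab`.
#' @return 3 x 4 matrix `split[actual, predicted]` of percentages over each
#'   actual activity's FN epochs; the diagonal and rows without FN are `NA`.
#' @export
sensitivity_decomposition <- function(ct) {
  acts <- reference_labels()
  out <- matrix(NA_real_, 3, 4,
                dimnames = list(actual = acts, predicted = activity_labels()))
  for (a in acts) {
    fn <- ct[a, setdiff(activity_labels(), a)]
    if (sum(fn) > 0) out[a, setdiff(activity_labels(), a)] <- 100 * fn / sum(fn)
  }
  out
}

#' Per-part and pooled performance table
#'
#' The pooled ("all") block is computed from summed epoch counts across
#' parts — pooling epochs, never averaging percentages.
#'
#' @param tabs named list of `cross_tab` objects, one per protocol part.
#' @param digits decimal places for reported values (default 1,
#'   half-away-from-zero).
#' @return data frame with columns `part`, `activity`, `metric`, `value`.
#' @export
pooled_report <- function(tabs, digits = 1) {
  stopifnot(is.list(tabs), length(tabs) > 0, !is.null(names(tabs)))
  if (length(tabs) > 1L) {
    tabs <- c(tabs, list(all = as_cross_tab(Reduce(`+`, lapply(tabs, unclass)))))
  }
  rows <- list()
  for (part in names(tabs)) {
    for (a in reference_labels()) {
      pv <- performance(one_vs_rest(tabs[[part]], a))
      rows[[length(rows) + 1L]] <- data.frame(
        part = part, activity = a, metric = names(pv),
        value = report_round(unname(pv), digits), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
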