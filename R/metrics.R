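#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC; tied scores are handled by midranks.
#'
#' @param scores Numeric score vector (larger = more disease-like).
#' @param labels Binary labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required for AUROC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise (non-interpolated) integration of the precision-recall curve:
#' `AP = sum_k (R_k - R_{k-1}) P_k` over thresholds at distinct score
#' values, so tied scores enter the curve simultaneously. Equals positive
#' prevalence in expectation for an uninformative scorer.
#'
#' @inheritParams auroc
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || all(labels == 1L)) {
    stop("both classes required for average precision")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # thresholds: last index of each run of tied scores
  at <- c(s[-1L] != s[-length(s)], TRUE)
  precision <- tp[at] / (tp[at] + fp[at])
  recall <- tp[at] / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Compute both performance metrics
#'
#' @inheritParams auroc
#' @param label Optional name recorded with the result.
#' @return One-row data frame of class `performance_record` with columns
#'   `label`, `auroc`, `avg_precision`.
#' @export
compute_metrics <- function(scores, labels, label = NA_character_) {
  stopifnot(length(scores) == length(labels))
  out <- data.frame(label = label,
                    auroc = auroc(scores, labels),
                    avg_precision = average_precision(scores, labels),
                    stringsAsFactors = FALSE)
  class(out) <- c("performance_record", "data.frame")
  out
}

#' Stratified subsample index sets
#'
#' Builds `B` index sets, each containing a fraction `frac` of the positives
#' and of the controls, drawn without replacement. Exposed so that the same
#' subsamples can be delivered to every score method under comparison
#' (paired design).
#'
#' @param labels Binary labels.
#' @param B Number of subsamples (default 30).
#' @param frac Fraction of each class retained (default 0.9).
#' @param seed Integer seed.
#' @return List of `B` integer index vectors.
#' @export
subsample_indices <- function(labels, B = 30, frac = 0.9, seed = 1L) {
  labels <- as.integer(labels)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  n_pos <- max(1L, round(frac * length(pos)))
  n_neg <- max(1L, round(frac * length(neg)))
  seeds <- derive_seeds(seed, B)
  lapply(seq_len(B), function(b) {
    with_seed(seeds[b], sort(c(sample(pos, n_pos), sample(neg, n_neg))))
  })
}

#' Bootstrap-style subsample performance
#'
#' Computes AUROC and average precision on `B` stratified 90% subsamples
#' (without replacement). Pass the same `indices` (from
#' [subsample_indices()]) for every method being compared so the records
#' are paired.
#'
#' @inheritParams auroc
#' @param B,frac,seed Subsampling design, see [subsample_indices()].
#' @param indices Optional pre-built index sets; overrides `B`, `frac`,
#'   `seed`.
#' @param label Method name recorded in each row.
#' @return Data frame with one row per subsample and the index sets attached
#'   as attribute `"indices"`.
#' @export
bootstrap_subsample_performance <- function(scores, labels, B = 30, frac = 0.9,
                                            seed = 1L, indices = NULL,
                                            label = NA_character_) {
  stopifnot(length(scores) == length(labels))
  if (is.null(indices)) indices <- subsample_indices(labels, B, frac, seed)
  records <- lapply(seq_along(indices), function(b) {
    idx <- indices[[b]]
    if (length(unique(labels[idx])) < 2L) {
      warning("subsample ", b, " collapsed to a single class; redrawn")
      idx <- subsample_indices(labels, 1L, frac, seed + 10000L + b)[[1L]]
      indices[[b]] <<- idx
    }
    perf <- compute_metrics(scores[idx], labels[idx], label = label)
    data.frame(label = label, subsample = b, auroc = perf$auroc,
               avg_precision = perf$avg_precision, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, records)
  attr(out, "indices") <- indices
  out
}
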