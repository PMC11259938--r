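# Wilcoxon signed-rank machinery for paired performance comparisons.
# Zero differences are dropped (Wilcoxon convention); exact null for small
# samples without tied ranks, sign-flip enumeration for small tied samples,
# normal approximation with continuity and tie correction otherwise.

signed_rank_p <- function(d, exact_max = 25L, enum_max = 15L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(p = 1, statistic = NA_real_, n = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (!ties && n <= exact_max) {
    # exact signed-rank null (psignrank); distribution of W over sign flips
    p <- 2 * min(psignrank(W, n), 1 - psignrank(W - 1, n))
  } else if (ties && n <= enum_max) {
    # full 2^n sign-flip enumeration accommodates tied ranks exactly
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wnull <- drop(signs %*% r)
    p <- 2 * min(mean(Wnull <= W), mean(Wnull >= W))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(p = min(p, 1), statistic = W, n = n)
}

#' Paired Wilcoxon comparison of two performance vectors
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences. The
#' outcome is a tie when `p >= alpha`; otherwise the method with the larger
#' mean is declared the winner. Comparisons are antisymmetric:
#' swapping the arguments swaps the outcome and leaves the p-value
#' unchanged.
#'
#' @param perf_a,perf_b Equal-length paired performance vectors (one entry
#'   per disease term, repeat or subsample).
#' @param alpha Significance level for the tie rule (default 0.05).
#' @param labels Character vector of length 2 naming the two methods.
#' @return List of class `comparison_result` with `score_a`, `score_b`,
#'   `p_value`, `outcome` (`"win_a"`, `"win_b"` or `"tie"`), `statistic`,
#'   `n_effective` and `mean_diff`.
#' @export
pairwise_compare <- function(perf_a, perf_b, alpha = 0.05,
                             labels = c("a", "b")) {
  stopifnot(length(perf_a) == length(perf_b), length(perf_a) >= 1L)
  d <- perf_a - perf_b
  test <- signed_rank_p(d)
  mean_diff <- mean(d)
  outcome <- if (test$p >= alpha || mean_diff == 0) "tie"
             else if (mean_diff > 0) "win_a" else "win_b"
  structure(list(score_a = labels[1L], score_b = labels[2L],
                 p_value = test$p, outcome = outcome,
                 statistic = test$statistic, n_effective = test$n,
                 mean_diff = mean_diff, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Wilcoxon comparison ", x$score_a, " vs ", x$score_b, ": ", x$outcome,
      " (p = ", signif(x$p_value, 3), ", n = ", x$n_effective, ")\n", sep = "")
  invisible(x)
}

#' Winning percentage
#'
#' `100 * wins / (wins + losses)`, rounded to the nearest integer; ties do
#' not enter the denominator. `NA` when no comparison was decided.
#'
#' @param wins,losses Non-negative counts.
#' @return Rounded percentage (or `NA`).
#' @export
winning_percentage <- function(wins, losses) {
  ifelse(wins + losses > 0, round(100 * wins / (wins + losses)), NA_real_)
}

#' Tally wins, losses and ties across comparisons
#'
#' Aggregates a list of [pairwise_compare()] results into per-method counts
#' and the winning percentage `100 * wins / (wins + losses)`, rounded to the
#' nearest integer. Methods with no decided comparison get a missing
#' winning percentage.
#'
#' @param results List of `comparison_result` objects.
#' @return Data frame with columns `score`, `wins`, `losses`, `ties`,
#'   `winning_percentage`, ordered by decreasing winning percentage.
#' @export
tally_comparisons <- function(results) {
  stopifnot(all(vapply(results, inherits, logical(1L), "comparison_result")))
  methods <- unique(unlist(lapply(results, function(r) c(r$score_a, r$score_b))))
  tal <- data.frame(score = methods, wins = 0L, losses = 0L, ties = 0L,
                    stringsAsFactors = FALSE)
  rownames(tal) <- methods
  for (r in results) {
    if (r$outcome == "tie") {
      tal[r$score_a, "ties"] <- tal[r$score_a, "ties"] + 1L
      tal[r$score_b, "ties"] <- tal[r$score_b, "ties"] + 1L
    } else {
      winner <- if (r$outcome == "win_a") r$score_a else r$score_b
      loser <- if (r$outcome == "win_a") r$score_b else r$score_a
      tal[winner, "wins"] <- tal[winner, "wins"] + 1L
      tal[loser, "losses"] <- tal[loser, "losses"] + 1L
    }
  }
  tal$winning_percentage <- winning_percentage(tal$wins, tal$losses)
  tal <- tal[order(-ifelse(is.na(tal$winning_percentage), -1,
                           tal$winning_percentage)), , drop = FALSE]
  rownames(tal) <- NULL
  tal
}
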