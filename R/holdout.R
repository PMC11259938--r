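# Exact 0/1 knapsack by depth-first branch and bound with a fractional
# (LP-relaxation) upper bound. Items carry value v >= 0 and weight w >= 0;
# maximize sum(v x) subject to sum(w x) <= budget. Small n (chromosomes),
# so exactness is cheap and the returned solution is certified optimal.
knapsack_exact <- function(v, w, budget) {
  n <- length(v)
  if (n == 0L) return(list(select = integer(0), value = 0))
  ord <- order(-(v / pmax(w, .Machine$double.eps)))
  v <- v[ord]; w <- w[ord]
  best_val <- -Inf
  best_set <- integer(0)
  frac_bound <- function(i, cap) {
    # greedy fractional fill of items i..n into remaining capacity
    b <- 0
    while (i <= n && cap > 0) {
      if (w[i] <= cap) {
        b <- b + v[i]; cap <- cap - w[i]
      } else {
        b <- b + v[i] * cap / w[i]; cap <- 0
      }
      i <- i + 1L
    }
    b
  }
  rec <- function(i, cap, val, set) {
    if (val > best_val) {
      best_val <<- val; best_set <<- set
    }
    if (i > n) return()
    if (val + frac_bound(i, cap) <= best_val + 1e-12) return()
    # small tolerance so exact-capacity selections survive rounding
    if (w[i] <= cap + 1e-12) rec(i + 1L, cap - w[i], val + v[i], c(set, i))
    rec(i + 1L, cap, val, set)
  }
  rec(1L, budget, 0, integer(0))
  list(select = ord[best_set], value = best_val)
}

#' Select holdout chromosomes by exact binary programming
#'
#' Chooses a set of chromosomes to hold out as a test set that contains
#' about `budget` (default 20%) of a disease's positive SNVs while
#' approximately preserving the overall positive:control imbalance.
#' Solves, exactly,
#' \deqn{\max_x \sum_i c_i x_i \quad \mathrm{s.t.} \sum_i w^+_i x_i \le
#'   \mathrm{budget},\ x_i \in \{0,1\},}
#' with \eqn{c_i = w^+_i - |w^+_i - w^-_i|}, where \eqn{w^+_i} and
#' \eqn{w^-_i} are the fractions of positive and control SNPs on chromosome
#' \eqn{i}. Chromosomes where positives and controls are balanced
#' contribute the most; a literal zero right-hand side would force the
#' empty set, so the budget is an explicit parameter.
#'
#' @param w_plus,w_minus Non-negative per-chromosome fractions of positive
#'   and control SNPs (each summing to 1).
#' @param budget Maximum fraction of positives allowed in the holdout set
#'   (default 0.20).
#' @return List of class `holdout_selection` with `x` (binary indicator
#'   vector), `selected` (chromosome indices), `objective`, `c`, `w_plus`,
#'   `w_minus`, `budget`, and `positive_fraction` of the selected set.
#' @export
select_holdout_chromosomes <- function(w_plus, w_minus, budget = 0.20) {
  stopifnot(length(w_plus) == length(w_minus),
            all(w_plus >= 0), all(w_minus >= 0))
  if (budget < 0) stop("budget must be non-negative")
  if (abs(sum(w_plus) - 1) > 1e-6 || abs(sum(w_minus) - 1) > 1e-6) {
    warning("w_plus / w_minus do not sum to 1; interpreting as given")
  }
  cc <- w_plus - abs(w_plus - w_minus)
  # items with non-positive objective weight never improve the maximum
  cand <- which(cc > 0 & w_plus <= budget)
  sol <- knapsack_exact(cc[cand], w_plus[cand], budget)
  selected <- sort(cand[sol$select])
  x <- integer(length(w_plus))
  x[selected] <- 1L
  structure(list(x = x, selected = selected,
                 objective = sum(cc[selected]),
                 c = cc, w_plus = w_plus, w_minus = w_minus,
                 budget = budget,
                 positive_fraction = sum(w_plus[selected])),
            class = "holdout_selection")
}

#' @export
print.holdout_selection <- function(x, ...) {
  cat("Holdout selection: chromosomes {",
      paste(x$selected, collapse = ", "), "}\n",
      "  positives held out: ", round(100 * x$positive_fraction, 1),
      "% (budget ", round(100 * x$budget, 1), "%), objective ",
      signif(x$objective, 4), "\n", sep = "")
  invisible(x)
}

#' Per-chromosome SNP fractions
#'
#' Convenience helper computing `w_plus` and `w_minus` from labeled
#' variants for [select_holdout_chromosomes()].
#'
#' @param chrom Chromosome of each variant (integer in 1..n_chrom).
#' @param labels Binary labels aligned with `chrom`.
#' @param n_chrom Number of chromosomes (default 22).
#' @return List with `w_plus` and `w_minus`, each length `n_chrom`.
#' @export
chromosome_fractions <- function(chrom, labels, n_chrom = 22) {
  chrom <- as.integer(chrom)
  labels <- as.integer(labels)
  stopifnot(all(chrom >= 1L & chrom <= n_chrom))
  w_plus <- tabulate(chrom[labels == 1L], n_chrom) / sum(labels == 1L)
  w_minus <- tabulate(chrom[labels == 0L], n_chrom) / sum(labels == 0L)
  list(w_plus = w_plus, w_minus = w_minus)
}
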