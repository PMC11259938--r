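#' Matching configuration
#'
#' Settings for matched-control selection. The four strategies are:
#' `"random"` (uniform draws from the candidate pool), `"tss"` (draws from
#' the positive's TSS-distance quantile bin), `"snpsnap"` (all four
#' attributes constrained) and `"snpsnap_tss"` (only TSS distance
#' constrained; the other tolerances are set to 100, i.e. 10,000%,
#' effectively unconstrained).
#'
#' Tolerances are maximum allowable relative deviations
#' `|a_ctrl - a_pos| / a_pos`, in the order (maf, gene_density, dist_tss,
#' ld_partners). When a positive's attribute is exactly zero the relative
#' deviation is undefined and candidates must match it exactly.
#'
#' @param strategy One of `"random"`, `"tss"`, `"snpsnap"`, `"snpsnap_tss"`.
#' @param n_controls Controls requested per positive (default 10).
#' @param tolerances Named numeric vector of per-attribute tolerances;
#'   defaults depend on the strategy.
#' @param n_bins Number of equal-count TSS-distance bins for the `"tss"`
#'   strategy (default 50).
#' @param rng_seed Integer seed driving all sampling.
#' @return List of class `match_config`.
#' @export
match_config <- function(strategy = c("snpsnap", "random", "tss", "snpsnap_tss"),
                         n_controls = 10,
                         tolerances = NULL,
                         n_bins = 50,
                         rng_seed = 1L) {
  strategy <- match.arg(strategy)
  if (is.null(tolerances)) {
    tolerances <- switch(strategy,
      snpsnap = c(maf = 0.05, gene_density = 0.50, dist_tss = 0.20, ld_partners = 0.50),
      snpsnap_tss = c(maf = 100, gene_density = 100, dist_tss = 0.20, ld_partners = 100),
      c(maf = Inf, gene_density = Inf, dist_tss = Inf, ld_partners = Inf)
    )
  }
  stopifnot(all(tolerances > 0), n_controls >= 1, n_bins >= 1)
  structure(list(strategy = strategy, n_controls = as.integer(n_controls),
                 tolerances = tolerances, n_bins = as.integer(n_bins),
                 rng_seed = as.integer(rng_seed)),
            class = "match_config")
}

#' Equal-count bins of TSS distance
#'
#' Sorts the pool by `dist_tss` (ties broken by `id` for determinism) and
#' splits it into `n_bins` bins whose sizes differ by at most one.
#'
#' @param pool Data frame with `id` and `dist_tss` columns.
#' @param n_bins Number of bins; must not exceed the pool size.
#' @return Integer vector of bin indices aligned with `pool` rows.
#' @export
bin_by_tss_distance <- function(pool, n_bins = 50) {
  stopifnot(n_bins >= 1)
  n <- nrow(pool)
  if (n_bins > n) stop("n_bins (", n_bins, ") exceeds pool size (", n, ")")
  ord <- order(pool$dist_tss, pool$id)
  # sizes differ by at most 1; larger bins first
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}

# relative deviation with a division guard at a_pos = 0
relative_deviation <- function(a_ctrl, a_pos) {
  if (is.na(a_pos)) return(rep(NA_real_, length(a_ctrl)))
  if (a_pos == 0) return(ifelse(a_ctrl == 0, 0, Inf))
  abs(a_ctrl - a_pos) / abs(a_pos)
}

match_attributes <- c("maf", "gene_density", "dist_tss", "ld_partners")

# indices of pool rows eligible for one positive under a tolerance set
eligible_candidates <- function(positive, pool, tolerances) {
  ok <- rep(TRUE, nrow(pool))
  for (a in names(tolerances)) {
    tol <- tolerances[[a]]
    if (!is.finite(tol) && tol > 0) next
    dev <- relative_deviation(pool[[a]], positive[[a]])
    ok <- ok & !is.na(dev) & dev <= tol
  }
  which(ok)
}

#' Select matched control variants
#'
#' For each positive (disease-associated) variant, draws up to
#' `config$n_controls` control variants from `pool` according to the
#' configured strategy. Controls are globally unique: once claimed by one
#' positive a control is unavailable to all others. Claims are processed in
#' a seeded random order over positives. Pool variants appearing in
#' `catalog_ids` (the full association catalog) or among the positives are
#' never used. Positives with no eligible candidate are dropped and
#' recorded.
#'
#' @param positives Data frame of positive variants carrying the matching
#'   attributes (`maf`, `gene_density`, `dist_tss`, `ld_partners`) required
#'   by the strategy.
#' @param pool Data frame of candidate control variants with the same
#'   attribute columns.
#' @param catalog_ids Character vector of variant ids that must never be
#'   used as controls (defaults to the positive ids).
#' @param config A [match_config()].
#' @return List of class `match_result` with elements `mapping` (named list
#'   positive id -> character vector of control ids), `dropped_positives`,
#'   and `audit` (one row per returned pair with per-attribute relative
#'   deviations).
#' @export
match_controls <- function(positives, pool, catalog_ids = NULL,
                           config = match_config()) {
  stopifnot(inherits(config, "match_config"))
  check_variants(positives, c("id"))
  check_variants(pool, c("id"))
  needed <- switch(config$strategy,
                   random = character(0),
                   tss = "dist_tss",
                   match_attributes)
  miss <- setdiff(needed, intersect(names(positives), names(pool)))
  if (length(miss) > 0L) {
    stop("strategy '", config$strategy, "' needs attribute column(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(catalog_ids)) catalog_ids <- positives$id
  pool <- pool[!(pool$id %in% c(catalog_ids, positives$id)), , drop = FALSE]

  mapping <- stats::setNames(vector("list", nrow(positives)),
                             as.character(positives$id))
  dropped <- character(0)
  audit <- list()
  if (nrow(positives) == 0L) {
    return(structure(list(mapping = mapping, dropped_positives = dropped,
                          audit = empty_audit(), config = config),
                     class = "match_result"))
  }
  if (config$strategy == "tss") {
    pool_bins <- bin_by_tss_distance(pool, config$n_bins)
    # a positive falls in the bin whose distance range contains its dist_tss
    bin_max <- vapply(split(pool$dist_tss, pool_bins), max, numeric(1L))
  }

  claimed <- logical(nrow(pool))
  order_pos <- with_seed(config$rng_seed,
                         sample.int(nrow(positives), nrow(positives)))
  draw_seeds <- derive_seeds(config$rng_seed + 1L, nrow(positives))

  for (i in order_pos) {
    positive <- positives[i, , drop = FALSE]
    cand <- switch(config$strategy,
      random = seq_len(nrow(pool)),
      tss = {
        b <- findInterval(positive$dist_tss, bin_max,
                          left.open = TRUE) + 1L
        b <- min(b, config$n_bins)
        which(pool_bins == b)
      },
      eligible_candidates(positive, pool, config$tolerances)
    )
    cand <- cand[!claimed[cand]]
    if (length(cand) == 0L) {
      dropped <- c(dropped, as.character(positive$id))
      next
    }
    take <- if (length(cand) <= config$n_controls) cand else
      with_seed(draw_seeds[i], cand[sample.int(length(cand), config$n_controls)])
    claimed[take] <- TRUE
    mapping[[as.character(positive$id)]] <- as.character(pool$id[take])
    audit[[length(audit) + 1L]] <- data.frame(
      positive_id = as.character(positive$id),
      control_id = as.character(pool$id[take]),
      rank = seq_along(take),
      dev_maf = dev_or_na(pool, take, positive, "maf"),
      dev_gene_density = dev_or_na(pool, take, positive, "gene_density"),
      dev_dist_tss = dev_or_na(pool, take, positive, "dist_tss"),
      dev_ld_partners = dev_or_na(pool, take, positive, "ld_partners"),
      stringsAsFactors = FALSE
    )
  }
  mapping <- mapping[!vapply(mapping, is.null, logical(1L))]
  short <- vapply(mapping, length, integer(1L)) < config$n_controls
  if (any(short) || length(dropped) > 0L) {
    warning("control supply exhausted for ", sum(short), " positive(s); ",
            length(dropped), " positive(s) dropped")
  }
  audit <- if (length(audit) > 0L) do.call(rbind, audit) else empty_audit()
  rownames(audit) <- NULL
  structure(list(mapping = mapping, dropped_positives = sort(dropped),
                 audit = audit, config = config),
            class = "match_result")
}

dev_or_na <- function(pool, idx, positive, attribute) {
  if (is.null(pool[[attribute]]) || is.null(positive[[attribute]])) {
    return(rep(NA_real_, length(idx)))
  }
  relative_deviation(pool[[attribute]][idx], positive[[attribute]])
}

empty_audit <- function() {
  data.frame(positive_id = character(0), control_id = character(0),
             rank = integer(0), dev_maf = numeric(0),
             dev_gene_density = numeric(0), dev_dist_tss = numeric(0),
             dev_ld_partners = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.match_result <- function(x, ...) {
  n_ctrl <- sum(vapply(x$mapping, length, integer(1L)))
  cat("Matched controls (", x$config$strategy, "): ", length(x$mapping),
      " positives -> ", n_ctrl, " controls; ",
      length(x$dropped_positives), " dropped\n", sep = "")
  invisible(x)
}
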