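#' Shrink coefficient standard deviations toward a pooled floor
#'
#' Stabilizes near-zero standard-deviation estimates before they are
#' inverted into regression weights: `s = mix * gamma + (1 - mix) * m`,
#' where `m` is the `floor_quantile` quantile (linear interpolation) of all
#' observed standard deviations pooled across diseases and tissues.
#'
#' @param gamma Non-negative matrix (diseases x tissues) or vector of
#'   coefficient standard deviations.
#' @param mix Mixing fraction toward the raw values (default 3/4).
#' @param floor_quantile Pooled quantile defining the floor `m`
#'   (default 0.25).
#' @return Shrunken standard deviations, same shape as `gamma`; `m` is
#'   attached as attribute `"m"`.
#' @export
shrink_sds <- function(gamma, mix = 0.75, floor_quantile = 0.25) {
  stopifnot(all(gamma >= 0), mix >= 0, mix <= 1,
            floor_quantile > 0, floor_quantile < 1)
  m <- unname(quantile(as.numeric(gamma), floor_quantile, type = 7))
  if (m <= 0) {
    stop("pooled standard-deviation floor m is zero; ",
         "similarity weights would be undefined (supply a positive floor)")
  }
  s <- mix * gamma + (1 - mix) * m
  attr(s, "m") <- m
  s
}

# weighted Pearson correlation
weighted_correlation <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Coefficient-based similarity of two disease models
#'
#' Signed squared weighted correlation between two diseases' tissue
#' coefficient vectors, with weights `w_k = 1 / (s_k^i * s_k^j)` built from
#' shrunken coefficient standard deviations; this equals the
#' coefficient of determination of the weighted regression of one vector on
#' the other, signed by the regression slope, and is symmetric in the two
#' diseases. With constant weights it reduces to the signed squared Pearson
#' correlation.
#'
#' @param beta_i,beta_j Tissue coefficient vectors (equal length >= 3).
#' @param s_i,s_j Positive (shrunken) standard deviations, same length.
#' @return List of class `similarity_result` with `s_m`, `r_squared`,
#'   `slope_sign`, `weights` and `degenerate` (TRUE when either vector has
#'   zero weighted variance, in which case `s_m = 0`).
#' @export
disease_similarity <- function(beta_i, beta_j, s_i = NULL, s_j = NULL) {
  d <- length(beta_i)
  stopifnot(length(beta_j) == d, d >= 3L)
  if (is.null(s_i)) s_i <- rep(1, d)
  if (is.null(s_j)) s_j <- rep(1, d)
  stopifnot(all(s_i > 0), all(s_j > 0))
  w <- 1 / (s_i * s_j)
  r <- weighted_correlation(beta_i, beta_j, w)
  degenerate <- is.na(r)
  s_m <- if (degenerate) 0 else sign(r) * r^2
  structure(list(s_m = s_m,
                 r_squared = if (degenerate) 0 else r^2,
                 slope_sign = if (degenerate) 0 else sign(r),
                 weights = w, degenerate = degenerate),
            class = "similarity_result")
}

#' Disease x disease similarity matrix
#'
#' Computes all pairwise model similarities from per-disease coefficient
#' estimates. The standard-deviation floor `m` is pooled once across all
#' diseases and tissues (set `pool = "pair"` to pool per disease pair
#' instead). The result is exactly symmetric with unit diagonal.
#'
#' @param estimates Named list of [estimate_coefficients()] results sharing
#'   the same tissue axis.
#' @param mix,floor_quantile Shrinkage settings, see [shrink_sds()].
#' @param pool `"all"` (default) pools standard deviations across all
#'   diseases once; `"pair"` re-pools within each disease pair.
#' @return Symmetric numeric matrix with disease names as dimnames.
#' @export
similarity_matrix <- function(estimates, mix = 0.75, floor_quantile = 0.25,
                              pool = c("all", "pair")) {
  pool <- match.arg(pool)
  stopifnot(length(estimates) >= 1L)
  if (is.null(names(estimates))) {
    names(estimates) <- paste0("disease_", seq_along(estimates))
  }
  tissues <- names(estimates[[1L]]$beta_mean)
  for (e in estimates) {
    if (!identical(names(e$beta_mean), tissues)) {
      stop("coefficient estimates do not share the same tissue axis")
    }
  }
  B <- do.call(rbind, lapply(estimates, function(e) e$beta_mean))
  G <- do.call(rbind, lapply(estimates, function(e) e$beta_sd))
  n <- nrow(B)
  S <- diag(1, n)
  dimnames(S) <- list(names(estimates), names(estimates))
  if (n == 1L) return(S)
  if (pool == "all") Sh <- shrink_sds(G, mix, floor_quantile)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (pool == "pair") {
        Sh_ij <- shrink_sds(G[c(i, j), , drop = FALSE], mix, floor_quantile)
        si <- Sh_ij[1L, ]; sj <- Sh_ij[2L, ]
      } else {
        si <- Sh[i, ]; sj <- Sh[j, ]
      }
      S[i, j] <- S[j, i] <- disease_similarity(B[i, ], B[j, ], si, sj)$s_m
    }
  }
  S
}

#' Combine per-study genetic correlations into one disease-pair estimate
#'
#' Studies mapped to each disease are weighted by their sample size
#' (`w~(study) = size / sum(sizes)` within the disease); the genetic
#' correlation between two diseases is the doubly weighted combination
#' `s_g = sum_lm w~_l * w~_m * rg_lm`. Study pairs with a missing `rg` are
#' excluded and the weights renormalized, with a warning.
#'
#' @param rg Matrix of per-study-pair genetic correlations (studies of
#'   disease i in rows, studies of disease j in columns); `NA` = missing.
#' @param sizes_i,sizes_j Positive sample sizes of the studies mapped to
#'   each disease, aligned with the rows and columns of `rg`.
#' @return List of class `genetic_corr_estimate` with `s_g`, `w_tilde_i`,
#'   `w_tilde_j`, `w` (pair-weight matrix after any renormalization) and
#'   `rg`.
#' @export
combine_genetic_correlation <- function(rg, sizes_i, sizes_j) {
  rg <- as.matrix(rg)
  stopifnot(nrow(rg) == length(sizes_i), ncol(rg) == length(sizes_j),
            all(sizes_i > 0), all(sizes_j > 0))
  w_i <- sizes_i / sum(sizes_i)
  w_j <- sizes_j / sum(sizes_j)
  w <- outer(w_i, w_j)
  if (anyNA(rg)) {
    warning(sum(is.na(rg)), " study pair(s) without genetic correlation ",
            "excluded; weights renormalized")
    w[is.na(rg)] <- 0
    if (sum(w) == 0) stop("no study pair with an observed genetic correlation")
    w <- w / sum(w)
    rg[is.na(rg)] <- 0
  }
  structure(list(s_g = sum(w * rg), w_tilde_i = w_i, w_tilde_j = w_j,
                 w = w, rg = rg),
            class = "genetic_corr_estimate")
}

#' Normalize a disease's tissue coefficients to the unit interval
#'
#' `x~ = (x - x_min) / x_95` capped at 1 for coefficients above the 95%
#' quantile `x_95` (linear-interpolation quantile), and clamped to `[0, 1]`.
#' Used for heatmap display and for cluster-tissue testing, where
#' coefficients must be comparable across diseases.
#'
#' @param beta Coefficient vector (length >= 2).
#' @return Normalized vector in `[0, 1]`, with `x_min` and `x_95` attached
#'   as attributes.
#' @export
normalize_coefficients <- function(beta) {
  stopifnot(length(beta) >= 2L)
  x_min <- min(beta)
  x_95 <- unname(quantile(beta, 0.95, type = 7))
  if (x_95 <= 0) stop("95% quantile of coefficients is not positive; ",
                      "normalization scale undefined")
  out <- ifelse(beta > x_95, 1, (beta - x_min) / x_95)
  out <- pmin(pmax(out, 0), 1)
  attr(out, "x_min") <- x_min
  attr(out, "x_95") <- x_95
  out
}

#' Hierarchical clustering of diseases from the similarity matrix
#'
#' Agglomerative clustering (average linkage by default) on the distance
#' `1 - s_m`, cut into `k` groups. Deterministic given the input matrix.
#'
#' @param sim_matrix Symmetric similarity matrix from [similarity_matrix()].
#' @param k Number of clusters (`2 <= k <= n`).
#' @param linkage Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return Named integer vector of cluster labels.
#' @export
cluster_diseases <- function(sim_matrix, k, linkage = "average") {
  sim_matrix <- as.matrix(sim_matrix)
  n <- nrow(sim_matrix)
  stopifnot(isSymmetric(unname(sim_matrix)))
  if (k > n) stop("k (", k, ") exceeds the number of diseases (", n, ")")
  hc <- hclust(as.dist(1 - sim_matrix), method = linkage)
  cutree(hc, k = k)
}

#' Cluster-specific tissues by one-sided rank-sum tests
#'
#' For each cluster and tissue, tests whether the cluster's normalized
#' coefficients exceed those of the comparison group: either all diseases
#' outside the cluster (`comparison = "rest"`, default) or the other
#' cluster with the highest mean normalized coefficient for that tissue
#' (`comparison = "next_highest"`). The `top_n` tissues with the smallest
#' p-values are reported per cluster; p ties are broken by the median
#' difference (larger effect first). Clusters of size one are skipped with
#' a warning.
#'
#' @param x_norm Diseases x tissues matrix of normalized coefficients (rows
#'   from [normalize_coefficients()]).
#' @param labels Cluster labels aligned with the rows of `x_norm`.
#' @param top_n Number of tissues reported per cluster (default 5).
#' @param comparison Comparison group, see above.
#' @return Data frame with columns `cluster`, `rank`, `tissue`, `p_value`,
#'   `median_diff`.
#' @export
cluster_specific_tissues <- function(x_norm, labels, top_n = 5,
                                     comparison = c("rest", "next_highest")) {
  comparison <- match.arg(comparison)
  x_norm <- as.matrix(x_norm)
  stopifnot(nrow(x_norm) == length(labels))
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  out <- list()
  for (cl in sort(unique(labels))) {
    inside <- labels == cl
    if (sum(inside) < 2L) {
      warning("cluster ", cl, " has a single member; tests skipped")
      next
    }
    res <- lapply(colnames(x_norm), function(tissue) {
      x_in <- x_norm[inside, tissue]
      if (comparison == "rest") {
        x_out <- x_norm[!inside, tissue]
      } else {
        others <- setdiff(unique(labels), cl)
        mu <- vapply(others, function(o) mean(x_norm[labels == o, tissue]),
                     numeric(1L))
        x_out <- x_norm[labels == others[which.max(mu)], tissue]
      }
      p <- suppressWarnings(
        wilcox.test(x_in, x_out, alternative = "greater")$p.value
      )
      data.frame(cluster = cl, tissue = tissue, p_value = p,
                 median_diff = median(x_in) - median(x_out),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res <- res[order(res$p_value, -res$median_diff), , drop = FALSE]
    res <- head(res, top_n)
    res$rank <- seq_len(nrow(res))
    out[[length(out) + 1L]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("cluster", "rank", "tissue", "p_value", "median_diff")]
}

#' Assign each tissue to the cluster where it is most active
#'
#' Per tissue, computes the median normalized coefficient within each
#' cluster and assigns the cluster with the highest median; exact ties go
#' to the lowest cluster index and are flagged.
#'
#' @inheritParams cluster_specific_tissues
#' @return Data frame with columns `tissue`, `cluster`, `tied`.
#' @export
assign_tissue_cluster <- function(x_norm, labels) {
  x_norm <- as.matrix(x_norm)
  stopifnot(nrow(x_norm) == length(labels))
  clusters <- sort(unique(labels))
  med <- vapply(clusters, function(cl) {
    apply(x_norm[labels == cl, , drop = FALSE], 2L, median)
  }, numeric(ncol(x_norm)))
  if (is.null(dim(med))) med <- matrix(med, nrow = 1L) # single-tissue case
  best <- apply(med, 1L, which.max)
  tied <- apply(med, 1L, function(row) sum(row == max(row)) > 1L)
  data.frame(tissue = colnames(x_norm), cluster = clusters[best],
             tied = tied, stringsAsFactors = FALSE, row.names = NULL)
}
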