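test_that("SD shrinkage mixes toward the pooled quantile floor", {
  g <- c(1, 2, 3, 4)
  s <- shrink_sds(g, mix = 0.75, floor_quantile = 0.25)
  expect_equal(attr(s, "m"), 1.75) # linear-interpolation quantile
  expect_equal(s[[2]], 0.75 * 2 + 0.25 * 1.75) # 1.9375
  expect_equal(as.numeric(shrink_sds(g, mix = 0)), rep(1.75, 4))
  expect_equal(as.numeric(shrink_sds(g, mix = 1)), g)
  expect_error(shrink_sds(rep(0, 10)), "floor m is zero")
})

test_that("identical coefficient vectors have similarity one", {
  set.seed(1)
  b <- rnorm(20)
  s <- runif(20, 0.5, 1)
  expect_equal(disease_similarity(b, b, s, s)$s_m, 1)
})

test_that("constant weights reduce to the signed squared Pearson correlation", {
  set.seed(2)
  for (i in 1:100) {
    b1 <- rnorm(15); b2 <- rnorm(15)
    sm <- disease_similarity(b1, b2)$s_m
    r <- cor(b1, b2)
    expect_lt(abs(sm - sign(r) * r^2), 1e-12)
  }
})

test_that("weighted similarity matches a weighted-least-squares oracle", {
  set.seed(3)
  for (i in 1:10) {
    d <- 5
    b1 <- rnorm(d); b2 <- rnorm(d)
    s1 <- runif(d, 0.2, 2); s2 <- runif(d, 0.2, 2)
    res <- disease_similarity(b1, b2, s1, s2)
    # oracle: weighted regression of b1 on b2; signed r^2 via lm machinery
    fit <- lm(b1 ~ b2, weights = 1 / (s1 * s2))
    r2 <- summary(fit)$r.squared
    expect_equal(res$s_m, sign(coef(fit)[["b2"]]) * r2, tolerance = 1e-10)
    # symmetric in the two diseases
    expect_equal(res$s_m, disease_similarity(b2, b1, s2, s1)$s_m,
                 tolerance = 1e-12)
  }
})

test_that("similarity is equivariant under positive rescaling", {
  set.seed(4)
  b1 <- rnorm(12); b2 <- rnorm(12)
  s1 <- runif(12, 0.5, 1); s2 <- runif(12, 0.5, 1)
  a <- disease_similarity(b1, b2, s1, s2)$s_m
  b <- disease_similarity(3.7 * b1, 0.2 * b2, s1, s2)$s_m
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("degenerate constant vectors yield zero similarity with a flag", {
  res <- disease_similarity(rep(1, 5), rnorm(5))
  expect_true(res$degenerate)
  expect_equal(res$s_m, 0)
})

fake_estimate <- function(beta, sd = NULL) {
  d <- length(beta)
  if (is.null(sd)) sd <- rep(0.1, d)
  names(beta) <- names(sd) <- sprintf("tissue_%03d", seq_len(d))
  structure(list(beta_mean = beta, beta_sd = sd, n_fits = 50L),
            class = "coefficient_estimate")
}

test_that("the similarity matrix is symmetric with unit diagonal", {
  set.seed(5)
  ests <- lapply(1:4, function(i) fake_estimate(rnorm(30)))
  names(ests) <- paste0("d", 1:4)
  S <- similarity_matrix(ests)
  expect_identical(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 4))
  expect_true(all(abs(S) <= 1))

  # two identical diseases: all ones
  two <- list(a = fake_estimate(1:10 / 10), b = fake_estimate(1:10 / 10))
  expect_equal(unname(similarity_matrix(two)), matrix(1, 2, 2))

  # tissue-axis mismatch is an error
  bad <- fake_estimate(rnorm(29))
  expect_error(similarity_matrix(list(a = ests[[1]], b = bad)), "tissue axis")
})

test_that("shared planted support produces higher similarity than disjoint
           support", {
  wins <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    d <- 40
    base <- c(rep(2, 5), rep(0, d - 5))
    b1 <- base + rnorm(d, sd = 0.3)
    b2 <- base + rnorm(d, sd = 0.3)
    b3 <- c(rep(0, d - 5), rep(2, 5)) + rnorm(d, sd = 0.3)
    S <- similarity_matrix(list(a = fake_estimate(b1), b = fake_estimate(b2),
                                c = fake_estimate(b3)))
    if (S["a", "b"] > max(S["a", "c"], S["b", "c"])) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("genetic correlations combine with size-proportional weights", {
  # one study per disease: the single rg passes through
  one <- combine_genetic_correlation(matrix(0.42), 1000, 2000)
  expect_equal(one$s_g, 0.42)

  # hand-worked example: sizes (100, 300) vs one study, rg = (0.2, 0.6)
  est <- combine_genetic_correlation(matrix(c(0.2, 0.6), nrow = 2),
                                     sizes_i = c(100, 300), sizes_j = 500)
  expect_equal(est$w_tilde_i, c(0.25, 0.75))
  expect_equal(est$s_g, 0.25 * 0.2 + 0.75 * 0.6)

  # equal sizes: simple average
  eq <- combine_genetic_correlation(matrix(c(0.1, 0.3, 0.5, 0.7), 2),
                                    c(10, 10), c(10, 10))
  expect_equal(eq$s_g, mean(c(0.1, 0.3, 0.5, 0.7)))

  # missing rg: excluded with renormalized weights summing to one
  expect_warning(
    mis <- combine_genetic_correlation(matrix(c(0.2, NA), nrow = 2),
                                       c(100, 300), 500),
    "renormalized"
  )
  expect_equal(sum(mis$w), 1)
  expect_equal(mis$s_g, 0.2)
})

test_that("coefficient normalization follows the capped 95%-quantile rule", {
  x <- 0:19
  out <- normalize_coefficients(x)
  expect_equal(attr(out, "x_95"), 18.05)
  expect_equal(out[[11]], 10 / 18.05) # x = 10
  expect_equal(out[[1]], 0) # x = x_min
  expect_equal(out[[20]], 1) # above the 95% quantile
  expect_true(all(out >= 0 & out <= 1))
  expect_error(normalize_coefficients(c(-3, -2, -1)), "not positive")
})

test_that("hierarchical clustering recovers planted blocks and handles
           degenerate k", {
  set.seed(6)
  S <- matrix(0.05, 10, 10)
  S[1:5, 1:5] <- 0.8
  S[6:10, 6:10] <- 0.8
  diag(S) <- 1
  dimnames(S) <- list(paste0("d", 1:10), paste0("d", 1:10))
  labels <- cluster_diseases(S, k = 2)
  expect_length(unique(labels[1:5]), 1L)
  expect_length(unique(labels[6:10]), 1L)
  expect_false(labels[1] == labels[6])

  expect_length(unique(cluster_diseases(S, k = 10)), 10L)
  expect_error(cluster_diseases(S, k = 11), "exceeds")
})

test_that("cluster-specific tissue tests rank a planted tissue first", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    x <- matrix(runif(40 * 10), 40, 10,
                dimnames = list(NULL, paste0("t", 1:10)))
    labels <- rep(c(1, 2), each = 20)
    x[labels == 1, "t7"] <- x[labels == 1, "t7"] + 0.5 # planted shift
    top <- cluster_specific_tissues(x, labels, top_n = 3)
    if (top$tissue[top$cluster == 1 & top$rank == 1] == "t7") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("small-sample rank-sum p-values match exact enumeration", {
  x_in <- c(0.9, 0.8, 0.7, 0.4)
  x_out <- c(0.5, 0.3, 0.2, 0.1)
  x <- matrix(c(x_in, x_out, runif(8)), ncol = 2,
              dimnames = list(NULL, c("focal", "noise")))
  labels <- rep(c(1, 2), each = 4)
  res <- cluster_specific_tissues(x, labels, top_n = 2)
  p_pkg <- res$p_value[res$cluster == 1 & res$tissue == "focal"]
  # enumerate all assignments of ranks to the in-cluster group
  pooled <- c(x_in, x_out)
  r <- rank(pooled)
  combos <- combn(8, 4)
  W_obs <- sum(r[1:4])
  W_null <- apply(combos, 2, function(ix) sum(r[ix]))
  p_oracle <- mean(W_null >= W_obs)
  expect_equal(p_pkg, p_oracle)
})

test_that("tissues are assigned to the cluster with the highest median", {
  x <- matrix(0.1, 9, 3, dimnames = list(NULL, c("a", "b", "c")))
  labels <- rep(1:3, each = 3)
  x[labels == 2, "a"] <- 0.9
  out <- assign_tissue_cluster(x, labels)
  expect_identical(out$cluster[out$tissue == "a"], 2L)
  expect_true(out$tied[out$tissue == "b"]) # all-equal tissue is flagged

  set.seed(7)
  xr <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  lr <- rep(1:2, each = 5)
  got <- assign_tissue_cluster(xr, lr)
  for (t in c("a", "b", "c")) {
    meds <- c(median(xr[lr == 1, t]), median(xr[lr == 2, t]))
    expect_identical(got$cluster[got$tissue == t], which.max(meds))
  }
})

test_that("single-member clusters are skipped with a warning", {
  x <- matrix(runif(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(cluster_specific_tissues(x, c(1, 1, 1, 2), top_n = 2),
                 "single member")
})
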