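test_that("TSS bins are equal-count with sizes differing by at most one", {
  pool <- make_variants(100, seed = 1)
  bins <- bin_by_tss_distance(pool, 50)
  expect_true(all(table(bins) == 2L))

  pool101 <- make_variants(101, seed = 2)
  bins101 <- bin_by_tss_distance(pool101, 50)
  sizes <- as.integer(table(bins101))
  expect_setequal(unique(sizes), c(2L, 3L))
  expect_identical(sum(sizes == 3L), 1L)

  expect_true(all(bin_by_tss_distance(pool, 1) == 1L))
  expect_error(bin_by_tss_distance(pool, 101), "exceeds pool size")

  # bins are ordered by distance: max of bin b <= min of bin b+1
  d_by_bin <- split(pool$dist_tss, bins)
  maxs <- vapply(d_by_bin, max, numeric(1))
  mins <- vapply(d_by_bin, min, numeric(1))
  expect_true(all(maxs[-50] <= mins[-1]))
})

test_that("relative-deviation eligibility follows the SNPsnap arithmetic", {
  pos <- make_variants(1)
  pos$maf <- 0.10
  pool <- make_variants(2, seed = 3)
  pool$id <- c("c_6pct", "c_4pct")
  pool$maf <- c(0.106, 0.104)
  # constrain only maf so the other attributes cannot interfere
  cfg <- match_config("snpsnap", n_controls = 10,
                      tolerances = c(maf = 0.05, gene_density = 100,
                                     dist_tss = 100, ld_partners = 100))
  res <- suppressWarnings(match_controls(pos, pool, config = cfg))
  expect_identical(res$mapping[[pos$id]], "c_4pct") # 6% deviation ineligible
})

test_that("candidate sets equal a brute-force tolerance filter", {
  pos <- make_variants(2, seed = 4)
  pool <- make_variants(20, seed = 5)
  pool$id <- paste0("pool_", pool$id)
  cfg <- match_config("snpsnap", n_controls = 50) # keep all eligibles
  tol <- cfg$tolerances
  oracle <- function(p) {
    dev <- function(a) {
      ap <- p[[a]]
      if (ap == 0) ifelse(pool[[a]] == 0, 0, Inf) else abs(pool[[a]] - ap) / ap
    }
    pool$id[dev("maf") <= tol["maf"] &
            dev("gene_density") <= tol["gene_density"] &
            dev("dist_tss") <= tol["dist_tss"] &
            dev("ld_partners") <= tol["ld_partners"]]
  }
  sets <- lapply(seq_len(2), function(i) oracle(pos[i, ]))
  # process one positive at a time so claims cannot shrink the other's set
  for (i in 1:2) {
    res <- suppressWarnings(match_controls(pos[i, ], pool, config = cfg))
    got <- res$mapping[[pos$id[i]]]
    if (length(sets[[i]]) == 0) {
      expect_identical(res$dropped_positives, pos$id[i])
    } else {
      expect_setequal(got, sets[[i]])
    }
  }
})

test_that("fewer eligible candidates than requested are all kept", {
  pos <- make_variants(1, seed = 6)
  pool <- make_variants(7, seed = 7)
  pool$id <- paste0("ctrl_", seq_len(7))
  for (a in c("maf", "gene_density", "dist_tss", "ld_partners")) {
    pool[[a]] <- pos[[a]] # exact matches: always eligible
  }
  res <- suppressWarnings(
    match_controls(pos, pool, config = match_config("snpsnap", n_controls = 10))
  )
  expect_length(res$mapping[[pos$id]], 7L)
})

test_that("empty positives give an empty result", {
  pool <- make_variants(10)
  res <- match_controls(make_variants(0), pool, config = match_config("random"))
  expect_length(res$mapping, 0L)
  expect_length(res$dropped_positives, 0L)
})

test_that("matching is deterministic, controls are globally unique and pass
           their tolerance audit", {
  pos <- make_variants(15, seed = 8)
  pool <- simulate_control_pool(pos, n_background = 300, seed = 9)
  cfg <- match_config("snpsnap", n_controls = 10, rng_seed = 11)
  res1 <- suppressWarnings(match_controls(pos, pool, config = cfg))
  res2 <- suppressWarnings(match_controls(pos, pool, config = cfg))
  expect_identical(res1$mapping, res2$mapping)
  expect_identical(res1$audit, res2$audit)

  ctrl <- unlist(res1$mapping)
  expect_false(anyDuplicated(ctrl) > 0)
  expect_length(intersect(ctrl, pos$id), 0L)
  # audit: every returned control within every tolerance window
  expect_true(all(res1$audit$dev_maf <= cfg$tolerances["maf"]))
  expect_true(all(res1$audit$dev_gene_density <= cfg$tolerances["gene_density"]))
  expect_true(all(res1$audit$dev_dist_tss <= cfg$tolerances["dist_tss"]))
  expect_true(all(res1$audit$dev_ld_partners <= cfg$tolerances["ld_partners"]))
  # accounting: every positive either mapped or dropped
  expect_setequal(c(names(res1$mapping), res1$dropped_positives), pos$id)
})

test_that("catalog variants are never used as controls", {
  pos <- make_variants(3, seed = 10)
  pool <- make_variants(30, seed = 11)
  pool$id <- paste0("pool_", seq_len(30))
  catalog <- c(pool$id[1:5], pos$id)
  res <- suppressWarnings(
    match_controls(pos, pool, catalog_ids = catalog,
                   config = match_config("random", n_controls = 5))
  )
  expect_length(intersect(unlist(res$mapping), catalog), 0L)
})

test_that("random matching reproduces the pool attribute distribution", {
  pos <- make_variants(100, seed = 12)
  pool <- make_variants(5000, seed = 13)
  pool$id <- paste0("pool_", seq_len(5000))
  res <- suppressWarnings(
    match_controls(pos, pool, config = match_config("random", n_controls = 10,
                                                    rng_seed = 14))
  )
  ctrl <- unlist(res$mapping)
  ks <- suppressWarnings(
    stats::ks.test(pool$maf[pool$id %in% ctrl], pool$maf)
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("tss strategy draws controls from the positive's distance bin", {
  pool <- make_variants(200, seed = 15)
  pool$id <- paste0("pool_", seq_len(200))
  cfg <- match_config("tss", n_controls = 5, n_bins = 10, rng_seed = 16)
  bins <- bin_by_tss_distance(pool, 10)
  pos <- make_variants(1, seed = 17)
  pos$dist_tss <- sort(pool$dist_tss)[105] # lands mid-pool
  res <- match_controls(pos, pool, config = cfg)
  got_bins <- bins[match(res$mapping[[pos$id]], pool$id)]
  expect_length(unique(got_bins), 1L)
  rng <- range(split(pool$dist_tss, bins)[[as.character(got_bins[1])]])
  expect_true(pos$dist_tss >= rng[1] && pos$dist_tss <= rng[2])
})
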