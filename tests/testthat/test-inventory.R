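test_that("non-coding filter removes coding classes and keeps the rest", {
  v <- make_variants(4)
  v$functional_class <- c("intron_variant", "missense_variant",
                          "frameshift_variant", "intergenic_variant")
  out <- filter_noncoding(v)
  expect_setequal(out$id, v$id[c(1, 4)])
  expect_identical(nrow(filter_noncoding(v[0, ])), 0L)

  v$functional_class[1] <- NA
  expect_warning(out2 <- filter_noncoding(v), "without a functional-class")
  expect_true(v$id[1] %in% out2$id)
})

test_that("QC filter enforces the HLA window and the strict MAF threshold", {
  v <- make_variants(6, chrom = rep(1L, 6))
  v$maf <- c(0.005, 0.01, 0.0099, 0.3, 0.011, NA)
  expect_warning(
    suppressMessages(out <- apply_qc_filters(v)),
    "without MAF"
  )
  # maf == 0.01 is retained (strict '<'), 0.005 / 0.0099 / NA removed
  expect_setequal(out$id, v$id[c(2, 4, 5)])
  expect_identical(attr(out, "n_removed"), 3L)

  # 10 variants, 3 planted inside the HLA window -> 7 retained
  h <- make_variants(10, seed = 2, chrom = rep(6L, 10))
  h$pos <- c(28477797, 30000000, 33448354, # inside (boundaries inclusive)
             seq(1e6, 7e6, length.out = 7))
  brute <- !(h$pos >= 28477797 & h$pos <= 33448354)
  out_h <- suppressMessages(apply_qc_filters(h))
  expect_identical(nrow(out_h), 7L)
  expect_setequal(out_h$id, h$id[brute])
})

test_that("annotation propagation unions descendant sets up the ontology", {
  tab <- annotation_table(c("child", "child", "child", "parent", "parent"),
                          c("v1", "v2", "v3", "v3", "v4"))
  edges <- data.frame(child = "child", parent = "parent")
  out <- propagate_annotations(tab, edges)
  expect_setequal(out$variant_id[out$term_id == "parent"],
                  c("v1", "v2", "v3", "v4"))

  # no edges: identity
  expect_identical(propagate_annotations(tab, NULL), tab)

  # chain A -> B -> C: C receives A's variants transitively
  tab2 <- annotation_table(c("A", "B", "C"), c("a1", "b1", "c1"))
  chain <- data.frame(child = c("A", "B"), parent = c("B", "C"))
  out2 <- propagate_annotations(tab2, chain)
  expect_setequal(out2$variant_id[out2$term_id == "C"], c("a1", "b1", "c1"))

  # cycle: hard error naming an edge
  expect_error(
    propagate_annotations(tab2, data.frame(child = c("A", "B"),
                                           parent = c("B", "A"))),
    "cycle"
  )
})

test_that("propagation is monotone and idempotent on random ontologies", {
  for (seed in 1:5) {
    ont <- simulate_ontology(depth = 3, branching = 2, n_per_leaf = 4,
                             seed = seed)
    once <- propagate_annotations(ont$table, ont$edges)
    twice <- propagate_annotations(once, ont$edges)
    sets1 <- lapply(split(once$variant_id, once$term_id), sort)
    sets2 <- lapply(split(twice$variant_id, twice$term_id), sort)
    expect_identical(sets1, sets2)
    for (i in seq_len(nrow(ont$edges))) {
      child_set <- sets1[[ont$edges$child[i]]]
      parent_set <- sets1[[ont$edges$parent[i]]]
      if (!is.null(child_set)) {
        expect_true(all(child_set %in% parent_set))
      }
    }
  }
})

test_that("term selection applies the minimum-SNV threshold inclusively", {
  sizes <- c(t1 = 50, t2 = 100, t3 = 150, t4 = 99, t5 = 101)
  tab <- annotation_table(rep(names(sizes), sizes),
                          unlist(lapply(names(sizes), function(t) {
                            paste0(t, "_v", seq_len(sizes[[t]]))
                          })))
  out <- select_terms(tab, min_snvs = 100)
  expect_setequal(out$term_id, c("t2", "t3", "t5"))
  expect_identical(out$n_snvs[out$term_id == "t2"], 100L)
})

test_that("LD blocks are r2-threshold components with min-p representatives", {
  v <- make_variants(4)
  v$id <- c("a", "b", "c", "d")
  v$assoc_p <- c(1e-8, 1e-12, 1e-5, 1e-3)
  pairs <- data.frame(id1 = c("a", "b", "c"), id2 = c("b", "c", "d"),
                      r2 = c(0.6, 0.7, 0.4))
  out <- assign_ld_blocks(v, pairs)
  blocks <- split(out$blocks$id, out$blocks$ld_block)
  expect_true(any(vapply(blocks, function(b) setequal(b, c("a", "b", "c")),
                         logical(1))))
  abc_block <- out$blocks$ld_block[out$blocks$id == "a"]
  expect_identical(out$representatives$id[out$representatives$ld_block == abc_block],
                   "b")
  # r2 = 0.4 creates no edge: d is its own block
  expect_false(out$blocks$ld_block[out$blocks$id == "d"] == abc_block)

  # no pairs: every variant its own representative
  solo <- assign_ld_blocks(v, NULL)
  expect_setequal(solo$representatives$id, v$id)

  expect_warning(
    assign_ld_blocks(v, data.frame(id1 = "a", id2 = "zz", r2 = 0.9)),
    "unknown"
  )
})

test_that("every LD-block representative attains the block's minimum p-value", {
  set.seed(9)
  v <- make_variants(40, seed = 9)
  pairs <- data.frame(id1 = sample(v$id, 60, replace = TRUE),
                      id2 = sample(v$id, 60, replace = TRUE),
                      r2 = runif(60))
  pairs <- pairs[pairs$id1 != pairs$id2, ]
  out <- assign_ld_blocks(v, pairs)
  for (b in unique(out$blocks$ld_block)) {
    members <- out$blocks$id[out$blocks$ld_block == b]
    rep_id <- out$representatives$id[out$representatives$ld_block == b]
    expect_equal(v$assoc_p[v$id == rep_id],
                 min(v$assoc_p[v$id %in% members]))
  }
})

test_that("temporal split excludes near-train test variants per chromosome", {
  v <- make_variants(4)
  v$id <- c("tr1", "te_near", "te_far", "te_otherchrom")
  v$chrom <- c(1L, 1L, 1L, 2L)
  v$pos <- c(10000L, 10900L, 20000L, 10900L)
  v$date_added <- as.Date(c("2015-01-01", "2017-01-01", "2017-01-01",
                            "2017-01-01"))
  tab <- annotation_table(rep("term", 4), v$id)
  sp <- temporal_split(tab, v, cutoff_date = "2016-05-28",
                       min_train = 1, min_test = 1)
  expect_false("te_near" %in% sp$test$variant_id) # distance 900 < 1000
  expect_true("te_far" %in% sp$test$variant_id)
  expect_true("te_otherchrom" %in% sp$test$variant_id)
  expect_true("tr1" %in% sp$train$variant_id)
})

test_that("temporal split drops terms below the train/test thresholds and
           sends undated variants to train", {
  set.seed(3)
  v <- make_variants(90, seed = 3)
  v$chrom <- rep(1:9, each = 10) # spread out: no exclusion-radius collisions
  v$pos <- rep(seq(1e6, 10e6, length.out = 10), times = 9) + 1e7 * rep(1:9, each = 10)
  v$date_added <- rep(as.Date(c("2015-01-01", "2017-01-01")), c(19, 71))
  tab <- annotation_table(rep("term", 90), v$id)
  # 19 train / 71 test at thresholds (20, 50): dropped
  sp <- temporal_split(tab, v, cutoff_date = "2016-05-28")
  expect_identical(sp$retained_terms, character(0))
  # at thresholds (19, 50) the term is retained
  sp2 <- temporal_split(tab, v, cutoff_date = "2016-05-28", min_train = 19)
  expect_identical(sp2$retained_terms, "term")

  v$date_added[1] <- NA
  expect_warning(
    sp3 <- temporal_split(tab, v, cutoff_date = "2016-05-28", min_train = 1,
                          min_test = 1),
    "without date"
  )
  expect_true(v$id[1] %in% sp3$train$variant_id)
  expect_false(v$id[1] %in% sp3$test$variant_id)
})

test_that("QC and non-coding filters commute and never add variants", {
  v <- make_variants(50, seed = 5)
  v$functional_class <- sample(c("intron_variant", "missense_variant"),
                               50, replace = TRUE)
  a <- suppressMessages(apply_qc_filters(filter_noncoding(v)))
  b <- filter_noncoding(suppressMessages(apply_qc_filters(v)))
  expect_setequal(a$id, b$id)
  expect_lte(nrow(a), nrow(v))
})
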