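#' Default functional classes treated as protein-coding
#'
#' GWAS-Catalog-style labels of variant consequences that overlap or alter
#' protein-coding sequence. Variants carrying one of these labels are removed
#' by [filter_noncoding()].
#'
#' @export
coding_functional_classes <- c(
  "missense_variant",
  "frameshift_variant",
  "stop_gained",
  "stop_lost",
  "start_lost",
  "synonymous_variant",
  "coding_sequence_variant",
  "inframe_insertion",
  "inframe_deletion"
)

#' Extended MHC / HLA region (hg19)
#'
#' Default interval used by [apply_qc_filters()] to drop variants in the
#' human leukocyte antigen region, where extreme LD makes control matching
#' unreliable. Coordinates are 1-based inclusive on chromosome 6.
#'
#' @export
hla_region_hg19 <- c(chrom = 6, start = 28477797, end = 33448354)

check_variants <- function(variants, required = c("id", "chrom", "pos")) {
  stopifnot(is.data.frame(variants))
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0L) {
    stop("variant table lacks required column(s): ", paste(missing, collapse = ", "))
  }
  invisible(variants)
}

#' Remove variants annotated as protein-coding
#'
#' Keeps variants whose `functional_class` is not in `coding_classes`.
#' Unlabeled variants (`NA` or empty class) are presumed non-coding and kept,
#' with a warning.
#'
#' @param variants Data frame of variants with a `functional_class` column.
#' @param coding_classes Character vector of classes to exclude.
#' @return The retained subset of `variants`.
#' @export
filter_noncoding <- function(variants, coding_classes = coding_functional_classes) {
  check_variants(variants, c("id", "functional_class"))
  cls <- variants$functional_class
  unlabeled <- is.na(cls) | !nzchar(as.character(cls))
  if (any(unlabeled)) {
    warning(sum(unlabeled), " variant(s) without a functional-class label; ",
            "kept (presumed non-coding)")
  }
  keep <- unlabeled | !(as.character(cls) %in% coding_classes)
  variants[keep, , drop = FALSE]
}

#' Quality-control filters: HLA region and minor allele frequency
#'
#' Removes variants inside the HLA interval and variants with
#' `maf < maf_min` (strict inequality: a variant at exactly `maf_min` is
#' kept). Variants with a missing MAF are removed with a warning, since they
#' cannot be matched to controls on allele frequency.
#'
#' @param variants Data frame with `chrom`, `pos` and `maf` columns.
#' @param hla_interval Numeric vector `c(chrom, start, end)`, 1-based
#'   inclusive. Defaults to the extended MHC on hg19.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @return Retained variants; the number removed is reported via `message()`
#'   and attached as attribute `"n_removed"`.
#' @export
apply_qc_filters <- function(variants, hla_interval = hla_region_hg19,
                             maf_min = 0.01) {
  check_variants(variants, c("id", "chrom", "pos", "maf"))
  stopifnot(length(hla_interval) == 3L)
  in_hla <- variants$chrom == hla_interval[[1]] &
    variants$pos >= hla_interval[[2]] & variants$pos <= hla_interval[[3]]
  no_maf <- is.na(variants$maf)
  if (any(no_maf)) {
    warning(sum(no_maf), " variant(s) without MAF removed")
  }
  low_maf <- !no_maf & variants$maf < maf_min
  drop <- in_hla | no_maf | low_maf
  out <- variants[!drop, , drop = FALSE]
  message("apply_qc_filters: removed ", sum(drop), " of ", nrow(variants),
          " variants (", sum(in_hla), " HLA, ", sum(low_maf), " low-MAF, ",
          sum(no_maf), " missing MAF)")
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Construct an annotation table
#'
#' A long-format table of (ontology term, variant) pairs; duplicates are
#' collapsed.
#'
#' @param term_id Character vector of ontology term identifiers.
#' @param variant_id Character vector of variant identifiers (same length).
#' @return Data frame with columns `term_id`, `variant_id` and class
#'   `annotation_table`.
#' @export
annotation_table <- function(term_id, variant_id) {
  stopifnot(length(term_id) == length(variant_id))
  out <- unique(data.frame(term_id = as.character(term_id),
                           variant_id = as.character(variant_id),
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}

ontology_graph <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[[1]]), to = as.character(edges[[2]])),
    directed = TRUE
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- which(comp$csize > 1L)[1L]
    members <- names(comp$membership)[comp$membership == bad]
    sub <- igraph::induced_subgraph(g, members)
    e <- igraph::as_edgelist(sub)[1L, ]
    stop("ontology edges contain a cycle (e.g., edge ", e[1L], " -> ", e[2L], ")")
  }
  g
}

#' Propagate variant annotations from child to parent terms
#'
#' Each term's variant set becomes the union of its own set and the sets of
#' all its ontology descendants (a child term is the more specific one; edges
#' point child -> parent). Terms present only in the ontology inherit their
#' descendants' variants as well.
#'
#' @param table An [annotation_table()].
#' @param edges Data frame of directed edges, first column child term, second
#'   column parent term. Must be acyclic.
#' @return A propagated [annotation_table()].
#' @export
propagate_annotations <- function(table, edges) {
  stopifnot(inherits(table, "data.frame"))
  if (is.null(edges) || nrow(edges) == 0L) {
    return(annotation_table(table$term_id, table$variant_id))
  }
  g <- ontology_graph(edges)
  sets <- split(table$variant_id, table$term_id)
  # children before parents: process terms in topological order of the
  # child -> parent graph, folding each child's set into its parents
  ord <- names(igraph::topo_sort(g, mode = "out"))
  el <- igraph::as_edgelist(g)
  parents_of <- split(el[, 2L], el[, 1L])
  for (term in ord) {
    own <- sets[[term]]
    if (is.null(own)) next
    for (p in parents_of[[term]]) {
      sets[[p]] <- union(sets[[p]], own)
    }
  }
  annotation_table(rep(names(sets), lengths(sets)), unlist(sets, use.names = FALSE))
}

#' Select ontology terms with enough annotated variants
#'
#' @param table An [annotation_table()] (typically post-propagation).
#' @param min_snvs Minimum number of distinct variants per term (default 100).
#' @return Data frame with columns `term_id` and `n_snvs`, restricted to
#'   terms with `n_snvs >= min_snvs`, ordered by decreasing count.
#' @export
select_terms <- function(table, min_snvs = 100) {
  counts <- vapply(split(table$variant_id, table$term_id),
                   function(v) length(unique(v)), integer(1L))
  out <- data.frame(term_id = names(counts), n_snvs = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[out$n_snvs >= min_snvs, , drop = FALSE]
  out <- out[order(-out$n_snvs, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group variants into LD blocks and pick representative variants
#'
#' Blocks are the connected components of the graph whose edges connect
#' variant pairs with `r2 >= r2_min`. The representative of each block is the
#' variant with the smallest association p-value; ties are broken by the
#' lexicographically smaller id so results are deterministic.
#'
#' @param variants Data frame with `id` and `assoc_p` columns.
#' @param ld_pairs Data frame with columns `id1`, `id2`, `r2`. Pairs that
#'   reference unknown variants are ignored with a warning.
#' @param r2_min LD threshold (default 0.5).
#' @return List with `blocks` (data frame `id`, `ld_block`) and
#'   `representatives` (data frame `ld_block`, `id`, `assoc_p`).
#' @export
assign_ld_blocks <- function(variants, ld_pairs = NULL, r2_min = 0.5) {
  check_variants(variants, c("id", "assoc_p"))
  ids <- as.character(variants$id)
  stopifnot(!anyDuplicated(ids))
  if (is.null(ld_pairs) || nrow(ld_pairs) == 0L) {
    edges <- matrix(character(0L), ncol = 2L)
  } else {
    known <- ld_pairs$id1 %in% ids & ld_pairs$id2 %in% ids
    if (any(!known)) {
      warning(sum(!known), " LD pair(s) reference unknown variants; ignored")
      ld_pairs <- ld_pairs[known, , drop = FALSE]
    }
    ld_pairs <- ld_pairs[ld_pairs$r2 >= r2_min, , drop = FALSE]
    edges <- cbind(as.character(ld_pairs$id1), as.character(ld_pairs$id2))
  }
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                     vertices = ids)
  memb <- igraph::components(g)$membership
  blocks <- data.frame(id = names(memb),
                       ld_block = paste0("block_", as.integer(memb)),
                       stringsAsFactors = FALSE)
  blocks <- blocks[match(ids, blocks$id), , drop = FALSE]
  rownames(blocks) <- NULL
  p <- variants$assoc_p[match(blocks$id, ids)]
  reps <- do.call(rbind, lapply(split(seq_len(nrow(blocks)), blocks$ld_block),
    function(idx) {
      ord <- order(p[idx], blocks$id[idx])
      data.frame(ld_block = blocks$ld_block[idx[1L]],
                 id = blocks$id[idx[ord[1L]]],
                 assoc_p = p[idx[ord[1L]]],
                 stringsAsFactors = FALSE)
    }))
  rownames(reps) <- NULL
  list(blocks = blocks, representatives = reps)
}

#' Split annotations into temporally disjoint train and test sets
#'
#' Variants dated after `cutoff_date` form the test pool; all others
#' (including undated variants, which are never allowed to contaminate the
#' test set) form the training pool. Test variants within `exclusion_bp` of
#' any training variant on the same chromosome are discarded. Terms are
#' retained only when they keep at least `min_train` training and `min_test`
#' test variants.
#'
#' @param table An [annotation_table()].
#' @param variants Data frame with `id`, `chrom`, `pos`, `date_added`
#'   (`Date` or coercible).
#' @param cutoff_date Cutoff date; training variants are dated on or before it.
#' @param min_train,min_test Per-term minimum counts (defaults 20 and 50).
#' @param exclusion_bp Exclusion radius in bp around training variants
#'   (default 1000).
#' @return List of class `temporal_split` with elements `train`, `test`
#'   (annotation tables restricted to retained terms), `retained_terms`,
#'   `cutoff_date` and `exclusion_radius_bp`.
#' @export
temporal_split <- function(table, variants, cutoff_date,
                           min_train = 20, min_test = 50,
                           exclusion_bp = 1000) {
  check_variants(variants, c("id", "chrom", "pos", "date_added"))
  cutoff_date <- as.Date(cutoff_date)
  dates <- as.Date(variants$date_added)
  if (anyNA(dates)) {
    warning(sum(is.na(dates)), " variant(s) without date assigned to train")
  }
  is_train <- is.na(dates) | dates <= cutoff_date
  train_ids <- as.character(variants$id[is_train])
  cand <- variants[!is_train, , drop = FALSE]

  # drop test candidates too close to a training variant on the same chromosome
  keep <- rep(TRUE, nrow(cand))
  for (ch in unique(cand$chrom)) {
    tp <- sort(variants$pos[is_train & variants$chrom == ch])
    if (length(tp) == 0L) next
    ci <- which(cand$chrom == ch)
    lo <- findInterval(cand$pos[ci], tp)
    d_left <- ifelse(lo >= 1L, cand$pos[ci] - tp[pmax(lo, 1L)], Inf)
    d_right <- ifelse(lo < length(tp), tp[pmin(lo + 1L, length(tp))] - cand$pos[ci], Inf)
    keep[ci] <- pmin(d_left, d_right) >= exclusion_bp
  }
  test_ids <- as.character(cand$id[keep])

  train_tab <- table[table$variant_id %in% train_ids, , drop = FALSE]
  test_tab <- table[table$variant_id %in% test_ids, , drop = FALSE]
  n_train <- vapply(split(train_tab$variant_id, train_tab$term_id),
                    function(v) length(unique(v)), integer(1L))
  n_test <- vapply(split(test_tab$variant_id, test_tab$term_id),
                   function(v) length(unique(v)), integer(1L))
  terms <- union(names(n_train), names(n_test))
  ok <- vapply(terms, function(t) {
    isTRUE(n_train[t] >= min_train) && isTRUE(n_test[t] >= min_test)
  }, logical(1L))
  retained <- sort(terms[ok])

  train_tab <- train_tab[train_tab$term_id %in% retained, , drop = FALSE]
  test_tab <- test_tab[test_tab$term_id %in% retained, , drop = FALSE]
  out <- list(
    train = annotation_table(train_tab$term_id, train_tab$variant_id),
    test = annotation_table(test_tab$term_id, test_tab$variant_id),
    retained_terms = retained,
    cutoff_date = cutoff_date,
    exclusion_radius_bp = exclusion_bp
  )
  class(out) <- "temporal_split"
  out
}

#' @export
print.temporal_split <- function(x, ...) {
  cat("Temporal split (cutoff ", format(x$cutoff_date),
      ", exclusion radius ", x$exclusion_radius_bp, " bp)\n", sep = "")
  cat("  terms retained: ", length(x$retained_terms), "\n", sep = "")
  cat("  train annotations: ", nrow(x$train),
      " | test annotations: ", nrow(x$test), "\n", sep = "")
  invisible(x)
}
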