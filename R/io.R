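# Readers and writers for the tab-separated interchange formats.

#' Read a GWAS-Catalog-style association table
#'
#' Tab-separated with a header row; columns are located by name through
#' `col_map`, whose names are the canonical internal fields and whose
#' values are the column names in the file. Fields absent from `col_map`
#' (or mapped to `NA`) are filled with `NA`.
#'
#' @param file Path to the TSV.
#' @param col_map Named character vector mapping internal fields
#'   (`id`, `chrom`, `pos`, `term_id`, `assoc_p`, `date_added`,
#'   `functional_class`, `maf`) to file columns. Defaults assume canonical
#'   internal names.
#' @return List with `variants` (one row per distinct variant) and `table`
#'   (an [annotation_table()] of term-variant pairs, when a term column is
#'   mapped).
#' @export
read_associations <- function(file,
                              col_map = c(id = "id", chrom = "chrom",
                                          pos = "pos", term_id = "term_id",
                                          assoc_p = "assoc_p",
                                          date_added = "date_added",
                                          functional_class = "functional_class",
                                          maf = "maf")) {
  raw <- read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  get_col <- function(field) {
    src <- unname(col_map[field])
    if (is.na(src) || !(src %in% names(raw))) return(NULL)
    raw[[src]]
  }
  fields <- c("id", "chrom", "pos", "assoc_p", "date_added",
              "functional_class", "maf")
  variants <- data.frame(id = as.character(get_col("id")),
                         stringsAsFactors = FALSE)
  for (f in setdiff(fields, "id")) {
    v <- get_col(f)
    variants[[f]] <- if (is.null(v)) NA else v
  }
  if (!is.null(variants$date_added)) {
    variants$date_added <- as.Date(variants$date_added)
  }
  term <- get_col("term_id")
  tab <- if (!is.null(term)) annotation_table(term, variants$id) else NULL
  variants <- variants[!duplicated(variants$id), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, table = tab)
}

#' Read ontology edges
#'
#' Accepts either a two-column TSV (child, parent; header optional,
#' detected) or an OBO file, from which `is_a` relations are extracted as
#' child -> parent edges.
#'
#' @param file Path to the edge list or OBO file.
#' @return Data frame with columns `child`, `parent`.
#' @export
read_ontology_edges <- function(file) {
  first <- readLines(file, n = 50L)
  if (any(grepl("^\\[Term\\]", first)) || grepl("\\.obo$", file)) {
    return(read_obo_isa(file))
  }
  df <- read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                   header = FALSE)
  if (identical(tolower(as.character(df[1L, 1L])), "child")) {
    df <- df[-1L, , drop = FALSE]
  }
  data.frame(child = as.character(df[[1L]]), parent = as.character(df[[2L]]),
             stringsAsFactors = FALSE)
}

# minimal OBO reader: only [Term] ids and their is_a targets are needed
read_obo_isa <- function(file) {
  lines <- readLines(file)
  child <- NULL
  edges <- list()
  in_term <- FALSE
  for (line in lines) {
    if (grepl("^\\[", line)) {
      in_term <- grepl("^\\[Term\\]", line)
      child <- NULL
    } else if (in_term && grepl("^id:", line)) {
      child <- trimws(sub("^id:", "", line))
    } else if (in_term && grepl("^is_a:", line) && !is.null(child)) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", line)))
      edges[[length(edges) + 1L]] <- c(child, parent)
    }
  }
  if (length(edges) == 0L) {
    return(data.frame(child = character(0), parent = character(0)))
  }
  m <- do.call(rbind, edges)
  data.frame(child = m[, 1L], parent = m[, 2L], stringsAsFactors = FALSE)
}

#' Write an annotation table as TSV
#'
#' @param table An [annotation_table()].
#' @param file Output path.
#' @export
write_annotation_table <- function(table, file) {
  write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a variant pool table
#'
#' TSV with named attribute columns (`id`, `maf`, `dist_tss`,
#' `gene_density`, `ld_partners`, optionally `chrom`, `pos`, `ld_block`).
#'
#' @param file Path to the TSV.
#' @return Data frame.
#' @export
read_variant_pool <- function(file) {
  read.delim(file, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a match result as TSV
#'
#' One row per (positive, control) pair with the control's rank.
#'
#' @param result A `match_result`.
#' @param file Output path.
#' @export
write_match_result <- function(result, file) {
  stopifnot(inherits(result, "match_result"))
  write.table(result$audit[, c("positive_id", "control_id", "rank")],
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a variants x tissues score matrix from TSV
#'
#' First column holds variant ids; remaining columns are tissue contexts.
#'
#' @param file Path to the TSV.
#' @return A [tissue_score_matrix()].
#' @export
read_score_matrix <- function(file) {
  df <- read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  tissue_score_matrix(m)
}

#' Write a variants x tissues score matrix as TSV
#'
#' @param X Score matrix with row names.
#' @param file Output path.
#' @export
write_score_matrix <- function(X, file) {
  df <- data.frame(variant_id = rownames(X), as.matrix(X),
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
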