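#' Simulation configuration
#'
#' Study conditions for synthetic benchmark data. Defaults mirror the
#' design of the real benchmark: ten matched controls per disease-associated
#' variant (prevalence 1/11), 127 tissue/cell-type contexts, 22 autosomes,
#' and a sparse planted tissue support driving labels through the logistic
#' aggregation model. Tissue scores are right-skewed bounded draws
#' (Beta(1, 4)), emulating accessibility signal that is mostly closed with
#' an open tail; planted effects of 3 on the logit scale correspond to a
#' roughly 20-fold odds increase over a tissue's full score range, a strong
#' but realistic open-chromatin enrichment.
#'
#' @param n_pos Number of disease-associated variants (default 500).
#' @param n_ctrl_per_pos Controls per positive (default 10).
#' @param d_tissues Number of tissue contexts (default 127).
#' @param planted_support Indices of causal tissues (default 1:3).
#' @param planted_beta Logit-scale effect sizes on the support (default 3
#'   each).
#' @param baseline_alpha Non-negative coefficient on the tissue-mean column
#'   (default 1).
#' @param noise_shape1,noise_shape2 Beta parameters of the score noise
#'   (default 1 and 4).
#' @param n_chromosomes Number of chromosomes (default 22).
#' @param seed Integer seed; fully determines the generated data.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_pos = 500, n_ctrl_per_pos = 10,
                              d_tissues = 127,
                              planted_support = 1:3,
                              planted_beta = rep(3, length(planted_support)),
                              baseline_alpha = 1,
                              noise_shape1 = 1, noise_shape2 = 4,
                              n_chromosomes = 22, seed = 1L) {
  stopifnot(n_ctrl_per_pos >= 1, baseline_alpha >= 0,
            length(planted_beta) == length(planted_support),
            all(planted_support >= 1), all(planted_support <= d_tissues))
  structure(list(n_pos = as.integer(n_pos),
                 n_ctrl_per_pos = as.integer(n_ctrl_per_pos),
                 d_tissues = as.integer(d_tissues),
                 planted_support = as.integer(planted_support),
                 planted_beta = planted_beta,
                 baseline_alpha = baseline_alpha,
                 noise_shape1 = noise_shape1, noise_shape2 = noise_shape2,
                 n_chromosomes = as.integer(n_chromosomes),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

simulate_variant_attributes <- function(n, n_chromosomes, labels) {
  data.frame(
    id = sprintf("snv_%06d", seq_len(n)),
    chrom = sample.int(n_chromosomes, n, replace = TRUE),
    pos = sample.int(100000000L, n, replace = TRUE),
    maf = runif(n, 0.01, 0.5),
    dist_tss = round(10^runif(n, 2, 6)),
    gene_density = rpois(n, 5),
    ld_partners = rpois(n, 20),
    assoc_p = ifelse(labels == 1L, 10^-runif(n, 5, 30), NA_real_),
    date_added = as.Date("2016-05-28") + sample(-1500:1500, n, replace = TRUE),
    functional_class = sample(c("intron_variant", "intergenic_variant",
                                "regulatory_region_variant", "3_prime_UTR_variant"),
                              n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate a labeled benchmark dataset
#'
#' Draws a variants x tissues score matrix from the configured bounded
#' noise family, then draws labels from the logistic aggregation model with
#' the planted coefficients. The model intercept is calibrated (by root
#' finding, deterministically given the scores) so the expected positive
#' fraction equals `1 / (1 + n_ctrl_per_pos)`, matching the 1:10 benchmark
#' design. Variants also receive chromosomes, positions, dates and
#' control-matching attributes.
#'
#' @param config A [simulation_config()].
#' @return List with `X` (score matrix), `y` (labels), `variants`
#'   (attribute table), `intercept` (calibrated) and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_pos * (1L + config$n_ctrl_per_pos)
  target <- 1 / (1 + config$n_ctrl_per_pos)
  with_seed(config$seed, {
    X <- matrix(rbeta(n * config$d_tissues, config$noise_shape1,
                      config$noise_shape2),
                nrow = n, ncol = config$d_tissues,
                dimnames = list(sprintf("snv_%06d", seq_len(n)),
                                sprintf("tissue_%03d", seq_len(config$d_tissues))))
    eta_raw <- config$baseline_alpha * rowMeans(X) +
      drop(X[, config$planted_support, drop = FALSE] %*% config$planted_beta)
    a0 <- uniroot(function(b) mean(plogis(b + eta_raw)) - target,
                  lower = -60, upper = 60)$root
    y <- rbinom(n, 1L, plogis(a0 + eta_raw))
    tries <- 0L
    while (length(unique(y)) < 2L && tries < 10L) {
      warning("degenerate labels; resampling with shifted intercept")
      a0 <- a0 + if (sum(y) == 0L) 1 else -1
      y <- rbinom(n, 1L, plogis(a0 + eta_raw))
      tries <- tries + 1L
    }
    variants <- simulate_variant_attributes(n, config$n_chromosomes, y)
    list(X = tissue_score_matrix(X), y = y, variants = variants,
         intercept = a0, config = config)
  })
}

#' Simulate a collection of disease datasets with group structure
#'
#' Diseases in the same group share the planted tissue support (with
#' effect sizes jittered by up to 20% per disease); supports are disjoint
#' across groups. Used to exercise the similarity analysis: within-group
#' disease pairs should score high, between-group pairs low.
#'
#' @param n_diseases Number of diseases.
#' @param groups Integer vector of length `n_diseases` assigning each
#'   disease to a group (default: all in one group).
#' @param config Base [simulation_config()]; per-disease seeds and supports
#'   are derived from it.
#' @return Named list of [simulate_dataset()] results, with the per-disease
#'   support attached to each element as `planted_support`.
#' @export
simulate_disease_collection <- function(n_diseases, groups = rep(1L, n_diseases),
                                        config = simulation_config()) {
  stopifnot(length(groups) == n_diseases)
  group_ids <- sort(unique(groups))
  support_size <- length(config$planted_support)
  if (length(group_ids) * support_size > config$d_tissues) {
    stop("disjoint supports for ", length(group_ids), " groups of size ",
         support_size, " exceed d_tissues = ", config$d_tissues)
  }
  supports <- lapply(seq_along(group_ids), function(g) {
    seq.int((g - 1L) * support_size + 1L, g * support_size)
  })
  names(supports) <- group_ids
  seeds <- derive_seeds(config$seed, n_diseases)
  jitters <- with_seed(config$seed + 1L,
                       matrix(runif(n_diseases * support_size, 0.8, 1.2),
                              nrow = n_diseases))
  out <- lapply(seq_len(n_diseases), function(i) {
    cfg <- config
    cfg$planted_support <- supports[[as.character(groups[i])]]
    cfg$planted_beta <- config$planted_beta * jitters[i, ]
    cfg$seed <- seeds[i]
    ds <- simulate_dataset(cfg)
    ds$planted_support <- cfg$planted_support
    ds$group <- groups[i]
    ds
  })
  names(out) <- sprintf("disease_%02d", seq_len(n_diseases))
  out
}

#' Simulate a balanced ontology with leaf-annotated variants
#'
#' Builds a balanced tree of the given depth and branching factor (edges
#' child -> parent) and annotates `n_per_leaf` fresh variants at each leaf,
#' so propagated counts have a closed form: the root receives
#' `branching^depth * n_per_leaf` distinct variants when leaves are
#' disjoint.
#'
#' @param depth Tree depth (root = level 0; leaves = level `depth`).
#' @param branching Children per internal node.
#' @param n_per_leaf Variants annotated per leaf (default 10).
#' @param seed Integer seed (variant id scrambling).
#' @return List with `edges` (child, parent), `table` (annotation table of
#'   the leaf annotations) and `terms`.
#' @export
simulate_ontology <- function(depth, branching, n_per_leaf = 10, seed = 1L) {
  stopifnot(depth >= 1, branching >= 1)
  levels <- lapply(0:depth, function(l) {
    sprintf("T%d_%03d", l, seq_len(branching^l))
  })
  edges <- do.call(rbind, lapply(seq_len(depth), function(l) {
    child <- levels[[l + 1L]]
    parent <- rep(levels[[l]], each = branching)
    data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
  }))
  leaves <- levels[[depth + 1L]]
  n_var <- length(leaves) * n_per_leaf
  ids <- with_seed(seed, sample(sprintf("snv_%06d", seq_len(n_var))))
  tab <- annotation_table(rep(leaves, each = n_per_leaf), ids)
  list(edges = edges, table = tab, terms = unlist(levels))
}

#' Simulate a matched candidate pool for control selection
#'
#' Generates a candidate pool whose attribute distributions mirror the
#' positives': a background of independent draws plus, for each positive,
#' `n_guaranteed` candidates jittered within the default SNPsnap tolerance
#' windows, so every positive has eligible candidates under the default
#' tolerances. The guarantee is audited at generation time.
#'
#' @param positives Variant data frame with the matching attributes.
#' @param n_background Size of the random background pool (default
#'   `20 * nrow(positives)`).
#' @param n_guaranteed Within-tolerance candidates per positive (default
#'   12).
#' @param seed Integer seed.
#' @return Candidate pool data frame with the same attribute columns.
#' @export
simulate_control_pool <- function(positives, n_background = 20 * nrow(positives),
                                  n_guaranteed = 12, seed = 1L) {
  tol <- match_config("snpsnap")$tolerances
  with_seed(seed, {
    bg <- simulate_variant_attributes(n_background, 22L,
                                      rep(0L, n_background))
    jit <- do.call(rbind, lapply(seq_len(nrow(positives)), function(i) {
      p <- positives[i, ]
      m <- n_guaranteed
      # jitter each attribute inside half its tolerance window
      data.frame(
        id = sprintf("pool_g%04d_%02d", i, seq_len(m)),
        chrom = sample.int(22L, m, replace = TRUE),
        pos = sample.int(100000000L, m, replace = TRUE),
        maf = pmin(0.5, pmax(0.01, p$maf * runif(m, 1 - tol["maf"] / 2,
                                                 1 + tol["maf"] / 2))),
        dist_tss = round(p$dist_tss * runif(m, 1 - tol["dist_tss"] / 2,
                                            1 + tol["dist_tss"] / 2)),
        gene_density = round(p$gene_density *
                               runif(m, 1 - tol["gene_density"] / 2,
                                     1 + tol["gene_density"] / 2)),
        ld_partners = round(p$ld_partners *
                              runif(m, 1 - tol["ld_partners"] / 2,
                                    1 + tol["ld_partners"] / 2)),
        assoc_p = NA_real_,
        date_added = as.Date("2016-05-28") + sample(-1500:1500, m, replace = TRUE),
        functional_class = "intron_variant",
        stringsAsFactors = FALSE
      )
    }))
    bg$id <- sprintf("pool_b%06d", seq_len(nrow(bg)))
    pool <- rbind(bg, jit)
    # audit the eligibility guarantee
    for (i in seq_len(nrow(positives))) {
      n_elig <- length(eligible_candidates(positives[i, ], pool, tol))
      if (n_elig < 1L) {
        stop("generation audit failed: positive ", positives$id[i],
             " has no eligible candidate")
      }
    }
    pool
  })
}
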