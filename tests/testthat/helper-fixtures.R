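# Shared fixture builders; everything is generated in code under fixed seeds.

with_seed_local <- dscore:::with_seed

make_variants <- function(n, seed = 1L, chrom = NULL) {
  if (n == 0L) return(make_variants(1L, seed = seed)[0L, , drop = FALSE])
  set.seed(seed)
  data.frame(
    id = sprintf("rs%04d", seq_len(n)),
    chrom = if (is.null(chrom)) sample.int(22L, n, replace = TRUE) else chrom,
    pos = sample.int(1e8L, n),
    maf = runif(n, 0.01, 0.5),
    dist_tss = round(10^runif(n, 2, 6)),
    gene_density = rpois(n, 5),
    ld_partners = rpois(n, 20),
    assoc_p = 10^-runif(n, 3, 20),
    date_added = as.Date("2015-01-01") + sample.int(2000L, n, replace = TRUE),
    functional_class = "intron_variant",
    stringsAsFactors = FALSE
  )
}

# small labeled dataset for model tests
small_dataset <- function(n_pos = 50, d = 8, seed = 1L, beta = c(3, 3),
                          support = 1:2) {
  simulate_dataset(simulation_config(
    n_pos = n_pos, n_ctrl_per_pos = 10, d_tissues = d,
    planted_support = support, planted_beta = beta, seed = seed
  ))
}
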