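# Shared fixtures, simulated once per test session.

the_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 101, ...) {
  sim_config(m_snps = 4000, n_genes = 60, n_sets = 4, genes_per_set = 10,
             n = c(20000, 20000), seed = seed, ...)
}

# A full two-trait scene reused by most module tests.
small_scene <- function() {
  if (is.null(the_cache$scene))
    the_cache$scene <- simulate_study(small_config())
  the_cache$scene
}

# Gene-level scores for trait A of the small scene.
small_gene_scores <- function() {
  if (is.null(the_cache$gene_scores)) {
    sc <- small_scene()
    the_cache$gene_scores <- run_gene_analysis(sc$studies[[1]], sc$genes,
                                               sc$ld)
  }
  the_cache$gene_scores
}

# Brute-force GSEA running-sum oracle: O(N) literal walk down the ranking.
brute_force_es <- function(ranked, set_genes, weight_exponent) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% set_genes
  k <- sum(hit)
  w <- abs(ranked$score)^weight_exponent * hit
  W <- sum(w)
  inc <- if (W > 0) w / W else hit / k
  running <- cumsum(inc - (!hit) / (N - k))
  pos <- max(running)
  neg <- min(running)
  # exact-magnitude ties resolve to the positive excursion
  if (pos >= -neg) pos else neg
}

# A hand-built tiny study table with non-palindromic alleles.
toy_study <- function(m = 400, seed = 11, n = 10000,
                      trait_name = "toy") {
  withr::with_seed(seed, {
    z <- rnorm(m)
    ea <- rep(c("A", "T"), length.out = m)
    oa <- rep(c("G", "C"), length.out = m)
  })
  se <- 1 / sqrt(n)
  new_gwas_study(tibble::tibble(
    chrom = "1", pos = seq_len(m) * 50L, rsid = paste0("rs", seq_len(m)),
    effect_allele = ea, other_allele = oa,
    beta = z * se, se = se, pvalue = 2 * pnorm(-abs(z)), n = n
  ), trait_name = trait_name)
}
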