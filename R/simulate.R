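# Synthetic two-trait GWAS generator: block LD, annotation-specific
# heritability multipliers, configurable cross-trait genetic correlation,
# plus matching gene tracks, gene-set panels and expression-prediction
# weights. Everything downstream is validated against this ground truth.

#' Build a simulation configuration
#'
#' Defines a complete generative scene for a pair of GWAS: the variant grid,
#' the block-LD reference, per-trait heritability, the cross-trait genetic
#' correlation of per-SNP effects, per-annotation heritability multipliers,
#' and the gene/panel/prediction-weight structure used by the downstream
#' layers.
#'
#' Effects are simulated on the standardized-genotype scale: each SNP's true
#' effect pair is bivariate normal with per-SNP variance `(h2/m) * multiplier`
#' and correlation `rg`, then rescaled so the realized per-trait sum of
#' squared effects equals `h2` exactly. Summary statistics are drawn directly
#' in z-space around `sqrt(n) * R beta`, the sampling model all the
#' summary-level estimators in this package assume.
#'
#' @param m_snps Total number of variants.
#' @param blocks Tibble with columns `size` and `rho` describing AR(1) LD
#'   blocks (within-block correlation `rho^|i-j|`, zero across blocks).
#'   Defaults to `m_snps / block_size` equal blocks.
#' @param block_size,rho Used to build `blocks` when it is `NULL`.
#' @param h2 Length-2 numeric, per-trait SNP heritability in `[0,1)`.
#' @param rg True cross-trait genetic correlation in `[-1,1]`.
#' @param n Length-2 numeric, per-trait (effective) sample size.
#' @param annotations Optional tibble with columns `name`, `prop`,
#'   `multiplier`: disjoint random SNP masks covering a `prop` share of SNPs
#'   whose per-SNP effect variance is multiplied by `multiplier` (multipliers
#'   are renormalized to a SNP-weighted mean of 1 so `h2` is preserved).
#' @param enriched_set Optional list `list(set = <name>, multiplier = <x>)`:
#'   instead of a random mask, SNPs falling inside the named gene set's
#'   (padded) gene bodies receive the multiplier. Exercises the full
#'   gene-to-annotation path.
#' @param enriched_set_pad Padding in bp around gene bodies for
#'   `enriched_set` (default 10,000, matching the annotation BED convention).
#' @param n_genes Number of non-overlapping genes tiled over the coordinate
#'   space.
#' @param gene_length Gene body length in bp.
#' @param snp_spacing Distance between adjacent SNPs in bp.
#' @param n_sets Number of gene sets in the panel (default 8).
#' @param genes_per_set Genes sampled into each set.
#' @param set_overlap Optional tibble (`set_a`, `set_b`, `n_shared`) forcing
#'   that many genes of `set_a` to also appear in `set_b` (before
#'   priority deduplication).
#' @param n_tissues Number of tissues with expression-prediction models.
#' @param snps_per_gene SNPs per gene prediction model.
#' @param eqtl_signal Optional list `list(gene = <index>, scale = <x>)`
#'   adding an expression-mediated signal to trait 1 through that gene's
#'   prediction-weight SNPs.
#' @param seed Integer seed; the scene is reproducible bit-for-bit from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(m_snps = 20000, blocks = NULL, block_size = 100,
                       rho = NULL, h2 = c(0.3, 0.3), rg = 0,
                       n = c(50000, 50000), annotations = NULL,
                       enriched_set = NULL, enriched_set_pad = 10000,
                       n_genes = 300, gene_length = 20000,
                       snp_spacing = 1000, n_sets = 8, genes_per_set = 25,
                       set_overlap = NULL, n_tissues = 3, snps_per_gene = 5,
                       eqtl_signal = NULL, seed = 1) {
  if (is.null(blocks)) {
    if (m_snps %% block_size != 0)
      abort("`m_snps` must be a multiple of `block_size` when `blocks` is NULL")
    nb <- m_snps / block_size
    # default LD landscape: block-wise AR(1) with rho cycling over a grid,
    # so per-SNP LD scores vary severalfold across the genome as they do in
    # real data (uniform rho would leave the LD score regression slope
    # nearly unidentified).
    rho <- rho %||% rep_len(seq(0.1, 0.9, length.out = min(20, nb)), nb)
    blocks <- tibble::tibble(size = rep(block_size, nb),
                             rho = rep_len(rho, nb))
  }
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("size", "rho") %in% names(blocks)))
  if (sum(blocks$size) != m_snps)
    abort("block sizes must sum to `m_snps`")
  if (any(abs(blocks$rho) >= 1)) abort("|rho| must be < 1 in every block")
  if (any(blocks$size < 1)) abort("block sizes must be >= 1")
  h2 <- rep_len(h2, 2)
  n <- rep_len(n, 2)
  if (any(h2 < 0) || any(h2 >= 1)) abort("per-trait h2 must lie in [0,1)")
  if (abs(rg) > 1) abort("|rg| must be <= 1")
  if (any(n <= 0)) abort("sample sizes must be positive")
  if (!is.null(annotations)) {
    annotations <- tibble::as_tibble(annotations)
    stopifnot(all(c("name", "prop", "multiplier") %in% names(annotations)))
    if (any(annotations$multiplier <= 0)) abort("multipliers must be > 0")
    if (sum(annotations$prop) > 1)
      abort("annotation proportions must sum to <= 1 (masks are disjoint)")
  }
  span <- m_snps * snp_spacing
  if (n_genes * gene_length > span)
    abort("gene demand exceeds the simulated coordinate space")
  structure(list(
    m_snps = m_snps, blocks = blocks, h2 = h2, rg = rg, n = n,
    annotations = annotations, enriched_set = enriched_set,
    enriched_set_pad = enriched_set_pad,
    n_genes = n_genes, gene_length = gene_length, snp_spacing = snp_spacing,
    n_sets = n_sets, genes_per_set = genes_per_set,
    set_overlap = set_overlap, n_tissues = n_tissues,
    snps_per_gene = snps_per_gene, eqtl_signal = eqtl_signal,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' AR(1) correlation matrix for one LD block
#' @param size Block size.
#' @param rho AR(1) parameter, `|rho| < 1`.
#' @return A `size x size` correlation matrix with entries `rho^|i-j|`.
#' @export
ld_block_matrix <- function(size, rho) {
  if (abs(rho) >= 1) abort("|rho| must be < 1")
  idx <- seq_len(size)
  rho^abs(outer(idx, idx, "-"))
}

#' Build a block-diagonal LD reference
#'
#' @param blocks Tibble with columns `size`, `rho`.
#' @return An object of class `ld_blocks`: block matrices, per-SNP block ids,
#'   and a cache of Cholesky factors reused across simulations.
#' @export
simulate_ld <- function(blocks) {
  blocks <- tibble::as_tibble(blocks)
  if (any(abs(blocks$rho) >= 1)) abort("|rho| must be < 1 in every block")
  sizes <- as.integer(blocks$size)
  key <- paste(sizes, blocks$rho)
  uniq <- !duplicated(key)
  mats <- setNames(
    purrr::map2(sizes[uniq], blocks$rho[uniq], ld_block_matrix),
    key[uniq]
  )
  structure(list(
    sizes = sizes, rhos = blocks$rho, key = key,
    block_id = rep(seq_along(sizes), sizes),
    offset = c(0L, cumsum(sizes)[-length(sizes)]),
    matrices = mats,
    chol_cache = new.env(parent = emptyenv())
  ), class = "ld_blocks")
}

#' @export
print.ld_blocks <- function(x, ...) {
  cat(sprintf("<ld_blocks> %d SNPs in %d blocks (sizes %s; rho %s)\n",
              sum(x$sizes), length(x$sizes),
              paste(unique(range(x$sizes)), collapse = "-"),
              paste(unique(signif(x$rhos, 3)), collapse = ", ")))
  invisible(x)
}

# Correlation matrix of one block.
ld_block <- function(ld, b) ld$matrices[[ld$key[b]]]

# Lower-triangular Cholesky factor of one block, cached.
ld_chol <- function(ld, b) {
  k <- ld$key[b]
  if (is.null(ld$chol_cache[[k]]))
    ld$chol_cache[[k]] <- t(chol(ld$matrices[[k]]))
  ld$chol_cache[[k]]
}

#' Extract the local LD matrix for a set of SNP indices
#'
#' Correlations across blocks are exactly zero, so the result is block
#' diagonal in the order of the (sorted) requested indices.
#'
#' @param ld An `ld_blocks` object.
#' @param idx Integer SNP indices (1-based, genome order).
#' @return A correlation matrix over `idx` (in sorted order).
#' @export
ld_submatrix <- function(ld, idx) {
  idx <- sort(unique(as.integer(idx)))
  k <- length(idx)
  out <- diag(1, k)
  bid <- ld$block_id[idx]
  for (b in unique(bid)) {
    sel <- which(bid == b)
    if (length(sel) > 1L) {
      local <- idx[sel] - ld$offset[b]
      out[sel, sel] <- ld_block(ld, b)[local, local]
    }
  }
  out
}

# Multiplier vector (mean 1) from annotation masks.
build_multipliers <- function(m, masks, multipliers) {
  mult <- rep(1, m)
  if (length(masks)) {
    for (i in seq_along(masks)) mult[masks[[i]]] <- multipliers[[i]]
  }
  mult / mean(mult)
}

#' Draw true per-SNP effect pairs
#'
#' Effects for the two traits are bivariate normal per SNP with variances
#' `(h2/m) * multiplier` and correlation `rg`, then each trait is rescaled so
#' its realized sum of squared effects equals `h2` exactly (so heritability
#' is conserved by construction).
#'
#' @param config A `sim_config`.
#' @param multiplier Optional per-SNP variance multiplier vector (mean 1);
#'   defaults to the flat vector.
#' @param seed Seed for the draw (defaults to a stream derived from the
#'   config seed).
#' @return Tibble with columns `snp`, `multiplier`, `beta1`, `beta2`.
#' @export
simulate_effects <- function(config, multiplier = NULL, seed = NULL) {
  m <- config$m_snps
  multiplier <- multiplier %||% rep(1, m)
  stopifnot(length(multiplier) == m, all(multiplier > 0))
  seed <- seed %||% derive_seed(config$seed, "effects")
  rg <- config$rg
  h2 <- config$h2
  withr::with_seed(seed, {
    x1 <- rnorm(m)
    x2 <- rnorm(m)
  })
  sd1 <- sqrt(h2[1] / m * multiplier)
  sd2 <- sqrt(h2[2] / m * multiplier)
  b1 <- sd1 * x1
  b2 <- sd2 * (rg * x1 + sqrt(1 - rg^2) * x2)
  rescale <- function(b, h2t) {
    ss <- sum(b^2)
    if (h2t == 0 || ss == 0) rep(0, length(b)) else b * sqrt(h2t / ss)
  }
  tibble::tibble(snp = seq_len(m), multiplier = multiplier,
                 beta1 = rescale(b1, h2[1]), beta2 = rescale(b2, h2[2]))
}

# Assign alleles: deterministic seeded draw from non-palindromic pairs.
draw_alleles <- function(m, seed) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  withr::with_seed(seed, i <- sample.int(nrow(pairs), m, replace = TRUE))
  list(effect = pairs[i, 1], other = pairs[i, 2])
}

#' Simulate marginal GWAS summary statistics from true effects
#'
#' Per LD block, the z-vector is drawn from a multivariate normal with mean
#' `sqrt(n) * R beta` and covariance `R` (the classical summary-statistic
#' sampling model); `beta = z/sqrt(n)`, `se = 1/sqrt(n)`, two-sided p from z.
#'
#' @param beta Numeric vector of true standardized effects, one per SNP.
#' @param ld An `ld_blocks` object of matching dimension.
#' @param n Sample size (effective N for case-control designs).
#' @param seed Integer seed.
#' @param variants Optional tibble with `chrom`, `pos`, `rsid`,
#'   `effect_allele`, `other_allele` (generated if omitted).
#' @param trait_name,n_cases,n_controls,genome_build Study metadata.
#' @param snp_spacing SNP spacing in bp used when `variants` is omitted.
#' @return A `gwas_study` tibble of validated variant associations.
#' @export
simulate_sumstats <- function(beta, ld, n, seed, variants = NULL,
                              trait_name = "trait", n_cases = NULL,
                              n_controls = NULL, genome_build = "GRCh37",
                              snp_spacing = 1000) {
  m <- length(beta)
  stopifnot(sum(ld$sizes) == m)
  if (is.null(variants)) {
    al <- draw_alleles(m, derive_seed(seed, "alleles"))
    variants <- tibble::tibble(
      chrom = "1", pos = seq_len(m) * snp_spacing,
      rsid = paste0("rs", seq_len(m)),
      effect_allele = al$effect, other_allele = al$other
    )
  }
  z <- numeric(m)
  withr::with_seed(seed, {
    for (b in seq_along(ld$sizes)) {
      i <- ld$offset[b] + seq_len(ld$sizes[b])
      R <- ld_block(ld, b)
      L <- ld_chol(ld, b)
      z[i] <- sqrt(n) * drop(R %*% beta[i]) + drop(L %*% rnorm(ld$sizes[b]))
    }
  })
  se <- 1 / sqrt(n)
  out <- dplyr::mutate(variants,
    beta = z * se, se = se, pvalue = 2 * pnorm(-abs(z)),
    n = n, z = z, chi2 = z^2
  )
  new_gwas_study(out, trait_name = trait_name, n_cases = n_cases,
                 n_controls = n_controls, n_effective = n,
                 genome_build = genome_build)
}

#' Simulate gene coordinates, a gene-set panel, and prediction weights
#'
#' Non-overlapping gene bodies are tiled over the simulated coordinate space
#' (alternating strand); the panel holds `n_sets` named sets with a priority
#' order and optional forced overlaps; each gene gets a per-tissue
#' expression-prediction weight vector over SNPs inside its body, with SNP
#' covariance taken from the true LD.
#'
#' @param config A `sim_config`.
#' @return List with `genes` (tibble gene_id/chrom/start/end/strand), `panel`
#'   (a `gene_set_panel` tibble: set, priority, gene_id), `weights` (tibble
#'   gene_id/tissue/snp/effect_allele/other_allele/weight), `covariance`
#'   (tibble gene_id/snp1/snp2/value), and `gene_snps` (list of SNP indices
#'   per gene body).
#' @export
simulate_gene_tracks <- function(config) {
  m <- config$m_snps
  spacing <- config$snp_spacing
  span <- m * spacing
  ng <- config$n_genes
  slot <- floor(span / ng)
  if (config$gene_length > slot)
    abort("gene demand exceeds coordinate space: shrink `gene_length` or `n_genes`")
  start <- (seq_len(ng) - 1L) * slot + floor((slot - config$gene_length) / 2) + 1L
  genes <- tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(ng)),
    chrom = "1",
    start = as.integer(start),
    end = as.integer(start + config$gene_length - 1L),
    strand = rep_len(c("+", "-"), ng)
  )

  set_names <- c("housekeeping", "monoaminergic", "neurosteroid",
                 "glutamatergic", "synaptic_pruning", "autophagy",
                 "rna_processing", "immune")
  if (config$n_sets <= length(set_names)) {
    set_names <- set_names[seq_len(config$n_sets)]
  } else {
    set_names <- c(set_names,
                   sprintf("set%02d", seq_len(config$n_sets - length(set_names))))
  }

  withr::with_seed(derive_seed(config$seed, "panel"), {
    pool <- sample(genes$gene_id)
    need <- config$n_sets * config$genes_per_set
    if (need > length(pool))
      abort("panel demands more genes than exist: reduce `genes_per_set`")
    members <- split(pool[seq_len(need)],
                     rep(seq_len(config$n_sets), each = config$genes_per_set))
  })
  panel <- purrr::imap_dfr(members, function(g, i) {
    i <- as.integer(i)
    tibble::tibble(set = set_names[i], priority = i, gene_id = g)
  })
  if (!is.null(config$set_overlap)) {
    ov <- tibble::as_tibble(config$set_overlap)
    for (r in seq_len(nrow(ov))) {
      from <- panel$gene_id[panel$set == ov$set_a[r]]
      shared <- head(from, ov$n_shared[r])
      panel <- dplyr::bind_rows(panel, tibble::tibble(
        set = ov$set_b[r],
        priority = panel$priority[match(ov$set_b[r], panel$set)],
        gene_id = shared
      ))
    }
    panel <- dplyr::distinct(panel)
  }
  panel <- new_gene_set_panel(panel)

  pos <- seq_len(m) * spacing
  gene_snps <- purrr::map2(genes$start, genes$end,
                           function(s, e) which(pos >= s & pos <= e))
  names(gene_snps) <- genes$gene_id
  tissues <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  al <- draw_alleles(m, derive_seed(config$seed, "alleles"))
  withr::with_seed(derive_seed(config$seed, "weights"), {
    weights <- purrr::map_dfr(seq_len(ng), function(i) {
      idx <- gene_snps[[i]]
      if (!length(idx)) return(NULL)
      k <- min(config$snps_per_gene, length(idx))
      idx <- sort(sample(idx, k))
      purrr::map_dfr(tissues, function(tis) {
        tibble::tibble(
          gene_id = genes$gene_id[i], tissue = tis,
          snp = paste0("rs", idx), snp_index = idx,
          effect_allele = al$effect[idx], other_allele = al$other[idx],
          weight = rnorm(k)
        )
      })
    })
  })
  ld <- simulate_ld(config$blocks)
  covariance <- weights |>
    dplyr::distinct(.data$gene_id, .data$snp, .data$snp_index) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      R <- ld_submatrix(ld, d$snp_index)
      i <- rep(seq_len(nrow(d)), times = nrow(d))
      j <- rep(seq_len(nrow(d)), each = nrow(d))
      keep <- i <= j
      tibble::tibble(snp1 = d$snp[i[keep]], snp2 = d$snp[j[keep]],
                     value = R[cbind(i[keep], j[keep])])
    }) |>
    dplyr::ungroup()
  list(genes = genes, panel = panel, weights = weights,
       covariance = covariance, gene_snps = gene_snps)
}

#' Generate a full synthetic two-trait scene
#'
#' Orchestrates the LD reference, gene tracks, annotation masks, true
#' effects, and both traits' summary statistics into a single reproducible
#' scene. Every random stream is derived from `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A list of class `gwas_scene` with elements `config`, `ld`,
#'   `genes`, `panel`, `weights`, `covariance`, `effects`, `annotations`
#'   (named list of SNP index masks), `multiplier`, and `studies` (list of
#'   two `gwas_study` tibbles).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m_snps
  ld <- simulate_ld(config$blocks)
  tracks <- simulate_gene_tracks(config)

  masks <- list(); mults <- list()
  if (!is.null(config$annotations)) {
    ann <- config$annotations
    withr::with_seed(derive_seed(config$seed, "masks"), {
      remaining <- seq_len(m)
      for (r in seq_len(nrow(ann))) {
        k <- round(ann$prop[r] * m)
        pick <- sort(sample(remaining, k))
        remaining <- setdiff(remaining, pick)
        masks[[ann$name[r]]] <- pick
        mults[[ann$name[r]]] <- ann$multiplier[r]
      }
    })
  }
  if (!is.null(config$enriched_set)) {
    es <- config$enriched_set
    members <- tracks$panel$gene_id[tracks$panel$set == es$set]
    g <- tracks$genes[tracks$genes$gene_id %in% members, ]
    pos <- seq_len(m) * config$snp_spacing
    pad <- config$enriched_set_pad
    in_set <- rep(FALSE, m)
    for (r in seq_len(nrow(g)))
      in_set <- in_set | (pos >= g$start[r] - pad & pos <= g$end[r] + pad)
    masks[[paste0("set_", es$set)]] <- which(in_set)
    mults[[paste0("set_", es$set)]] <- es$multiplier
  }
  multiplier <- build_multipliers(m, masks, mults)

  effects <- simulate_effects(config, multiplier)
  if (!is.null(config$eqtl_signal)) {
    sig <- config$eqtl_signal
    w <- tracks$weights[tracks$weights$gene_id ==
                          tracks$genes$gene_id[sig$gene] &
                          tracks$weights$tissue == tracks$weights$tissue[1], ]
    effects$beta1[w$snp_index] <- effects$beta1[w$snp_index] +
      sig$scale * w$weight / sqrt(sum(w$weight^2))
  }

  al <- draw_alleles(m, derive_seed(config$seed, "alleles"))
  variants <- tibble::tibble(
    chrom = "1", pos = seq_len(m) * config$snp_spacing,
    rsid = paste0("rs", seq_len(m)),
    effect_allele = al$effect, other_allele = al$other
  )
  studies <- list(
    simulate_sumstats(effects$beta1, ld, config$n[1],
                      derive_seed(config$seed, "sumstats1"),
                      variants = variants, trait_name = "trait_a"),
    simulate_sumstats(effects$beta2, ld, config$n[2],
                      derive_seed(config$seed, "sumstats2"),
                      variants = variants, trait_name = "trait_b")
  )
  structure(list(
    config = config, ld = ld, genes = tracks$genes, panel = tracks$panel,
    weights = tracks$weights, covariance = tracks$covariance,
    gene_snps = tracks$gene_snps, effects = effects,
    annotations = masks, multiplier = multiplier, studies = studies
  ), class = "gwas_scene")
}

#' @export
print.gwas_scene <- function(x, ...) {
  cat(sprintf(
    "<gwas_scene> m=%d SNPs, %d genes, %d-set panel; h2=(%.2f, %.2f), rg=%.2f, n=(%d, %d)\n",
    x$config$m_snps, nrow(x$genes), length(unique(x$panel$set)),
    x$config$h2[1], x$config$h2[2], x$config$rg,
    x$config$n[1], x$config$n[2]))
  invisible(x)
}

#' Corrupt a study's allele coding for harmonization tests
#'
#' Applies, to disjoint random subsets of variants: allele swaps (alleles
#' exchanged and beta negated -- same variant, opposite coding), strand flips
#' (both alleles complemented), and palindromization (alleles replaced by an
#' A/T or C/G pair, which makes the strand unresolvable). The returned study
#' carries the injected row indices as attributes so tests know ground truth.
#'
#' @param study A `gwas_study`.
#' @param prop_swap,prop_strand,prop_palindromic Proportions of variants to
#'   corrupt in each mode.
#' @param seed Integer seed.
#' @return A modified `gwas_study` with attributes `swapped`, `strand_flipped`,
#'   `palindromized` (integer row indices).
#' @export
inject_harmonization_noise <- function(study, prop_swap = 0,
                                       prop_strand = 0,
                                       prop_palindromic = 0, seed = 1) {
  m <- nrow(study)
  withr::with_seed(seed, {
    pool <- sample.int(m)
    n_swap <- round(prop_swap * m)
    n_strand <- round(prop_strand * m)
    n_pal <- round(prop_palindromic * m)
    swap <- sort(pool[seq_len(n_swap)])
    strand <- sort(pool[n_swap + seq_len(n_strand)])
    pal <- sort(pool[n_swap + n_strand + seq_len(n_pal)])
    pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    pal_pick <- sample.int(4, n_pal, replace = TRUE)
  })
  out <- study
  if (length(swap)) {
    ea <- out$effect_allele[swap]
    out$effect_allele[swap] <- out$other_allele[swap]
    out$other_allele[swap] <- ea
    out$beta[swap] <- -out$beta[swap]
    out$z[swap] <- -out$z[swap]
  }
  if (length(strand)) {
    out$effect_allele[strand] <- complement_allele(out$effect_allele[strand])
    out$other_allele[strand] <- complement_allele(out$other_allele[strand])
  }
  if (length(pal)) {
    out$effect_allele[pal] <- pal_pairs[pal_pick, 1]
    out$other_allele[pal] <- pal_pairs[pal_pick, 2]
  }
  attr(out, "swapped") <- swap
  attr(out, "strand_flipped") <- strand
  attr(out, "palindromized") <- pal
  out
}
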