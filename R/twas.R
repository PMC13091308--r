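# Summary-based transcriptome-wide association: gene Z from expression
# prediction weights and reference SNP covariance, per-tissue FDR,
# Mann-Whitney set enrichment on absolute Z, and a best-tissue summary.

#' Gene-level TWAS Z from prediction weights and SNP covariance
#'
#' `z_gene = sum(w_l * sd_l * z_l) / sqrt(w' S w)` over the model SNPs
#' available in the study, where `S` is the reference covariance of the
#' SNPs and `sd_l` their reference standard deviations (1 when genotypes
#' are standardized and `S` is the LD correlation). Missing model SNPs are
#' dropped and the variance recomputed over the retained subset; strict
#' mode errors instead.
#'
#' @param weights Named numeric vector of SNP weights (names = SNP ids).
#' @param covariance Covariance matrix with dimnames covering the weight
#'   SNPs.
#' @param snp_z Named numeric vector mapping SNP id to GWAS z-score.
#' @param snp_sd Named numeric vector of reference SDs (default 1).
#' @param strict Error on missing SNPs instead of subsetting.
#' @return List: `z`, `pvalue`, `n_snps_used`, `n_snps_missing`.
#' @export
twas_z <- function(weights, covariance, snp_z, snp_sd = NULL, strict = FALSE) {
  snps <- names(weights)
  stopifnot(!is.null(snps), all(snps %in% rownames(covariance)))
  have <- snps[snps %in% names(snp_z) & is.finite(snp_z[snps])]
  n_missing <- length(snps) - length(have)
  if (n_missing > 0 && strict)
    abort("model SNPs missing from the study in strict mode")
  if (!length(have)) return(list(z = NA_real_, pvalue = NA_real_,
                                 n_snps_used = 0L,
                                 n_snps_missing = n_missing))
  w <- weights[have]
  S <- covariance[have, have, drop = FALSE]
  sdv <- if (is.null(snp_sd)) rep(1, length(have)) else snp_sd[have]
  pv <- drop(t(w) %*% S %*% w)
  if (pv <= 0) return(list(z = NA_real_, pvalue = NA_real_,
                           n_snps_used = 0L, n_snps_missing = n_missing))
  z <- sum(w * sdv * snp_z[have]) / sqrt(pv)
  list(z = z, pvalue = 2 * pnorm(-abs(z)), n_snps_used = length(have),
       n_snps_missing = n_missing)
}

# Expand the long covariance table of one gene into a symmetric matrix.
cov_matrix_for_gene <- function(cov_tbl, gene) {
  d <- cov_tbl[cov_tbl$gene_id == gene, , drop = FALSE]
  snps <- unique(c(d$snp1, d$snp2))
  S <- matrix(0, length(snps), length(snps), dimnames = list(snps, snps))
  S[cbind(d$snp1, d$snp2)] <- d$value
  S[cbind(d$snp2, d$snp1)] <- d$value
  S
}

#' Run summary-based TWAS across tissues
#'
#' Aligns the study to each model's allele coding (z negated when the
#' study's effect allele is the model's other allele; incompatible alleles
#' dropped as missing), computes the gene Z per (gene, tissue), and appends
#' a per-tissue Benjamini-Hochberg FDR column.
#'
#' @param study A `gwas_study` (or harmonized side) with `rsid` identifiers.
#' @param weights Tibble (`gene_id`, `tissue`, `snp`, `effect_allele`,
#'   `other_allele`, `weight`).
#' @param covariance Tibble (`gene_id`, `snp1`, `snp2`, `value`) from the
#'   LD reference.
#' @param snp_sd Optional named vector of reference SDs (default 1,
#'   standardized genotypes).
#' @return Tibble of class `twas_results`: `gene_id`, `tissue`, `z`,
#'   `pvalue`, `q`, `n_snps_used`, `n_snps_missing`.
#' @export
run_twas <- function(study, weights, covariance, snp_sd = NULL) {
  zmap <- setNames(study$z, study$rsid)
  ea <- setNames(toupper(study$effect_allele), study$rsid)
  oa <- setNames(toupper(study$other_allele), study$rsid)
  res <- weights |>
    dplyr::group_by(.data$gene_id, .data$tissue) |>
    dplyr::group_modify(function(d, key) {
      S <- cov_matrix_for_gene(covariance, key$gene_id)
      z_aligned <- zmap[d$snp]
      mea <- toupper(d$effect_allele); moa <- toupper(d$other_allele)
      sea <- ea[d$snp]; soa <- oa[d$snp]
      same <- !is.na(sea) & sea == mea & soa == moa
      flip <- !is.na(sea) & sea == moa & soa == mea
      z_aligned[flip] <- -z_aligned[flip]
      z_aligned[!(same | flip)] <- NA_real_
      tz <- twas_z(setNames(d$weight, d$snp), S, z_aligned,
                   snp_sd = snp_sd)
      tibble::tibble(z = tz$z, pvalue = tz$pvalue,
                     n_snps_used = tz$n_snps_used,
                     n_snps_missing = tz$n_snps_missing)
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$z)) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::mutate(q = p.adjust(.data$pvalue, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::relocate("q", .after = "pvalue")
  class(res) <- c("twas_results", class(res))
  res
}

#' Mann-Whitney set enrichment of TWAS results within one tissue
#'
#' One-sided Mann-Whitney U test of member genes' absolute Z against the
#' remaining background (members stochastically greater), with the
#' enrichment ratio defined as the ratio of mean absolute Z (members over
#' background). `n_fdr_significant` counts members under the per-tissue FDR
#' threshold.
#'
#' @param results A `twas_results` tibble.
#' @param set_genes Character vector of member gene ids.
#' @param tissue Tissue label to test in.
#' @param set_name Label for the output row.
#' @param fdr_threshold FDR cut used for `n_fdr_significant` (default 0.05).
#' @return One-row tibble: `set`, `tissue`, `n_genes`, `n_fdr_significant`,
#'   `enrichment_ratio`, `mw_p`, `best_gene`, `best_z`, `degenerate`.
#' @export
set_enrichment_mw <- function(results, set_genes, tissue,
                              set_name = "set", fdr_threshold = 0.05) {
  d <- results[results$tissue == tissue, , drop = FALSE]
  inset <- d$gene_id %in% set_genes
  if (sum(inset) < 2 || sum(!inset) < 2)
    abort("set and background must each contain at least 2 tested genes")
  azi <- abs(d$z[inset]); azo <- abs(d$z[!inset])
  degen <- length(unique(c(azi, azo))) == 1L
  p <- if (degen) 1 else
    suppressWarnings(wilcox.test(azi, azo, alternative = "greater")$p.value)
  best <- which.max(azi)
  tibble::tibble(
    set = set_name, tissue = tissue, n_genes = sum(inset),
    n_fdr_significant = sum(d$q[inset] < fdr_threshold),
    enrichment_ratio = mean(azi) / mean(azo), mw_p = p,
    best_gene = d$gene_id[inset][best], best_z = d$z[inset][best],
    degenerate = degen
  )
}

#' Mann-Whitney enrichment for every set and tissue
#'
#' @param results A `twas_results` tibble.
#' @param panel A `gene_set_panel` (priority-deduplicated first).
#' @param fdr_threshold FDR cut for `n_fdr_significant`.
#' @return Tibble with one row per (set, tissue), plus a per-tissue BH
#'   correction of the Mann-Whitney p (`mw_p_fdr`).
#' @export
twas_panel_enrichment <- function(results, panel, fdr_threshold = 0.05) {
  panel <- dedup_panel(panel)
  sets <- dplyr::distinct(panel, .data$set, .data$priority) |>
    dplyr::arrange(.data$priority)
  out <- purrr::map_dfr(unique(results$tissue), function(tis) {
    purrr::map_dfr(sets$set, function(s) {
      set_enrichment_mw(results, panel$gene_id[panel$set == s], tis,
                        set_name = s, fdr_threshold = fdr_threshold)
    })
  })
  out |>
    dplyr::group_by(.data$tissue) |>
    dplyr::mutate(mw_p_fdr = p.adjust(.data$mw_p, method = "BH")) |>
    dplyr::ungroup()
}

#' Best-performing tissue per gene
#'
#' For each gene, the tissue with the largest absolute Z; ties are broken
#' by lexicographic tissue label so the result is deterministic.
#'
#' @param results A `twas_results` tibble.
#' @return Tibble (`gene_id`, `tissue`, `z`, `pvalue`, `q`).
#' @export
best_tissue_summary <- function(results) {
  results |>
    dplyr::arrange(.data$gene_id, dplyr::desc(abs(.data$z)), .data$tissue) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "tissue", "z", "pvalue", "q")
}
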