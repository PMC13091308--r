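# Gene-based association from summary statistics: strand-aware SNP-to-gene
# windows, mean chi-squared gene statistic with an LD-aware null, probit
# gene Z, priority-deduplicated gene-set panels, and competitive set tests.

#' Construct a gene-set panel
#'
#' A panel is a long tibble (`set`, `priority`, `gene_id`) with one row per
#' set membership; lower `priority` ranks outrank higher ones when a gene
#' belongs to several sets.
#'
#' @param x Tibble with columns `set`, `priority`, `gene_id` (and optionally
#'   `provenance`).
#' @return A `gene_set_panel` tibble.
#' @export
new_gene_set_panel <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("set", "priority", "gene_id") %in% names(x)))
  pr <- dplyr::distinct(x, .data$set, .data$priority)
  if (anyDuplicated(pr$set)) abort("a set appears with two priority ranks")
  if (anyDuplicated(pr$priority)) abort("priority ranks must be unique")
  if (!"provenance" %in% names(x)) x$provenance <- "synthetic"
  class(x) <- c("gene_set_panel", class(tibble::tibble()))
  x
}

#' Read a GMT-style panel file
#'
#' One set per line: set name, provenance/description, then member gene ids,
#' tab-separated. Priority is the line order.
#'
#' @param path GMT file path.
#' @return A `gene_set_panel`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  purrr::imap_dfr(lines, function(l, i) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    tibble::tibble(set = f[1], priority = i, provenance = f[2],
                   gene_id = f[-(1:2)])
  }) |> new_gene_set_panel()
}

#' Write a panel as GMT
#' @param panel A `gene_set_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(panel, path) {
  lines <- panel |>
    dplyr::group_by(.data$set, .data$priority, .data$provenance) |>
    dplyr::summarise(line = paste(.data$gene_id, collapse = "\t"),
                     .groups = "drop") |>
    dplyr::arrange(.data$priority)
  writeLines(sprintf("%s\t%s\t%s", lines$set, lines$provenance, lines$line),
             path)
  invisible(path)
}

#' Deduplicate a panel by priority
#'
#' Each gene appearing in more than one set is retained only in its
#' highest-priority (lowest rank) set, so post-dedup sets are pairwise
#' disjoint. Idempotent.
#'
#' @param panel A `gene_set_panel`.
#' @return The deduplicated panel, with attribute `n_unique_genes`.
#' @export
dedup_panel <- function(panel) {
  out <- panel |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_min(.data$priority, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$priority, .data$gene_id)
  out <- new_gene_set_panel(out)
  attr(out, "n_unique_genes") <- dplyr::n_distinct(out$gene_id)
  out
}

#' Map SNPs to genes with strand-aware windows
#'
#' A SNP maps to a gene when it falls inside the gene body extended by
#' `window_up` bp upstream (5' of the gene, so to the left of a `+`-strand
#' gene and to the right of a `-`-strand gene) and `window_down` bp
#' downstream, inclusive at both boundaries. A SNP may map to several genes.
#'
#' @param variants Tibble with `chrom`, `pos` (a `gwas_study` works).
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates).
#' @param window_up,window_down Window sizes in bp (defaults 35 kb / 10 kb).
#' @return Tibble (`gene_id`, `snp_row`, `pos`) with one row per mapping;
#'   `snp_row` indexes rows of `variants`.
#' @export
map_snps_to_genes <- function(variants, genes, window_up = 35000,
                              window_down = 10000) {
  genes <- tibble::as_tibble(genes)
  up <- ifelse(genes$strand == "-", window_down, window_up)
  dn <- ifelse(genes$strand == "-", window_up, window_down)
  lo <- genes$start - up
  hi <- genes$end + dn
  res <- purrr::map_dfr(unique(genes$chrom), function(ch) {
    gi <- which(genes$chrom == ch)
    vi <- which(variants$chrom == ch)
    if (!length(gi) || !length(vi)) return(NULL)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = variants$pos[vi], width = 1L),
      IRanges::IRanges(start = lo[gi], end = hi[gi])
    )
    tibble::tibble(
      gene_id = genes$gene_id[gi[S4Vectors::subjectHits(hits)]],
      snp_row = vi[S4Vectors::queryHits(hits)],
      pos = variants$pos[vi[S4Vectors::queryHits(hits)]]
    )
  })
  dplyr::arrange(res, .data$gene_id, .data$snp_row)
}

#' Gene-level mean chi-squared test with LD correction
#'
#' The gene statistic is the mean of its SNPs' chi-squared values. Under the
#' null its distribution is `(1/m) * sum(lambda_i * chisq_1)` with
#' `lambda_i` the eigenvalues of the local LD correlation matrix; the
#' p-value uses two-moment (Satterthwaite) matching to a scaled chi-squared,
#' which is exact for independent SNPs and for rank-one (perfect) LD.
#' Slightly negative eigenvalues from numerical error are clipped at zero.
#'
#' @param snp_z Numeric vector of SNP z-scores mapped to the gene.
#' @param ld Local LD correlation matrix over the same SNPs.
#' @return List with `t_stat` (mean chi-squared), `pvalue`, `n_snps`,
#'   `scale`, `df`.
#' @export
gene_test <- function(snp_z, ld) {
  m <- length(snp_z)
  stopifnot(m >= 1)
  if (m == 1) ld <- matrix(1, 1, 1)
  stopifnot(nrow(ld) == m, ncol(ld) == m)
  lam <- eigen(ld, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-6 * max(lam))
    abort("local LD matrix is not positive semi-definite; clip or repair it first")
  lam <- pmax(lam, 0)
  t_stat <- mean(snp_z^2)
  s1 <- sum(lam); s2 <- sum(lam^2)
  g <- s2 / (m * s1)   # scale of the matched g * chisq_df
  df <- s1^2 / s2
  pvalue <- pchisq(t_stat / g, df = df, lower.tail = FALSE)
  list(t_stat = t_stat, pvalue = pvalue, n_snps = m, scale = g, df = df)
}

#' Probit gene Z from a gene p-value
#'
#' `z = qnorm(1 - p)`; extreme p-values are clamped at the representable
#' limit rather than returning infinities.
#'
#' @param pvalue Numeric vector of p-values in (0, 1].
#' @return Numeric vector of gene Z statistics.
#' @export
gene_z <- function(pvalue) {
  if (any(!is.finite(pvalue) | pvalue <= 0 | pvalue > 1))
    abort("p-values must lie in (0, 1]")
  z <- qnorm(pvalue, lower.tail = FALSE)
  zmax <- qnorm(.Machine$double.xmin, lower.tail = FALSE)
  pmin(pmax(z, -zmax), zmax)
}

#' Run the gene-based association layer for one study
#'
#' Maps SNPs to genes, runs the mean chi-squared test per gene using the
#' local LD (from the block reference), and appends the probit gene Z.
#' Genes with no mapped SNPs are excluded and listed in the
#' `dropped_genes` attribute.
#'
#' @param study A `gwas_study` whose rows are in genome order matching `ld`.
#' @param genes Gene coordinate tibble.
#' @param ld An `ld_blocks` object aligned to the study's rows.
#' @param window_up,window_down Mapping windows in bp.
#' @return Tibble of class `gene_scores` (`gene_id`, `n_snps`, `t_stat`,
#'   `pvalue`, `z`).
#' @export
run_gene_analysis <- function(study, genes, ld, window_up = 35000,
                              window_down = 10000) {
  mapping <- map_snps_to_genes(study, genes, window_up, window_down)
  res <- mapping |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      gt <- gene_test(study$z[d$snp_row], ld_submatrix(ld, d$snp_row))
      tibble::tibble(n_snps = gt$n_snps, t_stat = gt$t_stat,
                     pvalue = gt$pvalue)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(z = gene_z(.data$pvalue))
  attr(res, "dropped_genes") <- setdiff(genes$gene_id, res$gene_id)
  class(res) <- c("gene_scores", class(res))
  res
}

#' Bonferroni significance threshold
#' @param alpha Family-wise error level.
#' @param m Number of tests.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 8)     # 0.00625
#' bonferroni_threshold(0.05, 18222) # 2.74e-06
#' @export
bonferroni_threshold <- function(alpha, m) {
  check_prob(alpha, "alpha", open_left = TRUE, closed_right = FALSE)
  stopifnot(m >= 1)
  alpha / m
}

#' Competitive gene-set test
#'
#' One-sided Welch two-sample t-test of member gene Z against non-member
#' gene Z (alternative: members greater), the competitive question of
#' whether a set carries more association signal than the genomic
#' background. Degenerate inputs (both groups constant) return p = 1 with a
#' flag.
#'
#' @param gene_results A `gene_scores` tibble (needs `gene_id`, `z`,
#'   `pvalue`).
#' @param set_genes Character vector of member gene ids.
#' @param set_name Label for the output row.
#' @return One-row tibble: `set`, `n_genes`, `n_missing`, `mean_z`,
#'   `median_z`, `n_nominal`, `p_raw`, `degenerate`.
#' @export
competitive_set_test <- function(gene_results, set_genes, set_name = "set") {
  inset <- gene_results$gene_id %in% set_genes
  n_missing <- length(setdiff(set_genes, gene_results$gene_id))
  zi <- gene_results$z[inset]
  zo <- gene_results$z[!inset]
  if (length(zi) < 2 || length(zo) < 2)
    abort("set and background must each contain at least 2 tested genes")
  degen <- sd(zi) == 0 && sd(zo) == 0
  p <- if (degen) 1 else
    t.test(zi, zo, alternative = "greater", var.equal = FALSE)$p.value
  tibble::tibble(
    set = set_name, n_genes = length(zi), n_missing = n_missing,
    mean_z = mean(zi), median_z = median(zi),
    n_nominal = sum(gene_results$pvalue[inset] < 0.05),
    p_raw = p, degenerate = degen
  )
}

#' Competitive tests across a whole panel
#'
#' Deduplicates the panel by priority, runs [competitive_set_test()] per
#' set, and appends Bonferroni and Benjamini-Hochberg corrections across the
#' sets tested together.
#'
#' @param gene_results A `gene_scores` tibble.
#' @param panel A `gene_set_panel`.
#' @param dedup Apply priority deduplication first (default `TRUE`).
#' @return Tibble of class `set_test_results`, one row per set, with
#'   `p_bonferroni` and `p_fdr` columns.
#' @export
competitive_panel_test <- function(gene_results, panel, dedup = TRUE) {
  if (dedup) panel <- dedup_panel(panel)
  sets <- dplyr::distinct(panel, .data$set, .data$priority) |>
    dplyr::arrange(.data$priority)
  res <- purrr::map_dfr(sets$set, function(s) {
    competitive_set_test(gene_results,
                         panel$gene_id[panel$set == s], set_name = s)
  })
  res$p_bonferroni <- pmin(1, res$p_raw * nrow(res))
  res$p_fdr <- p.adjust(res$p_raw, method = "BH")
  class(res) <- c("set_test_results", class(res))
  res
}
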