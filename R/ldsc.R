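# LD score regression from block LD references: per-SNP and per-annotation
# LD scores, univariate and partitioned heritability with block-jackknife
# standard errors, a simplified stratified-chi-squared fallback enrichment,
# annotation BED construction, and cross-trait genetic correlation.

#' Contiguous equal-count jackknife block ids
#' @param m Number of SNPs.
#' @param n_blocks Number of blocks.
#' @return Integer vector of block ids, non-decreasing.
#' @export
jack_blocks <- function(m, n_blocks) {
  if (n_blocks < 2) abort("need at least 2 jackknife blocks")
  as.integer(ceiling(seq_len(m) * n_blocks / m))
}

# Weighted least squares with delete-one-block refits via per-block
# sufficient statistics (X'WX and X'WY accumulated per block, subtracted
# per deletion): exact and O(G p^2) instead of G full refits.
wls_jack <- function(X, Y, w, block_id) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- ncol(X); q <- ncol(Y)
  # column scaling for conditioning (l/m columns are tiny next to the
  # intercept); coefficients are unscaled on the way out.
  sc <- apply(X, 2, function(c) max(sqrt(mean(c^2)), .Machine$double.eps))
  X <- sweep(X, 2, sc, "/")
  blocks <- sort(unique(block_id))
  G <- length(blocks)
  A_g <- array(0, c(p, p, G)); B_g <- array(0, c(p, q, G))
  for (g in seq_len(G)) {
    i <- which(block_id == blocks[g])
    Xw <- X[i, , drop = FALSE] * w[i]
    A_g[, , g] <- crossprod(Xw, X[i, , drop = FALSE])
    B_g[, , g] <- crossprod(Xw, Y[i, , drop = FALSE])
  }
  A <- apply(A_g, c(1, 2), sum); B <- apply(B_g, c(1, 2), sum)
  if (qr(A)$rank < p) abort("design matrix is rank deficient")
  coef <- solve(A, B) / sc
  coef_del <- array(NA_real_, c(p, q, G))
  for (g in seq_len(G))
    coef_del[, , g] <- solve(A - A_g[, , g], B - B_g[, , g]) / sc
  list(coef = coef, coef_del = coef_del, n_blocks = G)
}

# Jackknife SE of a statistic from its delete-one-block values.
jack_se <- function(theta_del) {
  theta_del <- theta_del[is.finite(theta_del)]
  G <- length(theta_del)
  if (G < 2) return(NA_real_)
  sqrt((G - 1) / G * sum((theta_del - mean(theta_del))^2))
}

#' Compute per-SNP (and per-annotation) LD scores
#'
#' `l_j = sum_k r^2_jk` over SNPs k in the same LD block (the self term
#' included, so `l_j >= 1`); per-annotation scores restrict the sum to
#' annotation members.
#'
#' @param ld An `ld_blocks` object.
#' @param annotations Optional named list of SNP index vectors (or logical
#'   masks) defining annotations.
#' @return Tibble (`snp`, `block`, `l2`, then one `l2_<name>` column per
#'   annotation).
#' @export
compute_ld_scores <- function(ld, annotations = NULL) {
  m <- sum(ld$sizes)
  ann_masks <- lapply(annotations %||% list(), function(a) {
    if (is.logical(a)) which(a) else as.integer(a)
  })
  l2 <- numeric(m)
  l2_ann <- lapply(ann_masks, function(a) numeric(m))
  for (b in seq_along(ld$sizes)) {
    i <- ld$offset[b] + seq_len(ld$sizes[b])
    R2 <- ld_block(ld, b)^2
    l2[i] <- rowSums(R2)
    for (nm in names(ann_masks)) {
      memb <- i %in% ann_masks[[nm]]
      l2_ann[[nm]][i] <- if (any(memb)) rowSums(R2[, memb, drop = FALSE]) else 0
    }
  }
  out <- tibble::tibble(snp = seq_len(m), block = ld$block_id, l2 = l2)
  for (nm in names(l2_ann)) out[[paste0("l2_", nm)]] <- l2_ann[[nm]]
  out
}

#' Padded, merged annotation intervals in BED form
#'
#' Pads each gene body by `pad` bp on each side (clipped at position 1),
#' merges overlapping or abutting intervals per chromosome, and returns
#' BED-convention coordinates (0-based, half-open).
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param pad Padding in bp (default 10,000).
#' @return Tibble (`chrom`, `start`, `end`) in BED coordinates.
#' @export
make_annotation_bed <- function(genes, pad = 10000) {
  genes <- tibble::as_tibble(genes)
  purrr::map_dfr(unique(genes$chrom), function(ch) {
    g <- genes[genes$chrom == ch, ]
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1L, as.integer(g$start - pad)),
      end = as.integer(g$end + pad)))
    tibble::tibble(chrom = ch,
                   start = IRanges::start(ir) - 1L,
                   end = IRanges::end(ir))
  })
}

#' Write BED intervals
#' @param bed Tibble from [make_annotation_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' SNP membership mask for BED intervals
#' @param variants Tibble with `chrom`, `pos` (1-based).
#' @param bed Tibble in BED coordinates (0-based half-open).
#' @return Logical vector over the rows of `variants`.
#' @export
annotation_mask <- function(variants, bed) {
  mask <- rep(FALSE, nrow(variants))
  for (ch in unique(bed$chrom)) {
    vi <- which(variants$chrom == ch)
    b <- bed[bed$chrom == ch, ]
    if (!length(vi) || !nrow(b)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = variants$pos[vi], width = 1L),
      IRanges::IRanges(start = b$start + 1L, end = b$end))
    mask[vi[S4Vectors::queryHits(hits)]] <- TRUE
  }
  mask
}

#' Univariate LD score regression for SNP heritability
#'
#' Weighted regression of per-SNP chi-squared on `n * l_j / m` with a free
#' intercept; the slope is the SNP heritability and the intercept flags
#' confounding or sample overlap. Weights follow the canonical two-step
#' scheme: a first pass with overcounting weights `1 / max(1, l_j)`, then a
#' refit whose weights also divide by the squared predicted mean chi-squared
#' (the heteroskedasticity term). Standard errors come from a
#' delete-one-block jackknife over contiguous SNP blocks.
#'
#' @param chi2 Per-SNP chi-squared statistics (genome order).
#' @param l Per-SNP LD scores.
#' @param n Sample size.
#' @param m Number of SNPs the heritability refers to (default
#'   `length(chi2)`).
#' @param n_blocks Jackknife blocks (default 200).
#' @return An object of class `h2_fit`: `h2`, `intercept`, `h2_se`,
#'   `intercept_se`, `n_blocks`, `n`, `m`.
#' @export
estimate_h2 <- function(chi2, l, n, m = length(chi2), n_blocks = 200) {
  stopifnot(length(chi2) == length(l))
  if (length(chi2) < 2000)
    warn("fewer than 2,000 SNPs: LD score regression will be unstable")
  if (sd(l) == 0) abort("LD scores are constant; the slope is unidentified")
  x <- n * l / m
  X <- cbind(intercept = 1, x = x)
  blocks <- jack_blocks(length(chi2), n_blocks)
  w0 <- 1 / pmax(1, l)
  fit0 <- wls_jack(X, chi2, w0, blocks)
  h2_0 <- min(max(fit0$coef[2, 1], 0), 1)
  mu <- pmax(1 + h2_0 * x, 0.1)
  w <- 1 / (pmax(1, l) * mu^2)
  fit <- wls_jack(X, chi2, w, blocks)
  structure(list(
    h2 = fit$coef[2, 1], intercept = fit$coef[1, 1],
    h2_se = jack_se(fit$coef_del[2, 1, ]),
    intercept_se = jack_se(fit$coef_del[1, 1, ]),
    h2_del = fit$coef_del[2, 1, ],
    n_blocks = fit$n_blocks, n = n, m = m
  ), class = "h2_fit")
}

#' @export
print.h2_fit <- function(x, ...) {
  cat(sprintf("<h2_fit> h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f), %d blocks\n",
              x$h2, x$h2_se, x$intercept, x$intercept_se, x$n_blocks))
  invisible(x)
}

#' Partitioned heritability with overlap-aware proportions
#'
#' Multivariate weighted regression of chi-squared on all annotation LD
#' score columns plus the all-SNPs base annotation; each annotation's
#' heritability share is computed from per-SNP coefficient sums (so
#' overlapping annotations are handled), enrichment is the share divided by
#' the annotation's SNP share, jackknife SEs come from delete-one-block
#' refits, and the one-tailed p tests enrichment > 1. A per-SNP chi-squared
#' Mann-Whitney p and Bonferroni/BH corrections across annotations are
#' reported alongside.
#'
#' @param chi2 Per-SNP chi-squared statistics (genome order).
#' @param ld_scores Tibble from [compute_ld_scores()] with one `l2_<name>`
#'   column per annotation.
#' @param annotations Named list of SNP index vectors (or logical masks),
#'   matching the `l2_` columns.
#' @param n Sample size.
#' @param n_blocks Jackknife blocks (default 200).
#' @return Tibble of class `partitioned_h2`, one row per annotation:
#'   `annotation`, `n_snps`, `pct_snps`, `prop_h2`, `enrichment`,
#'   `se_jackknife`, `p_one_tailed`, `mw_p`, `p_bonferroni`, `p_fdr`.
#'   Attributes `tau` (coefficients) and `h2_total`.
#' @export
partitioned_h2 <- function(chi2, ld_scores, annotations, n, n_blocks = 200) {
  m <- length(chi2)
  if (!length(annotations) || is.null(names(annotations)))
    abort("`annotations` must be a non-empty named list")
  ann_names <- names(annotations)
  cols <- paste0("l2_", ann_names)
  miss <- setdiff(cols, names(ld_scores))
  if (length(miss))
    abort(paste0("ld_scores lacks per-annotation columns: ",
                 paste(miss, collapse = ", ")))
  masks <- lapply(annotations, function(a) if (is.logical(a)) which(a)
                  else as.integer(a))
  # membership matrix incl. the all-SNPs base annotation
  A <- cbind(base = rep(1, m),
             vapply(masks, function(a) as.numeric(seq_len(m) %in% a),
                    numeric(m)))
  L <- cbind(base = ld_scores$l2,
             as.matrix(ld_scores[, cols, drop = FALSE]))
  X <- cbind(intercept = 1, n * L)
  Xs <- sweep(X, 2, apply(X, 2, function(c) max(sqrt(mean(c^2)), 1e-300)), "/")
  if (qr(Xs)$rank < ncol(X)) {
    abort(paste0("annotation LD score columns are collinear among: base, ",
                 paste(ann_names, collapse = ", ")))
  }
  # two-step weights: heteroskedasticity term from a univariate first pass
  l_tot <- ld_scores$l2
  x1 <- n * l_tot / m
  f0 <- wls_jack(cbind(1, x1), chi2, 1 / pmax(1, l_tot),
                 jack_blocks(m, n_blocks))
  h2_0 <- min(max(f0$coef[2, 1], 0), 1)
  mu <- pmax(1 + h2_0 * x1, 0.1)
  w <- 1 / (pmax(1, l_tot) * mu^2)
  fit <- wls_jack(X, chi2, w, jack_blocks(m, n_blocks))
  C <- ncol(A)
  # cross-membership sums: M[c', c] = sum_j a_jc' a_jc
  M <- crossprod(A)
  props_from_tau <- function(tau) {
    per_cat <- drop(crossprod(M, tau))        # sum_{j in c} h2_j
    total <- per_cat[1]                        # base = all SNPs
    per_cat / total
  }
  tau <- fit$coef[-1, 1]
  prop <- props_from_tau(tau)
  pct <- colSums(A) / m
  enr <- prop / pct
  G <- fit$n_blocks
  enr_del <- matrix(NA_real_, G, C)
  for (g in seq_len(G))
    enr_del[g, ] <- props_from_tau(fit$coef_del[-1, 1, g]) / pct
  se <- apply(enr_del, 2, jack_se)
  keep <- seq_len(C)[-1]
  p_one <- pnorm((enr[keep] - 1) / se[keep], lower.tail = FALSE)
  mw_p <- vapply(masks, function(a) {
    inm <- seq_len(m) %in% a
    if (!any(inm) || all(inm)) return(NA_real_)
    suppressWarnings(wilcox.test(chi2[inm], chi2[!inm],
                                 alternative = "greater")$p.value)
  }, numeric(1))
  out <- tibble::tibble(
    annotation = ann_names,
    n_snps = unname(lengths(masks)),
    pct_snps = unname(pct[keep]),
    prop_h2 = unname(prop[keep]),
    enrichment = unname(enr[keep]),
    se_jackknife = unname(se[keep]),
    p_one_tailed = unname(p_one),
    mw_p = unname(mw_p),
    p_bonferroni = pmin(1, p_one * length(keep)),
    p_fdr = p.adjust(p_one, method = "BH")
  )
  attr(out, "tau") <- setNames(tau, colnames(A))
  attr(out, "h2_total") <- unname(drop(crossprod(M, tau))[1])
  class(out) <- c("partitioned_h2", class(out))
  out
}

#' Simplified stratified-chi-squared fallback enrichment
#'
#' For annotations too sparse for stable partitioned regression: the ratio
#' of per-SNP excess association per unit LD score between annotated and
#' unannotated SNPs, `[(mean chi2_in - 1)/mean l_in] / [(mean chi2_out - 1)/
#' mean l_out]`, with a two-sample Mann-Whitney p on the per-SNP chi-squared
#' alongside. Negative excess signal is floored at a small positive value
#' and flagged.
#'
#' @param chi2 Per-SNP chi-squared.
#' @param mask Logical (or index) annotation membership.
#' @param l Per-SNP LD scores.
#' @return One-row tibble: `ratio`, `mw_p`, `mean_chi2_in`, `mean_chi2_out`,
#'   `floored`.
#' @export
fallback_enrichment <- function(chi2, mask, l) {
  m <- length(chi2)
  inm <- if (is.logical(mask)) mask else seq_len(m) %in% as.integer(mask)
  if (!any(inm) || all(inm)) abort("both strata must be nonempty")
  eps <- 1e-6
  num_in <- mean(chi2[inm]) - 1
  num_out <- mean(chi2[!inm]) - 1
  floored <- num_in < eps || num_out < eps
  num_in <- max(num_in, eps); num_out <- max(num_out, eps)
  ratio <- (num_in / mean(l[inm])) / (num_out / mean(l[!inm]))
  mw <- suppressWarnings(wilcox.test(chi2[inm], chi2[!inm],
                                     alternative = "greater")$p.value)
  tibble::tibble(ratio = ratio, mw_p = mw,
                 mean_chi2_in = mean(chi2[inm]),
                 mean_chi2_out = mean(chi2[!inm]), floored = floored)
}

#' Cross-trait genetic correlation by LD score regression
#'
#' The genetic covariance is the slope of `z_a * z_b` on
#' `sqrt(n_a * n_b) * l / m` (free cross-intercept); per-trait
#' heritabilities come from [estimate_h2()]; `rg = gencov /
#' sqrt(h2_a * h2_b)`. The SE and p come from a delete-one-block jackknife
#' over `n_blocks` contiguous blocks in which all three regressions are
#' re-estimated jointly. All three intercepts are reported, the cross
#' intercept flagging residual sample overlap.
#'
#' @param z_a,z_b Harmonized per-SNP z-scores (study 2 aligned to study 1's
#'   effect alleles), genome order.
#' @param l Per-SNP LD scores over the shared variants.
#' @param n_a,n_b Per-study sample sizes.
#' @param m Number of SNPs (default `length(z_a)`).
#' @param n_blocks Jackknife blocks (default 200, minimum 20).
#' @return An object of class `rg_fit` with fields `rg`, `se`, `pvalue`,
#'   `gencov`, `h2_a`, `h2_b`, `intercept_a`, `intercept_b`,
#'   `cross_intercept`, `n_snps_used`, `n_blocks`.
#' @export
genetic_correlation <- function(z_a, z_b, l, n_a, n_b, m = length(z_a),
                                n_blocks = 200) {
  stopifnot(length(z_a) == length(z_b), length(z_a) == length(l))
  if (n_blocks < 20) abort("use at least 20 jackknife blocks")
  mm <- length(z_a)
  blocks <- jack_blocks(mm, n_blocks)
  fa <- estimate_h2(z_a^2, l, n_a, m = m, n_blocks = n_blocks)
  fb <- estimate_h2(z_b^2, l, n_b, m = m, n_blocks = n_blocks)
  h2_a <- fa$h2; h2_b <- fb$h2
  if (h2_a <= 0 || h2_b <= 0)
    abort(sprintf(
      "rg undefined: nonpositive heritability estimate (h2_a = %.4f, h2_b = %.4f)",
      h2_a, h2_b))
  # cross regression: z_a z_b on sqrt(n_a n_b) l / m, two-step weights with
  # the product-of-means heteroskedasticity term.
  xc <- sqrt(n_a * n_b) * l / m
  X <- cbind(intercept = 1, x = xc)
  w0 <- 1 / pmax(1, l)
  fit0 <- wls_jack(X, z_a * z_b, w0, blocks)
  g0 <- fit0$coef[2, 1]
  g0 <- sign(g0) * min(abs(g0), sqrt(max(h2_a, 0) * max(h2_b, 0)))
  mu_a <- pmax(1 + max(h2_a, 0) * n_a * l / m, 0.1)
  mu_b <- pmax(1 + max(h2_b, 0) * n_b * l / m, 0.1)
  mu_c <- g0 * xc + fit0$coef[1, 1]
  w <- 1 / (pmax(1, l) * (mu_a * mu_b + mu_c^2))
  fit <- wls_jack(X, z_a * z_b, w, blocks)
  gencov <- fit$coef[2, 1]
  rg <- gencov / sqrt(h2_a * h2_b)
  G <- fit$n_blocks
  rg_del <- vapply(seq_len(G), function(g) {
    ha <- fa$h2_del[g]
    hb <- fb$h2_del[g]
    gc <- fit$coef_del[2, 1, g]
    if (ha <= 0 || hb <= 0) return(NA_real_)
    gc / sqrt(ha * hb)
  }, numeric(1))
  se <- jack_se(rg_del)
  structure(list(
    rg = rg, se = se, pvalue = 2 * pnorm(-abs(rg) / se),
    gencov = gencov, h2_a = h2_a, h2_b = h2_b,
    h2_fit_a = fa, h2_fit_b = fb,
    intercept_a = fa$intercept, intercept_b = fb$intercept,
    cross_intercept = fit$coef[1, 1],
    n_snps_used = mm, n_blocks = G,
    out_of_bounds = abs(rg) > 1
  ), class = "rg_fit")
}

#' @export
print.rg_fit <- function(x, ...) {
  cat(sprintf("<rg_fit> rg = %.4f (SE %.4f), p = %.3g; h2 = (%.3f, %.3f); cross-intercept = %.4f\n",
              x$rg, x$se, x$pvalue, x$h2_a, x$h2_b, x$cross_intercept))
  invisible(x)
}
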