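# broom-style tidiers for the package's fitted objects.

#' @rdname pathcross_tidiers
#' @param x An `h2_fit`, `rg_fit`, `gsea_results`, `dgsea_results`,
#'   `partitioned_h2` or `set_test_results` object.
#' @param ... Unused.
#' @return `tidy()` returns a tibble with one row per term or set;
#'   `glance()` a one-row summary tibble.
#' @export
tidy.h2_fit <- function(x, ...) {
  tibble::tibble(term = c("h2", "intercept"),
                 estimate = c(x$h2, x$intercept),
                 std.error = c(x$h2_se, x$intercept_se))
}

#' @rdname pathcross_tidiers
#' @export
glance.h2_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, h2_se = x$h2_se, intercept = x$intercept,
                 intercept_se = x$intercept_se, n_blocks = x$n_blocks,
                 n = x$n, m = x$m)
}

#' Tidiers for pathcross results
#'
#' broom-style `tidy()` and `glance()` methods for the fitted objects this
#' package returns: LD score regression fits (`h2_fit`), genetic
#' correlation fits (`rg_fit`), and the tabular result classes.
#'
#' @name pathcross_tidiers
#' @rdname pathcross_tidiers
#' @export
tidy.rg_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rg", "gencov", "h2_a", "h2_b", "intercept_a", "intercept_b",
             "cross_intercept"),
    estimate = c(x$rg, x$gencov, x$h2_a, x$h2_b, x$intercept_a,
                 x$intercept_b, x$cross_intercept),
    std.error = c(x$se, rep(NA_real_, 6))
  )
}

#' @rdname pathcross_tidiers
#' @export
glance.rg_fit <- function(x, ...) {
  tibble::tibble(rg = x$rg, se = x$se, pvalue = x$pvalue,
                 gencov = x$gencov, h2_a = x$h2_a, h2_b = x$h2_b,
                 intercept_a = x$intercept_a, intercept_b = x$intercept_b,
                 cross_intercept = x$cross_intercept,
                 n_snps_used = x$n_snps_used, n_blocks = x$n_blocks)
}

#' @rdname pathcross_tidiers
#' @export
tidy.gsea_results <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$leading_edge <- vapply(out$leading_edge, paste, character(1),
                             collapse = ";")
  out
}

#' @rdname pathcross_tidiers
#' @export
glance.gsea_results <- function(x, ...) {
  ok <- is.na(x$skipped)
  tibble::tibble(n_sets = nrow(x), n_tested = sum(ok),
                 n_skipped = sum(!ok),
                 n_significant = sum(x$fdr_q[ok] < 0.05, na.rm = TRUE),
                 n_perm = x$n_perm[1])
}

#' @rdname pathcross_tidiers
#' @export
glance.dgsea_results <- function(x, ...) {
  tibble::tibble(n_comparisons = nrow(x),
                 n_significant = sum(x$p_adj < 0.05),
                 min_p_diff = min(x$p_diff),
                 max_abs_delta = max(abs(x$delta_nes)))
}

#' @rdname pathcross_tidiers
#' @export
glance.partitioned_h2 <- function(x, ...) {
  tibble::tibble(n_annotations = nrow(x), h2_total = attr(x, "h2_total"),
                 n_enriched = sum(x$enrichment > 1),
                 n_significant = sum(x$p_fdr < 0.05, na.rm = TRUE))
}
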