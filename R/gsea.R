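# Weighted Kolmogorov-Smirnov gene-set enrichment on ranked gene Z
# statistics, permutation nulls by gene-label resampling, and exhaustive
# cross-disorder differential enrichment (DGSEA).

#' Build a ranked gene list
#'
#' Orders genes by descending score; ties are broken by gene id so runs are
#' reproducible. Gene ids must be unique.
#'
#' @param gene_results Tibble with `gene_id` and a score column.
#' @param score Name of the score column (default `"z"`).
#' @return Tibble of class `ranked_list` (`gene`, `score`), descending.
#' @export
rank_genes <- function(gene_results, score = "z") {
  stopifnot(score %in% names(gene_results))
  out <- tibble::tibble(gene = gene_results$gene_id,
                        score = gene_results[[score]])
  if (anyDuplicated(out$gene)) abort("gene ids must be unique")
  out <- out[order(-out$score, out$gene), ]
  class(out) <- c("ranked_list", class(out))
  out
}

# Enrichment score from sorted hit positions. `v` holds |score|^alpha at the
# hit positions; N is the universe size. O(k) per evaluation, which is what
# makes ten-thousand-permutation nulls cheap: the running sum only changes
# slope at hits, so its extrema sit immediately before or after a hit.
es_from_positions <- function(pos, v, N) {
  k <- length(pos)
  if (k == 0L || k >= N) abort("set must be a non-empty strict subset")
  W <- sum(v)
  w <- if (W > 0) v / W else rep(1 / k, k)
  cw <- cumsum(w)
  d <- 1 / (N - k)
  after <- cw - d * (pos - seq_len(k))
  before <- after - w
  i_max <- which.max(after)
  i_min <- which.min(before)
  if (after[i_max] >= -before[i_min]) {
    list(es = after[i_max], extreme = i_max, positive = TRUE)
  } else {
    list(es = before[i_min], extreme = i_min, positive = FALSE)
  }
}

#' Weighted enrichment score with running profile and leading edge
#'
#' Walks the ranked list; set members ("hits") increment the running sum by
#' their |score|^`weight_exponent` share of the set total, non-members
#' decrement by `1/(N - n_set)`. The enrichment score is the
#' maximum-magnitude excursion. The leading edge holds the members at or
#' before the extremum (for positive ES; at or after it for negative ES).
#'
#' @param ranked A `ranked_list` (or tibble with `gene`, `score`).
#' @param set_genes Character vector of member gene ids.
#' @param weight_exponent Weighting exponent (0 recovers the classic
#'   two-sample KS statistic; default 1).
#' @return List: `es`, `leading_edge`, `extremum_pos`, `n_hits`, and
#'   `profile` (tibble `pos`, `gene`, `running`).
#' @export
enrichment_score <- function(ranked, set_genes, weight_exponent = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% set_genes
  pos <- which(hit)
  if (!length(pos)) abort("set has an empty intersection with the ranking")
  v <- abs(ranked$score[pos])^weight_exponent
  es <- es_from_positions(pos, v, N)
  W <- sum(v)
  incr <- rep(-1 / (N - length(pos)), N)
  incr[pos] <- if (W > 0) v / W else 1 / length(pos)
  running <- cumsum(incr)
  ext_pos <- pos[es$extreme]
  leading <- if (es$positive) ranked$gene[pos[pos <= ext_pos]]
             else ranked$gene[pos[pos >= ext_pos]]
  list(es = es$es, leading_edge = leading, extremum_pos = ext_pos,
       n_hits = length(pos),
       profile = tibble::tibble(pos = seq_len(N), gene = ranked$gene,
                                running = running))
}

# Normalize an observed ES against the same-sign half of its permutation
# null, and return the one-sided permutation p with the +1 counting rule.
nes_and_p <- function(es, null_es) {
  if (es >= 0) {
    same <- null_es[null_es >= 0]
    if (!length(same)) return(list(nes = NA_real_, p = 1))
    list(nes = es / mean(same),
         p = (1 + sum(same >= es)) / (1 + length(same)))
  } else {
    same <- null_es[null_es < 0]
    if (!length(same)) return(list(nes = NA_real_, p = 1))
    list(nes = es / mean(abs(same)),
         p = (1 + sum(same <= es)) / (1 + length(same)))
  }
}

# Null ES draws for one set size on one ranking (gene-label permutation:
# random same-size gene draws). `vals` = |score|^alpha over the ranking.
null_es_draws <- function(vals, N, k, n_perm) {
  vapply(seq_len(n_perm), function(i) {
    pos <- sort(sample.int(N, k))
    es_from_positions(pos, vals[pos], N)$es
  }, numeric(1))
}

#' Gene-set enrichment analysis over a panel
#'
#' For each set surviving the size filters (after intersecting with the
#' ranked universe), computes the weighted enrichment score, a permutation
#' null of `n_perm` random same-size gene draws, the normalized enrichment
#' score (ES divided by the mean same-sign null ES), a one-sided permutation
#' p with the +1 rule (never exactly zero), and Benjamini-Hochberg FDR
#' across the sets tested in the run.
#'
#' @param ranked A `ranked_list`.
#' @param panel A `gene_set_panel`.
#' @param n_perm Number of permutations (default 10,000).
#' @param min_size,max_size Set-size filters after intersection (defaults
#'   5 and 500).
#' @param weight_exponent Weighting exponent (default 1).
#' @param seed Integer seed for the permutation stream.
#' @return Tibble of class `gsea_results`: one row per set (`set`, `size`,
#'   `es`, `nes`, `p_perm`, `fdr_q`, `leading_edge` list-column, `n_perm`,
#'   `skipped` reason or `NA`).
#' @export
gsea <- function(ranked, panel, n_perm = 10000, min_size = 5,
                 max_size = 500, weight_exponent = 1, seed = 1) {
  if (n_perm < 100) warn("n_perm < 100 gives unstable NES estimates")
  N <- nrow(ranked)
  vals <- abs(ranked$score)^weight_exponent
  sets <- dplyr::distinct(panel, .data$set, .data$priority) |>
    dplyr::arrange(.data$priority)
  member_idx <- lapply(sets$set, function(s) {
    which(ranked$gene %in% panel$gene_id[panel$set == s])
  })
  sizes <- lengths(member_idx)
  null_cache <- new.env(parent = emptyenv())
  res <- withr::with_seed(seed, {
    purrr::map_dfr(seq_along(sets$set), function(i) {
      k <- sizes[i]
      if (k < min_size || k > max_size || k >= N) {
        return(tibble::tibble(set = sets$set[i], size = k, es = NA_real_,
                              nes = NA_real_, p_perm = NA_real_,
                              fdr_q = NA_real_,
                              leading_edge = list(character()),
                              n_perm = n_perm,
                              skipped = if (k < min_size) "below_min_size"
                                        else "above_max_size"))
      }
      pos <- member_idx[[i]]
      obs <- es_from_positions(pos, vals[pos], N)
      key <- as.character(k)
      if (is.null(null_cache[[key]]))
        null_cache[[key]] <- null_es_draws(vals, N, k, n_perm)
      np <- nes_and_p(obs$es, null_cache[[key]])
      le <- if (obs$positive) ranked$gene[pos[pos <= pos[obs$extreme]]]
            else ranked$gene[pos[pos >= pos[obs$extreme]]]
      tibble::tibble(set = sets$set[i], size = k, es = obs$es,
                     nes = np$nes, p_perm = np$p, fdr_q = NA_real_,
                     leading_edge = list(le), n_perm = n_perm,
                     skipped = NA_character_)
    })
  })
  ok <- is.na(res$skipped)
  res$fdr_q[ok] <- p.adjust(res$p_perm[ok], method = "BH")
  attr(res, "seed") <- seed
  class(res) <- c("gsea_results", class(res))
  res
}

#' Difference of normalized enrichment scores
#'
#' The descriptive cross-disorder contrast for one set: the NES of the set
#' on one disorder's ranking minus its NES on the other's.
#'
#' @param nes_a,nes_b Normalized enrichment scores.
#' @return `nes_a - nes_b`.
#' @examples
#' nes_difference(1.968, 0.809) # 1.159
#' @export
nes_difference <- function(nes_a, nes_b) nes_a - nes_b

#' Differential GSEA across two disorders
#'
#' Enumerates set pairs between two rankings and tests the difference of
#' normalized enrichment scores against a permutation null in which gene
#' labels are resampled independently in both rankings. With `mode =
#' "cross"` (default), all ordered pairs of distinct sets are compared --
#' set A scored on ranking A against set B scored on ranking B, giving
#' `k*(k-1)` comparisons (56 for an 8-set panel). With `mode = "within"`,
#' the `choose(k,2)` unordered pairs are contrasted within each disorder's
#' own ranking (same total count). Two-sided p with the +1 rule;
#' Benjamini-Hochberg correction across all comparisons.
#'
#' @param ranked_a,ranked_b `ranked_list`s for the two disorders.
#' @param panel A `gene_set_panel` present in both universes.
#' @param n_perm Number of permutations (default 10,000).
#' @param weight_exponent Weighting exponent (default 1).
#' @param seed Integer seed.
#' @param mode `"cross"` or `"within"` (see Details).
#' @param disorders Length-2 character labels for the output.
#' @return Tibble of class `dgsea_results`: `set_a`, `disorder_a`, `set_b`,
#'   `disorder_b`, `nes_a`, `nes_b`, `delta_nes`, `p_diff`, `p_adj`.
#' @export
dgsea <- function(ranked_a, ranked_b, panel, n_perm = 10000,
                  weight_exponent = 1, seed = 1,
                  mode = c("cross", "within"),
                  disorders = c("A", "B")) {
  mode <- match.arg(mode)
  sets <- dplyr::distinct(panel, .data$set, .data$priority) |>
    dplyr::arrange(.data$priority)
  rankings <- list(ranked_a, ranked_b)
  vals <- lapply(rankings, function(r) abs(r$score)^weight_exponent)
  Ns <- vapply(rankings, nrow, integer(1))

  # Observed ES/NES and per-(ranking, size) null NES draws, one stream.
  prep <- withr::with_seed(seed, {
    lapply(1:2, function(ri) {
      r <- rankings[[ri]]
      idx <- lapply(sets$set, function(s)
        which(r$gene %in% panel$gene_id[panel$set == s]))
      ks <- lengths(idx)
      if (any(ks == 0))
        abort(paste0("set(s) missing from ranking ", disorders[ri], ": ",
                     paste(sets$set[ks == 0], collapse = ", ")))
      nulls <- list()
      for (k in unique(ks)) {
        es_null <- null_es_draws(vals[[ri]], Ns[ri], k, n_perm)
        pos_m <- mean(es_null[es_null >= 0])
        neg_m <- mean(abs(es_null[es_null < 0]))
        nes_null <- ifelse(es_null >= 0,
                           es_null / pos_m, es_null / neg_m)
        nulls[[as.character(k)]] <- list(es = es_null, nes = nes_null)
      }
      obs <- vapply(seq_along(idx), function(i) {
        p <- idx[[i]]
        es_from_positions(p, vals[[ri]][p], Ns[ri])$es
      }, numeric(1))
      nes_obs <- vapply(seq_along(obs), function(i) {
        nes_and_p(obs[i], nulls[[as.character(ks[i])]]$es)$nes
      }, numeric(1))
      list(ks = ks, nulls = nulls, nes = nes_obs)
    })
  })

  pairs <- if (mode == "cross") {
    g <- expand.grid(i = seq_len(nrow(sets)), j = seq_len(nrow(sets)))
    g <- g[g$i != g$j, ]
    tibble::tibble(i = g$i, ri = 1L, j = g$j, rj = 2L)
  } else {
    g <- utils::combn(nrow(sets), 2)
    dplyr::bind_rows(
      tibble::tibble(i = g[1, ], ri = 1L, j = g[2, ], rj = 1L),
      tibble::tibble(i = g[1, ], ri = 2L, j = g[2, ], rj = 2L)
    )
  }
  res <- purrr::pmap_dfr(pairs, function(i, ri, j, rj) {
    nes_i <- prep[[ri]]$nes[i]
    nes_j <- prep[[rj]]$nes[j]
    delta <- nes_i - nes_j
    null_i <- prep[[ri]]$nulls[[as.character(prep[[ri]]$ks[i])]]$nes
    null_j <- prep[[rj]]$nulls[[as.character(prep[[rj]]$ks[j])]]$nes
    dnull <- null_i - null_j
    p <- (1 + sum(abs(dnull) >= abs(delta))) / (1 + length(dnull))
    tibble::tibble(
      set_a = sets$set[i], disorder_a = disorders[ri],
      set_b = sets$set[j], disorder_b = disorders[rj],
      nes_a = nes_i, nes_b = nes_j, delta_nes = delta, p_diff = p
    )
  })
  res$p_adj <- p.adjust(res$p_diff, method = "BH")
  attr(res, "seed") <- seed
  attr(res, "n_perm") <- n_perm
  class(res) <- c("dgsea_results", class(res))
  res
}

#' Cross-disorder pivot table of GSEA results
#'
#' One row per set; per-disorder NES, p and FDR columns side by side, with
#' the leading-edge genes of each disorder collapsed to a string. Sets
#' missing from one disorder keep their row with empty cells.
#'
#' @param results Named list of `gsea_results`, one per disorder.
#' @return A wide tibble.
#' @export
pivot_report <- function(results) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  long <- purrr::imap_dfr(results, function(r, d) {
    tibble::tibble(set = r$set, disorder = d, nes = r$nes,
                   p_perm = r$p_perm, fdr_q = r$fdr_q,
                   leading_edge = vapply(r$leading_edge, paste,
                                         character(1), collapse = ";"))
  })
  tidyr::pivot_wider(long, names_from = "disorder",
                     values_from = c("nes", "p_perm", "fdr_q",
                                     "leading_edge"))
}
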