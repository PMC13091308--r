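test_that("rank_genes sorts descending with deterministic tie-breaks", {
  gr <- tibble::tibble(gene_id = c("b", "a", "c", "d"),
                       z = c(2, 2, -1, 5))
  r <- rank_genes(gr)
  expect_s3_class(r, "ranked_list")
  expect_equal(r$gene, c("d", "a", "b", "c"))
  expect_error(rank_genes(tibble::tibble(gene_id = c("a", "a"),
                                         z = c(1, 2))), "unique")
})

test_that("enrichment_score matches a brute-force running-sum oracle", {
  withr::with_seed(17, {
    for (rep in 1:50) {
      N <- 10
      scores <- rnorm(N)
      genes <- paste0("g", sample(100, N))
      ranked <- rank_genes(tibble::tibble(gene_id = genes, z = scores))
      k <- sample(1:(N - 1), 1)
      set <- sample(genes, k)
      alpha <- sample(c(0, 0.5, 1, 2), 1)
      es <- enrichment_score(ranked, set, alpha)
      expect_equal(es$es, brute_force_es(ranked, set, alpha),
                   tolerance = 1e-12)
      expect_equal(es$n_hits, k)
      # the profile itself is the literal running sum
      expect_equal(max(abs(es$profile$running)), abs(es$es),
                   tolerance = 1e-12)
    }
  })
})

test_that("at weight 0 the ES reduces to the two-sample KS statistic", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      N <- 40
      ranked <- rank_genes(tibble::tibble(gene_id = paste0("g", 1:N),
                                          z = rnorm(N)))
      set <- sample(ranked$gene, 12)
      es <- enrichment_score(ranked, set, weight_exponent = 0)$es
      hit_pos <- which(ranked$gene %in% set)
      ks <- suppressWarnings(
        ks.test(hit_pos, setdiff(seq_len(N), hit_pos))$statistic)
      expect_equal(abs(es), unname(ks), tolerance = 1e-12)
    }
  })
})

test_that("the leading edge sits on the extremum side of the profile", {
  ranked <- rank_genes(tibble::tibble(gene_id = paste0("g", 1:20),
                                      z = 20:1))
  es <- enrichment_score(ranked, c("g1", "g2", "g3"), 1)
  expect_gt(es$es, 0)
  expect_equal(es$leading_edge, c("g1", "g2", "g3"))
  es_low <- enrichment_score(ranked, c("g18", "g19", "g20"), 1)
  expect_lt(es_low$es, 0)
  expect_equal(es_low$leading_edge, c("g18", "g19", "g20"))
})

test_that("enrichment_score agrees with the fgsea reference implementation", {
  gs <- small_gene_scores()
  ranked <- rank_genes(gs)
  stats <- setNames(ranked$score, ranked$gene)
  panel <- dedup_panel(small_scene()$panel)
  for (s in unique(panel$set)) {
    genes <- panel$gene_id[panel$set == s]
    ours <- enrichment_score(ranked, genes, 1)$es
    ref <- fgsea::calcGseaStat(stats,
                               selectedStats = which(ranked$gene %in% genes),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("nes_and_p normalizes by the same-sign null with the +1 rule", {
  null_es <- c(0.5, 0.25, -0.5, -0.25)
  up <- pathcross:::nes_and_p(0.4, null_es)
  expect_equal(up$nes, 0.4 / 0.375)
  expect_equal(up$p, 2 / 3)
  dn <- pathcross:::nes_and_p(-0.3, null_es)
  expect_equal(dn$nes, -0.3 / 0.375)
  expect_equal(dn$p, 2 / 3)
})

test_that("gsea is seed-deterministic with correct bookkeeping", {
  gs <- small_gene_scores()
  ranked <- rank_genes(gs)
  panel <- small_scene()$panel
  r1 <- gsea(ranked, panel, n_perm = 300, seed = 4)
  r2 <- gsea(ranked, panel, n_perm = 300, seed = 4)
  expect_identical(r1$nes, r2$nes)
  expect_identical(r1$p_perm, r2$p_perm)
  r3 <- gsea(ranked, panel, n_perm = 300, seed = 5)
  expect_false(identical(r3$p_perm, r1$p_perm))
  expect_equal(nrow(r1), 4L)
  expect_true(all(r1$p_perm > 0 & r1$p_perm <= 1))
  expect_equal(r1$fdr_q, p.adjust(r1$p_perm, method = "BH"))
  expect_true(all(sign(r1$nes) == sign(r1$es)))
})

test_that("gsea size filters skip sets with a reason", {
  gs <- small_gene_scores()
  ranked <- rank_genes(gs)
  panel <- new_gene_set_panel(tibble::tibble(
    set = c(rep("tiny", 2), rep("big", 20), rep("ok", 8)),
    priority = c(rep(1L, 2), rep(2L, 20), rep(3L, 8)),
    gene_id = c(gs$gene_id[1:2], gs$gene_id[3:22], gs$gene_id[23:30])))
  r <- gsea(ranked, panel, n_perm = 200, min_size = 5, max_size = 15,
            seed = 1)
  expect_equal(r$skipped[r$set == "tiny"], "below_min_size")
  expect_equal(r$skipped[r$set == "big"], "above_max_size")
  expect_true(is.na(r$skipped[r$set == "ok"]))
  expect_true(is.na(r$nes[r$set == "tiny"]))
})

test_that("nes_difference subtracts", {
  expect_equal(nes_difference(2.5, 1), 1.5)
})

test_that("dgsea enumerates the comparison grid in both modes", {
  gs <- small_gene_scores()
  sc <- small_scene()
  gs_b <- run_gene_analysis(sc$studies[[2]], sc$genes, sc$ld)
  ra <- rank_genes(gs); rb <- rank_genes(gs_b)
  cross <- dgsea(ra, rb, sc$panel, n_perm = 200, seed = 2,
                 disorders = c("da", "db"))
  expect_equal(nrow(cross), 4 * 3)
  expect_true(all(cross$disorder_a == "da" & cross$disorder_b == "db"))
  expect_false(any(cross$set_a == cross$set_b))
  expect_equal(cross$p_adj, p.adjust(cross$p_diff, method = "BH"))
  expect_equal(cross$delta_nes, cross$nes_a - cross$nes_b)
  within <- dgsea(ra, rb, sc$panel, n_perm = 200, seed = 2, mode = "within")
  expect_equal(nrow(within), 2 * choose(4, 2))
  expect_true(all(within$disorder_a == within$disorder_b))
  # determinism
  cross2 <- dgsea(ra, rb, sc$panel, n_perm = 200, seed = 2,
                  disorders = c("da", "db"))
  expect_identical(cross2$p_diff, cross$p_diff)
})

test_that("dgsea refuses sets missing from a ranking", {
  gs <- small_gene_scores()
  ranked <- rank_genes(gs)
  panel <- new_gene_set_panel(tibble::tibble(
    set = c(rep("present", 6), rep("absent", 6)),
    priority = c(rep(1L, 6), rep(2L, 6)),
    gene_id = c(gs$gene_id[1:6], paste0("nope", 1:6))))
  expect_error(dgsea(ranked, ranked, panel, n_perm = 50), "missing")
})

test_that("pivot_report widens per-disorder results", {
  gs <- small_gene_scores()
  ranked <- rank_genes(gs)
  r <- gsea(ranked, small_scene()$panel, n_perm = 200, seed = 3)
  wide <- pivot_report(list(one = r, two = r))
  expect_equal(nrow(wide), 4L)
  expect_true(all(c("nes_one", "nes_two", "p_perm_one", "fdr_q_two",
                    "leading_edge_one") %in% names(wide)))
  expect_equal(wide$nes_one, wide$nes_two)
})
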