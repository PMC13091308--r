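test_that("sim_config validates its inputs", {
  expect_error(sim_config(h2 = c(1, 0.3)), "h2")
  expect_error(sim_config(rg = 1.5), "rg|<= 1")
  expect_error(sim_config(m_snps = 150, block_size = 100,
                          n_genes = 2, gene_length = 10), "multiple")
  expect_error(sim_config(blocks = tibble::tibble(size = 10, rho = 0.5)),
               "sum")
  expect_error(sim_config(n_genes = 10000), "coordinate space")
  expect_s3_class(small_config(), "sim_config")
})

test_that("ld_block_matrix is the AR(1) correlation matrix", {
  R <- ld_block_matrix(4, 0.5)
  idx <- 1:4
  expect_equal(R, 0.5^abs(outer(idx, idx, "-")))
  expect_error(ld_block_matrix(3, 1), "rho")
})

test_that("ld_submatrix matches a dense block-diagonal oracle", {
  blocks <- tibble::tibble(size = c(3L, 4L, 2L), rho = c(0.5, -0.3, 0.8))
  ld <- simulate_ld(blocks)
  full <- matrix(0, 9, 9)
  full[1:3, 1:3] <- ld_block_matrix(3, 0.5)
  full[4:7, 4:7] <- ld_block_matrix(4, -0.3)
  full[8:9, 8:9] <- ld_block_matrix(2, 0.8)
  idx <- c(2, 5, 6, 9)
  expect_equal(ld_submatrix(ld, idx), full[idx, idx])
  expect_equal(ld_submatrix(ld, c(6, 2, 9, 5)), full[idx, idx])
})

test_that("simulate_effects conserves heritability exactly", {
  eff <- simulate_effects(small_config())
  expect_equal(sum(eff$beta1^2), 0.3, tolerance = 1e-12)
  expect_equal(sum(eff$beta2^2), 0.3, tolerance = 1e-12)
  eff0 <- simulate_effects(sim_config(m_snps = 2000, h2 = c(0, 0.2),
                                      n_genes = 50))
  expect_true(all(eff0$beta1 == 0))
  expect_equal(sum(eff0$beta2^2), 0.2, tolerance = 1e-12)
})

test_that("effect pairs realize the configured genetic correlation", {
  cfg <- sim_config(m_snps = 20000, rg = 0.6, seed = 5)
  eff <- simulate_effects(cfg)
  expect_equal(cor(eff$beta1, eff$beta2), 0.6, tolerance = 0.05)
})

test_that("annotation multipliers scale per-SNP effect variance", {
  m <- 20000
  mult <- rep(c(1.5, 0.5), each = m / 2)
  eff <- simulate_effects(sim_config(m_snps = m, seed = 9), multiplier = mult)
  ratio <- mean(eff$beta1[1:(m / 2)]^2) / mean(eff$beta1[(m / 2 + 1):m]^2)
  expect_equal(ratio, 3, tolerance = 0.4)
})

test_that("simulate_sumstats draws z with the right null moments and LD", {
  sc <- small_scene()
  cfg <- small_config()
  beta0 <- rep(0, cfg$m_snps)
  st <- simulate_sumstats(beta0, sc$ld, 20000, seed = 77)
  expect_equal(mean(st$z), 0, tolerance = 0.1)
  expect_equal(var(st$z), 1, tolerance = 0.1)
  # adjacent-pair correlation within the strongest-LD blocks
  strong <- which(abs(sc$ld$rhos - 0.9) < 1e-9)
  pair_i <- unlist(lapply(strong, function(b)
    sc$ld$offset[b] + seq_len(sc$ld$sizes[b] - 1L)))
  expect_equal(cor(st$z[pair_i], st$z[pair_i + 1L]), 0.9, tolerance = 0.08)
  # determinism
  st2 <- simulate_sumstats(beta0, sc$ld, 20000, seed = 77)
  expect_identical(st2$z, st$z)
  st3 <- simulate_sumstats(beta0, sc$ld, 20000, seed = 78)
  expect_false(identical(st3$z, st$z))
})

test_that("simulated studies carry signal proportional to LD and n", {
  sc <- small_scene()
  # E[chi2] = 1 + n h2 l / m on average
  expect_equal(mean(sc$studies[[1]]$chi2),
               1 + 20000 * 0.3 * mean(compute_ld_scores(sc$ld)$l2) / 4000,
               tolerance = 0.15)
})

test_that("gene tracks tile disjoint genes with in-body weight SNPs", {
  sc <- small_scene()
  g <- sc$genes
  expect_equal(nrow(g), 60L)
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  expect_setequal(unique(g$strand), c("+", "-"))
  w <- sc$weights
  expect_setequal(unique(w$tissue), sprintf("tissue_%02d", 1:3))
  pos <- w$snp_index * small_config()$snp_spacing
  gi <- match(w$gene_id, g$gene_id)
  expect_true(all(pos >= g$start[gi] & pos <= g$end[gi]))
})

test_that("the panel has the configured shape and priorities", {
  p <- small_scene()$panel
  expect_s3_class(p, "gene_set_panel")
  expect_equal(dplyr::n_distinct(p$set), 4L)
  expect_true(all(table(p$set) == 10L))
  expect_false(anyDuplicated(p$gene_id) > 0)
})

test_that("per-gene covariance equals the LD submatrix oracle", {
  sc <- small_scene()
  gid <- sc$weights$gene_id[1]
  idx <- sort(unique(sc$weights$snp_index[sc$weights$gene_id == gid]))
  S <- pathcross:::cov_matrix_for_gene(sc$covariance, gid)
  ord <- paste0("rs", idx)
  expect_equal(unname(S[ord, ord]), ld_submatrix(sc$ld, idx))
})

test_that("random annotation masks are disjoint with the requested share", {
  cfg <- small_config(annotations = tibble::tibble(
    name = c("m1", "m2"), prop = c(0.1, 0.05), multiplier = c(2, 0.5)))
  sc <- simulate_study(cfg)
  a <- sc$annotations
  expect_named(a, c("m1", "m2"))
  expect_equal(lengths(a), c(m1 = 400L, m2 = 200L))
  expect_length(intersect(a$m1, a$m2), 0L)
  expect_equal(mean(sc$multiplier), 1, tolerance = 1e-12)
  expect_true(all(sc$multiplier[a$m1] > sc$multiplier[a$m2]))
})

test_that("enriched_set masks follow the padded gene bodies of the set", {
  cfg <- small_config(enriched_set = list(set = "housekeeping",
                                          multiplier = 3))
  sc <- simulate_study(cfg)
  mask <- sc$annotations$set_housekeeping
  expect_gt(length(mask), 0)
  members <- sc$panel$gene_id[sc$panel$set == "housekeeping"]
  g <- sc$genes[sc$genes$gene_id %in% members, ]
  pos <- mask * cfg$snp_spacing
  inside <- vapply(pos, function(p)
    any(p >= g$start - cfg$enriched_set_pad &
        p <= g$end + cfg$enriched_set_pad), logical(1))
  expect_true(all(inside))
  expect_gt(mean(sc$multiplier[mask]), mean(sc$multiplier[-mask]))
})

test_that("simulate_study is deterministic in its seed", {
  sc1 <- simulate_study(small_config(seed = 55))
  sc2 <- simulate_study(small_config(seed = 55))
  expect_identical(sc1$studies[[1]]$z, sc2$studies[[1]]$z)
  expect_identical(sc1$studies[[2]]$beta, sc2$studies[[2]]$beta)
  expect_identical(sc1$effects$beta1, sc2$effects$beta1)
  sc3 <- simulate_study(small_config(seed = 56))
  expect_false(identical(sc1$studies[[1]]$z, sc3$studies[[1]]$z))
})

test_that("inject_harmonization_noise corrupts disjoint subsets as labeled", {
  a <- toy_study(300, seed = 61)
  b <- inject_harmonization_noise(a, 0.1, 0.1, 0.1, seed = 3)
  sw <- attr(b, "swapped"); fl <- attr(b, "strand_flipped")
  pal <- attr(b, "palindromized")
  expect_equal(lengths(list(sw, fl, pal)), rep(30L, 3))
  expect_length(Reduce(intersect, list(sw, fl, pal)), 0L)
  expect_identical(b$effect_allele[sw], a$other_allele[sw])
  expect_identical(b$beta[sw], -a$beta[sw])
  expect_identical(b$effect_allele[fl],
                   pathcross:::complement_allele(a$effect_allele[fl]))
  expect_true(all(is_palindromic(b$effect_allele[pal],
                                 b$other_allele[pal])))
})
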