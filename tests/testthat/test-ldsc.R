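test_that("jack_blocks partitions SNPs into contiguous near-equal blocks", {
  b <- jack_blocks(1000, 40)
  expect_equal(length(b), 1000L)
  expect_equal(sort(unique(b)), 1:40)
  expect_true(all(diff(b) >= 0))
  expect_true(max(table(b)) - min(table(b)) <= 1)
  expect_error(jack_blocks(100, 1), "at least 2")
})

test_that("wls_jack equals the weighted lm oracle, refits included", {
  withr::with_seed(8, {
    X <- cbind(1, rnorm(200), runif(200))
    Y <- X %*% c(2, -1, 0.5) + rnorm(200)
    w <- runif(200, 0.5, 2)
  })
  blocks <- rep(1:10, each = 20)
  fit <- pathcross:::wls_jack(X, Y, w, blocks)
  oracle <- lm.wfit(X, Y, w)$coefficients
  expect_equal(drop(fit$coef), unname(oracle), tolerance = 1e-10)
  for (g in c(1, 5, 10)) {
    keep <- blocks != g
    del <- lm.wfit(X[keep, ], Y[keep, , drop = FALSE], w[keep])$coefficients
    expect_equal(drop(fit$coef_del[, , g]), unname(del), tolerance = 1e-10)
  }
  expect_error(pathcross:::wls_jack(cbind(1, 1:10, 2 * (1:10)),
                                    rnorm(10), rep(1, 10),
                                    rep(1:2, each = 5)),
               "rank deficient")
})

test_that("jack_se matches the delete-one-block formula", {
  theta <- c(0.9, 1.1, 1.0, 1.05, 0.95)
  G <- 5
  expect_equal(pathcross:::jack_se(theta),
               sqrt((G - 1) / G * sum((theta - mean(theta))^2)))
  expect_true(is.na(pathcross:::jack_se(1)))
})

test_that("compute_ld_scores matches brute-force r^2 sums and closed forms", {
  blocks <- tibble::tibble(size = c(2L, 3L, 4L), rho = c(0.5, 0.5, -0.4))
  ld <- simulate_ld(blocks)
  sc <- compute_ld_scores(ld)
  # closed forms for AR(1): size 2, rho .5 -> 1.25; size 3 middle -> 1.5
  expect_equal(sc$l2[1:2], c(1.25, 1.25))
  expect_equal(sc$l2[3:5], c(1.3125, 1.5, 1.3125))
  # brute force over the dense block-diagonal matrix
  full <- matrix(0, 9, 9)
  full[1:2, 1:2] <- ld_block_matrix(2, 0.5)
  full[3:5, 3:5] <- ld_block_matrix(3, 0.5)
  full[6:9, 6:9] <- ld_block_matrix(4, -0.4)
  expect_equal(sc$l2, rowSums(full^2))
  # annotation restriction
  mask <- c(1L, 4L, 7L, 8L)
  sca <- compute_ld_scores(ld, list(ann = mask))
  expect_equal(sca$l2_ann, rowSums(full[, mask]^2))
  expect_true(all(sc$l2 >= 1))
})

test_that("make_annotation_bed matches a per-base union oracle", {
  withr::with_seed(13, {
    genes <- tibble::tibble(
      gene_id = paste0("g", 1:15), chrom = sample(c("1", "2"), 15, TRUE),
      start = sample(1:5000, 15), end = 0L)
    genes$end <- genes$start + sample(100:1500, 15)
  })
  pad <- 250
  bed <- make_annotation_bed(genes, pad = pad)
  for (ch in unique(genes$chrom)) {
    L <- max(genes$end) + pad + 10
    oracle <- rep(FALSE, L)
    g <- genes[genes$chrom == ch, ]
    for (r in seq_len(nrow(g)))
      oracle[max(1, g$start[r] - pad):(g$end[r] + pad)] <- TRUE
    from_bed <- rep(FALSE, L)
    b <- bed[bed$chrom == ch, ]
    for (r in seq_len(nrow(b)))
      from_bed[(b$start[r] + 1):b$end[r]] <- TRUE
    expect_identical(from_bed, oracle)
    # intervals are sorted and strictly disjoint after merging
    expect_true(all(b$start[-1] > b$end[-nrow(b)]))
  }
})

test_that("annotation_mask agrees with interval membership", {
  bed <- tibble::tibble(chrom = "1", start = c(10L, 50L), end = c(20L, 60L))
  variants <- tibble::tibble(chrom = c("1", "1", "1", "1", "2"),
                             pos = c(10L, 11L, 20L, 21L, 15L))
  expect_identical(annotation_mask(variants, bed),
                   c(FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("write_bed emits three-column headerless TSV", {
  bed <- tibble::tibble(chrom = "1", start = 0L, end = 100L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(bed, path)
  expect_identical(readLines(path), "1\t0\t100")
})

test_that("estimate_h2 recovers an exact linear signal exactly", {
  sc <- small_scene()
  l <- compute_ld_scores(sc$ld)$l2
  m <- length(l); n <- 20000; h2 <- 0.25
  chi2 <- 1 + n * h2 * l / m
  fit <- estimate_h2(chi2, l, n, n_blocks = 40)
  expect_equal(fit$h2, h2, tolerance = 1e-8)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  expect_lt(fit$h2_se, 1e-8)
  expect_lt(fit$intercept_se, 1e-8)
  expect_error(estimate_h2(chi2, rep(1.5, m), n), "constant")
})

test_that("partitioned_h2 recovers exact annotation coefficients", {
  sc <- small_scene()
  m <- 4000; n <- 20000
  mask <- seq(3, m, by = 7)
  scores <- compute_ld_scores(sc$ld, list(target = mask))
  tau_base <- 0.25 / m; tau_t <- 0.5 / m
  chi2 <- 1 + n * (tau_base * scores$l2 + tau_t * scores$l2_target)
  ph <- partitioned_h2(chi2, scores, list(target = mask), n, n_blocks = 40)
  tau <- attr(ph, "tau")
  expect_equal(unname(tau), c(tau_base, tau_t), tolerance = 1e-10)
  # closed-form enrichment from per-SNP h2
  h2_j <- tau_base + tau_t * (seq_len(m) %in% mask)
  prop <- sum(h2_j[mask]) / sum(h2_j)
  pct <- length(mask) / m
  expect_equal(ph$prop_h2, prop, tolerance = 1e-8)
  expect_equal(ph$enrichment, prop / pct, tolerance = 1e-8)
  expect_equal(attr(ph, "h2_total"), sum(h2_j), tolerance = 1e-8)
  expect_lt(ph$se_jackknife, 1e-6)
  expect_error(partitioned_h2(chi2, scores, list(), n), "named list")
})

test_that("partitioned_h2 names collinear annotations", {
  sc <- small_scene()
  mask <- seq(1, 4000, by = 5)
  scores <- compute_ld_scores(sc$ld, list(a1 = mask, a2 = mask))
  expect_error(partitioned_h2(runif(4000) + 0.5, scores,
                              list(a1 = mask, a2 = mask), 1000,
                              n_blocks = 40),
               "collinear")
})

test_that("fallback_enrichment follows its stratified formula", {
  withr::with_seed(19, {
    chi2 <- rchisq(2000, df = 1) + c(rep(0.5, 500), rep(0, 1500))
    l <- runif(2000, 1, 5)
  })
  mask <- seq_len(500)
  fb <- fallback_enrichment(chi2, mask, l)
  inm <- seq_len(2000) %in% mask
  num_in <- mean(chi2[inm]) - 1
  num_out <- max(mean(chi2[!inm]) - 1, 1e-6)
  expect_equal(fb$ratio,
               (num_in / mean(l[inm])) / (num_out / mean(l[!inm])),
               tolerance = 1e-12)
  expect_equal(fb$mw_p,
               wilcox.test(chi2[inm], chi2[!inm],
                           alternative = "greater")$p.value)
  # floored branch: no excess signal anywhere
  fb0 <- fallback_enrichment(rep(0.5, 100), 1:50, rep(1, 100))
  expect_true(fb0$floored)
  expect_equal(fb0$ratio, 1)
  expect_error(fallback_enrichment(chi2, integer(0), l), "nonempty")
})

test_that("genetic_correlation of a study with itself is about 1", {
  sc <- small_scene()
  z <- sc$studies[[1]]$z
  l <- compute_ld_scores(sc$ld)$l2
  fit <- genetic_correlation(z, z, l, 20000, 20000, n_blocks = 40)
  expect_s3_class(fit, "rg_fit")
  expect_equal(fit$rg, 1, tolerance = 0.1)
  expect_gt(fit$h2_a, 0)
  expect_identical(fit$h2_a, fit$h2_b)
  # symmetric in its arguments
  fit2 <- genetic_correlation(z, sc$studies[[2]]$z, l, 20000, 20000,
                              n_blocks = 40)
  fit3 <- genetic_correlation(sc$studies[[2]]$z, z, l, 20000, 20000,
                              n_blocks = 40)
  expect_equal(fit2$rg, fit3$rg, tolerance = 1e-10)
  expect_error(genetic_correlation(z, z, l, 100, 100, n_blocks = 5),
               "jackknife")
})

test_that("genetic_correlation refuses nonpositive heritability", {
  sc <- small_scene()
  l <- compute_ld_scores(sc$ld)$l2
  # chi2 decreasing in l -> negative slope -> h2 < 0
  z <- sqrt(pmax(1.5 - 0.2 * l, 0.01))
  expect_error(genetic_correlation(z, z, l, 20000, 20000, n_blocks = 40),
               "nonpositive heritability")
})
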