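test_that("new_gwas_study validates rows and records exclusions", {
  tab <- tibble::tibble(
    chrom = "1", pos = 1:6 * 100L, rsid = paste0("rs", 1:6),
    effect_allele = c("A", "A", "A", "A", "G", "A"),
    other_allele = c("G", "G", "G", "G", "G", "C"),
    beta = c(0.1, NA, 0.1, 0.1, 0.1, 0.1),
    se = c(0.05, 0.05, -1, 0.05, 0.05, 0.05),
    pvalue = c(0.04, 0.04, 0.04, 1.2, 0.04, 0.04),
    n = 1000
  )
  st <- new_gwas_study(tab, trait_name = "t")
  expect_s3_class(st, "gwas_study")
  expect_equal(nrow(st), 2L)   # rows 1 and 6 survive
  led <- exclusion_ledger(st)
  expect_setequal(led$reason,
                  c("unparseable", "nonpositive_se", "invalid_p",
                    "identical_alleles"))
  expect_equal(sum(led$n), 4L)
  expect_equal(st$z, st$beta / st$se)
  expect_equal(st$chi2, st$z^2)
  expect_equal(attr(st, "n_effective"), 1000)
})

test_that("new_gwas_study errors on missing mandatory columns", {
  expect_error(new_gwas_study(tibble::tibble(chrom = "1", pos = 1L)),
               "missing mandatory columns")
})

test_that("effective_sample_size matches the balanced-design identity", {
  expect_equal(effective_sample_size(2000, 2000), 4000)
  expect_equal(effective_sample_size(100, 300), round(4 / (1 / 100 + 1 / 300)))
  expect_error(effective_sample_size(0, 10), "positive")
})

test_that("dialect-A TSV write/read round-trips bit for bit", {
  st <- small_scene()$studies[[1]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pgc_tsv(st, path)
  back <- read_pgc_tsv(path)
  expect_identical(back$beta, st$beta)
  expect_identical(back$se, st$se)
  expect_identical(back$pvalue, st$pvalue)
  expect_identical(back$n, as.numeric(st$n))
  # z is rederived as beta/se on read, so it matches its own derivation
  # exactly and the original to rounding error only
  expect_identical(back$z, back$beta / back$se)
  expect_equal(back$z, st$z, tolerance = 1e-12)
  expect_identical(back$rsid, st$rsid)
  expect_identical(back$effect_allele, st$effect_allele)
  expect_identical(attr(back, "trait_name"), attr(st, "trait_name"))
  expect_identical(attr(back, "genome_build"), attr(st, "genome_build"))
  expect_equal(attr(back, "n_effective"), attr(st, "n_effective"))
})

test_that("read_pgc_tsv accepts OR columns and custom column maps", {
  st <- toy_study(50)
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- tibble::tibble(
    SNP = st$rsid, CHR = st$chrom, BP = st$pos, A1 = st$effect_allele,
    A2 = st$other_allele, OR = exp(st$beta),
    SE = pathcross:::fmt_full(st$se), P = pathcross:::fmt_full(st$pvalue),
    N = st$n
  )
  readr::write_tsv(tab, path, progress = FALSE)
  back <- read_pgc_tsv(path)
  expect_equal(back$beta, st$beta, tolerance = 1e-12)
})

test_that("GWAS-VCF write/read round-trips effects exactly and p closely", {
  st <- small_scene()$studies[[2]]
  path <- withr::local_tempfile(fileext = ".vcf")
  write_gwas_vcf(st, path)
  back <- read_gwas_vcf(path)
  expect_identical(back$beta, st$beta)
  expect_identical(back$se, st$se)
  expect_identical(back$n, as.numeric(st$n))
  expect_identical(back$z, back$beta / back$se)
  expect_equal(back$z, st$z, tolerance = 1e-12)
  expect_identical(back$effect_allele, st$effect_allele)
  expect_identical(back$other_allele, st$other_allele)
  expect_equal(back$pvalue, st$pvalue, tolerance = 1e-12)
  expect_identical(attr(back, "trait_name"), attr(st, "trait_name"))
  expect_equal(attr(back, "n_effective"), attr(st, "n_effective"))
})

test_that("read_gwas_vcf skips multiallelics, floors p, recovers missing LP", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=ES,Number=A,Type=Float,Description=\"Effect size\">",
    "##FORMAT=<ID=SE,Number=A,Type=Float,Description=\"Standard error\">",
    "##FORMAT=<ID=LP,Number=A,Type=Float,Description=\"-log10 p\">",
    "##trait_meta=<trait_name=demo,genome_build=GRCh37,n_effective=5000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tdemo",
    "1\t100\trs1\tA\tG\t.\t.\t.\tES:SE:LP\t0.1:0.05:3",
    "1\t200\trs2\tA\tG,C\t.\t.\t.\tES:SE:LP\t0.1:0.05:3",
    "1\t300\trs3\tT\tC\t.\t.\t.\tES:SE:LP\t0.2:0.1:400",
    "1\t400\trs4\tA\tC\t.\t.\t.\tES:SE:LP\t-0.3:0.1:."
  ), path)
  st <- read_gwas_vcf(path)
  expect_equal(nrow(st), 3L)
  expect_false("rs2" %in% st$rsid)
  led <- exclusion_ledger(st)
  expect_equal(led$n[led$reason == "multiallelic"], 1L)
  expect_equal(st$pvalue[st$rsid == "rs3"], .Machine$double.xmin)
  expect_equal(attr(st, "p_floored"), 1L)
  expect_equal(st$pvalue[st$rsid == "rs4"], 2 * pnorm(-3), tolerance = 1e-12)
  expect_equal(st$n, rep(5000, 3))
  expect_identical(attr(st, "trait_name"), "demo")
})

test_that("harmonize_pair undoes swaps and strand flips, drops palindromics", {
  a <- toy_study(400, seed = 21)
  b <- inject_harmonization_noise(a, prop_swap = 0.1, prop_strand = 0.1,
                                  prop_palindromic = 0.05, seed = 7)
  swapped <- attr(b, "swapped")
  pal <- attr(b, "palindromized")
  hp <- harmonize_pair(a, b)
  v <- hp$variants
  expect_equal(nrow(v), 400L - length(pal))
  # swaps are detected and b's effects restored; strand flips leave no trace
  expect_setequal(v$pos[v$flipped], a$pos[swapped])
  expect_identical(v$z_b, v$z_a)
  expect_identical(v$beta_b, v$beta_a)
  # ledger conservation: every input row is shared or accounted for
  led_a <- hp$ledger[hp$ledger$study == "a", ]
  led_b <- hp$ledger[hp$ledger$study == "b", ]
  expect_equal(nrow(v) + sum(led_a$n), nrow(a))
  expect_equal(nrow(v) + sum(led_b$n), nrow(b))
  expect_equal(sum(led_b$n[led_b$reason == "palindromic"]), length(pal))
})

test_that("harmonize_pair falls back to rsID and flags position conflicts", {
  a <- toy_study(200, seed = 22)
  b_tab <- tibble::as_tibble(a)
  moved <- c(10L, 20L, 30L)
  b_tab$pos[moved] <- b_tab$pos[moved] + 7L   # same rsid, shifted position
  b_tab$chrom[50] <- "2"                      # rsid match, chrom conflict
  b <- new_gwas_study(b_tab, trait_name = "b", validate = FALSE)
  hp <- harmonize_pair(a, b)
  expect_true(all(a$rsid[moved] %in% hp$variants$rsid))
  expect_false(a$rsid[50] %in% hp$variants$rsid)
  led <- hp$ledger
  expect_equal(led$n[led$study == "a" & led$reason == "position_conflict"], 1L)
  expect_equal(nrow(hp$variants) +
                 sum(led$n[led$study == "a"]), nrow(a))
})

test_that("harmonize_pair refuses mixed genome builds", {
  a <- toy_study(20)
  b <- toy_study(20)
  attr(b, "genome_build") <- "GRCh38"
  expect_error(harmonize_pair(a, b), "genome builds differ")
})

test_that("harmonized_study extracts an aligned gwas_study", {
  a <- toy_study(100, seed = 31)
  b <- inject_harmonization_noise(a, prop_swap = 0.2, seed = 5)
  hp <- harmonize_pair(a, b)
  sb <- harmonized_study(hp, "b")
  expect_s3_class(sb, "gwas_study")
  expect_equal(nrow(sb), nrow(hp$variants))
  expect_identical(sb$z, hp$variants$z_b)
  expect_identical(sb$effect_allele, hp$variants$effect_allele)
})

test_that("write_ledger_csv emits the ledger", {
  a <- toy_study(100, seed = 41)
  b <- inject_harmonization_noise(a, prop_palindromic = 0.1, seed = 2)
  hp <- harmonize_pair(a, b)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ledger_csv(hp, path)
  back <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  expect_equal(nrow(back), nrow(hp$ledger))
})
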