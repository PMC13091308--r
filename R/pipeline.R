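# End-to-end orchestration: harmonization -> gene scores -> GSEA/DGSEA ->
# TWAS -> LDSC, with per-layer derived seeds, a run manifest, CSV report
# bundle, and layer-level resume from cached results.

#' Assemble a pipeline run configuration
#'
#' Inputs may be in-memory objects (as produced by [simulate_study()]) or
#' file paths: summary statistics in either dialect (auto-detected from the
#' `.vcf` extension), the gene table as TSV, the panel as GMT. The LD
#' reference must align with the row order (by position) of the study
#' tables.
#'
#' @param study_a,study_b `gwas_study` objects or file paths.
#' @param genes Gene tibble or TSV path (gene_id, chrom, start, end,
#'   strand).
#' @param panel A `gene_set_panel` or GMT path.
#' @param ld An `ld_blocks` object (or blocks tibble).
#' @param weights,covariance TWAS model tibbles or TSV paths.
#' @param window_up,window_down Gene mapping windows in bp.
#' @param n_perm GSEA/DGSEA permutations.
#' @param min_size,max_size GSEA set-size filters.
#' @param n_blocks Jackknife blocks.
#' @param bed_pad Annotation padding in bp.
#' @param seed Global seed; each layer draws from a stream derived from it.
#' @param out_dir Output directory for the report bundle.
#' @param resume Reuse cached layer results found in `out_dir`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(study_a, study_b, genes, panel, ld,
                       weights = NULL, covariance = NULL,
                       window_up = 35000, window_down = 10000,
                       n_perm = 10000, min_size = 5, max_size = 500,
                       n_blocks = 200, bed_pad = 10000,
                       seed = 1, out_dir = tempfile("pathcross_run_"),
                       resume = FALSE) {
  structure(list(study_a = study_a, study_b = study_b, genes = genes,
                 panel = panel, ld = ld, weights = weights,
                 covariance = covariance, window_up = window_up,
                 window_down = window_down, n_perm = n_perm,
                 min_size = min_size, max_size = max_size,
                 n_blocks = n_blocks, bed_pad = bed_pad,
                 seed = as.integer(seed), out_dir = out_dir,
                 resume = resume),
            class = "run_config")
}

#' Configuration for a whole scene
#'
#' Convenience wrapper building a [run_config()] straight from a
#' [simulate_study()] scene.
#'
#' @param scene A `gwas_scene`.
#' @param ... Passed to [run_config()].
#' @return A `run_config`.
#' @export
scene_config <- function(scene, ...) {
  run_config(study_a = scene$studies[[1]], study_b = scene$studies[[2]],
             genes = scene$genes, panel = scene$panel, ld = scene$ld,
             weights = scene$weights, covariance = scene$covariance, ...)
}

load_study <- function(x) {
  if (inherits(x, "gwas_study")) return(x)
  if (grepl("\\.vcf$", x)) read_gwas_vcf(x) else read_pgc_tsv(x)
}

load_genes <- function(x) {
  if (is.data.frame(x)) tibble::as_tibble(x)
  else readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
}

load_panel <- function(x) {
  if (inherits(x, "gene_set_panel")) x
  else if (is.data.frame(x)) new_gene_set_panel(x)
  else read_gmt(x)
}

# Execute one cached layer: reuse out_dir/cache/<name>.rds when resuming.
run_layer <- function(name, config, manifest_env, fn) {
  cache_dir <- file.path(config$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  cache <- file.path(cache_dir, paste0(name, ".rds"))
  if (isTRUE(config$resume) && file.exists(cache)) {
    res <- readRDS(cache)
    manifest_env$rows <- dplyr::bind_rows(manifest_env$rows,
      tibble::tibble(layer = name, file = cache, recomputed = FALSE))
    return(res)
  }
  res <- fn()
  saveRDS(res, cache)
  manifest_env$rows <- dplyr::bind_rows(manifest_env$rows,
    tibble::tibble(layer = name, file = cache, recomputed = TRUE))
  res
}

emit <- function(tbl, config, name, manifest_env) {
  path <- file.path(config$out_dir, name)
  listcols <- vapply(tbl, is.list, logical(1))
  for (c in names(tbl)[listcols])
    tbl[[c]] <- vapply(tbl[[c]], paste, character(1), collapse = ";")
  readr::write_csv(tbl, path, progress = FALSE)
  manifest_env$rows <- dplyr::bind_rows(manifest_env$rows,
    tibble::tibble(layer = "report", file = path, recomputed = TRUE))
  invisible(path)
}

#' Run the four-layer cross-disorder analysis end to end
#'
#' Executes harmonization, gene-based association, GSEA + differential
#' GSEA, TWAS, and LDSC (per-study h2, partitioned enrichment with the
#' stratified fallback alongside, and cross-trait rg), writing one CSV per
#' result table plus a manifest. Stochastic layers draw their seeds from
#' the global seed by a fixed per-layer derivation, so reruns with the same
#' configuration are byte-identical; with `resume = TRUE` layers whose
#' cached results exist are reused.
#'
#' @param config A `run_config`.
#' @return A list of class `run_result`: all layer objects plus `manifest`
#'   (tibble of files) and `config_hash`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  me <- new.env(); me$rows <- tibble::tibble(layer = character(),
                                             file = character(),
                                             recomputed = logical())
  study_a <- load_study(config$study_a)
  study_b <- load_study(config$study_b)
  genes <- load_genes(config$genes)
  panel <- load_panel(config$panel)
  ld <- if (inherits(config$ld, "ld_blocks")) config$ld
        else simulate_ld(config$ld)
  ord_a <- order(study_a$chrom, study_a$pos)
  ord_b <- order(study_b$chrom, study_b$pos)
  study_a <- study_a[ord_a, ]; study_b <- study_b[ord_b, ]
  if (nrow(study_a) != sum(ld$sizes) || nrow(study_b) != sum(ld$sizes))
    abort("LD reference dimension does not match the study tables")

  harmonized <- run_layer("harmonize", config, me, function() {
    harmonize_pair(study_a, study_b)
  })
  emit(harmonized$variants, config, "harmonized_variants.csv", me)
  emit(harmonized$ledger, config, "exclusion_ledger.csv", me)

  gene_layer <- run_layer("gene_scores", config, me, function() {
    list(a = run_gene_analysis(study_a, genes, ld,
                               config$window_up, config$window_down),
         b = run_gene_analysis(study_b, genes, ld,
                               config$window_up, config$window_down))
  })
  set_layer <- run_layer("set_test", config, me, function() {
    list(a = competitive_panel_test(gene_layer$a, panel),
         b = competitive_panel_test(gene_layer$b, panel))
  })
  emit(gene_layer$a, config, "gene_scores_a.csv", me)
  emit(gene_layer$b, config, "gene_scores_b.csv", me)
  emit(set_layer$a, config, "set_tests_a.csv", me)
  emit(set_layer$b, config, "set_tests_b.csv", me)

  gsea_layer <- run_layer("gsea", config, me, function() {
    ra <- rank_genes(gene_layer$a); rb <- rank_genes(gene_layer$b)
    list(
      a = gsea(ra, panel, n_perm = config$n_perm,
               min_size = config$min_size, max_size = config$max_size,
               seed = derive_seed(config$seed, "gsea_a")),
      b = gsea(rb, panel, n_perm = config$n_perm,
               min_size = config$min_size, max_size = config$max_size,
               seed = derive_seed(config$seed, "gsea_b")),
      dgsea = dgsea(ra, rb, panel, n_perm = config$n_perm,
                    seed = derive_seed(config$seed, "dgsea"),
                    disorders = c(study_meta(study_a)$trait_name,
                                  study_meta(study_b)$trait_name))
    )
  })
  emit(gsea_layer$a, config, "gsea_a.csv", me)
  emit(gsea_layer$b, config, "gsea_b.csv", me)
  emit(gsea_layer$dgsea, config, "dgsea.csv", me)
  emit(pivot_report(list(a = gsea_layer$a, b = gsea_layer$b)), config,
       "gsea_pivot.csv", me)

  twas_layer <- NULL
  if (!is.null(config$weights)) {
    twas_layer <- run_layer("twas", config, me, function() {
      w <- if (is.data.frame(config$weights)) config$weights
           else readr::read_tsv(config$weights, show_col_types = FALSE)
      cv <- if (is.data.frame(config$covariance)) config$covariance
            else readr::read_tsv(config$covariance, show_col_types = FALSE)
      ta <- run_twas(study_a, w, cv)
      tb <- run_twas(study_b, w, cv)
      list(a = ta, b = tb,
           enrichment_a = twas_panel_enrichment(ta, panel),
           enrichment_b = twas_panel_enrichment(tb, panel),
           best_a = best_tissue_summary(ta),
           best_b = best_tissue_summary(tb))
    })
    emit(twas_layer$a, config, "twas_a.csv", me)
    emit(twas_layer$b, config, "twas_b.csv", me)
    emit(twas_layer$enrichment_a, config, "twas_enrichment_a.csv", me)
    emit(twas_layer$enrichment_b, config, "twas_enrichment_b.csv", me)
    emit(twas_layer$best_a, config, "twas_best_tissue_a.csv", me)
    emit(twas_layer$best_b, config, "twas_best_tissue_b.csv", me)
  }

  ldsc_layer <- run_layer("ldsc", config, me, function() {
    dpanel <- dedup_panel(panel)
    set_names <- unique(dpanel$set)
    beds <- lapply(setNames(set_names, set_names), function(s) {
      make_annotation_bed(genes[genes$gene_id %in%
                                  dpanel$gene_id[dpanel$set == s], ],
                          pad = config$bed_pad)
    })
    masks <- lapply(beds, function(b) which(annotation_mask(study_a, b)))
    scores <- compute_ld_scores(ld, masks)
    nb <- min(config$n_blocks, floor(nrow(study_a) / 50))
    h2a <- estimate_h2(study_a$chi2, scores$l2,
                       attr(study_a, "n_effective"), n_blocks = nb)
    h2b <- estimate_h2(study_b$chi2, scores$l2,
                       attr(study_b, "n_effective"), n_blocks = nb)
    part_a <- partitioned_h2(study_a$chi2, scores, masks,
                             attr(study_a, "n_effective"), n_blocks = nb)
    part_b <- partitioned_h2(study_b$chi2, scores, masks,
                             attr(study_b, "n_effective"), n_blocks = nb)
    fb_a <- purrr::imap_dfr(masks, function(mk, nm)
      dplyr::mutate(fallback_enrichment(study_a$chi2, mk, scores$l2),
                    annotation = nm, .before = 1))
    fb_b <- purrr::imap_dfr(masks, function(mk, nm)
      dplyr::mutate(fallback_enrichment(study_b$chi2, mk, scores$l2),
                    annotation = nm, .before = 1))
    # rg on the harmonized shared set, aligned to the LD score rows
    hv <- harmonized$variants
    idx <- match(hv$key, paste0(study_a$chrom, ":", study_a$pos))
    ord <- order(idx)
    rg <- genetic_correlation(hv$z_a[ord], hv$z_b[ord], scores$l2[idx[ord]],
                              attr(study_a, "n_effective"),
                              attr(study_b, "n_effective"),
                              n_blocks = min(config$n_blocks,
                                             floor(length(idx) / 50)))
    list(beds = beds, masks = masks, scores = scores, h2_a = h2a,
         h2_b = h2b, partitioned_a = part_a, partitioned_b = part_b,
         fallback_a = fb_a, fallback_b = fb_b, rg = rg)
  })
  for (s in names(ldsc_layer$beds)) {
    path <- file.path(config$out_dir, paste0("annot_", s, ".bed"))
    write_bed(ldsc_layer$beds[[s]], path)
    me$rows <- dplyr::bind_rows(me$rows,
      tibble::tibble(layer = "report", file = path, recomputed = TRUE))
  }
  emit(ldsc_layer$partitioned_a, config, "partitioned_h2_a.csv", me)
  emit(ldsc_layer$partitioned_b, config, "partitioned_h2_b.csv", me)
  emit(ldsc_layer$fallback_a, config, "fallback_enrichment_a.csv", me)
  emit(ldsc_layer$fallback_b, config, "fallback_enrichment_b.csv", me)
  emit(glance(ldsc_layer$rg), config, "genetic_correlation.csv", me)

  manifest <- me$rows
  hash <- rlang::hash(config[setdiff(names(config), "resume")])
  readr::write_csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   progress = FALSE)
  structure(list(
    harmonized = harmonized, gene_scores = gene_layer,
    set_tests = set_layer, gsea = gsea_layer, twas = twas_layer,
    ldsc = ldsc_layer, manifest = manifest, config_hash = hash,
    out_dir = config$out_dir
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d output files in %s (config %s)\n",
              nrow(x$manifest), x$out_dir, substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Simulate a scene and validate every estimator against its ground truth
#'
#' Generates the configured scene, runs the pipeline, and reports estimated
#' versus true values for per-trait heritability, cross-trait rg, and
#' per-annotation enrichment, flagging each as consistent when the truth
#' lies within two jackknife standard errors (rg additionally reported as
#' "consistent with zero" when |rg| < 2 SE).
#'
#' @param config A `sim_config` (must carry a truth block: h2, rg, and any
#'   annotation multipliers).
#' @param ... Passed to [scene_config()] (e.g. `n_perm`, `out_dir`).
#' @return A list of class `validation_report`: `checks` tibble
#'   (quantity, truth, estimate, se, consistent), the `run_result`, and the
#'   scene.
#' @export
simulate_and_validate <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$h2) || is.null(config$rg))
    abort("validation needs a truth block: the config must set h2 and rg")
  scene <- simulate_study(config)
  res <- run_all(scene_config(scene, seed = config$seed, ...))
  truth_mult <- config$annotations
  checks <- tibble::tibble(
    quantity = c("h2_a", "h2_b", "rg"),
    truth = c(config$h2[1], config$h2[2], config$rg),
    estimate = c(res$ldsc$h2_a$h2, res$ldsc$h2_b$h2, res$ldsc$rg$rg),
    se = c(res$ldsc$h2_a$h2_se, res$ldsc$h2_b$h2_se, res$ldsc$rg$se)
  )
  if (!is.null(config$enriched_set)) {
    nm <- paste0("set_", config$enriched_set$set)
    row <- res$ldsc$partitioned_a[
      res$ldsc$partitioned_a$annotation == config$enriched_set$set, ]
    if (nrow(row))
      checks <- dplyr::bind_rows(checks, tibble::tibble(
        quantity = paste0("enrichment_", config$enriched_set$set),
        truth = config$enriched_set$multiplier,
        estimate = row$enrichment, se = row$se_jackknife))
  }
  checks$consistent <- abs(checks$estimate - checks$truth) <= 2 * checks$se
  checks$consistent_with_zero <- abs(checks$estimate) < 2 * checks$se
  structure(list(checks = checks, run = res, scene = scene),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  print(as.data.frame(x$checks), row.names = FALSE)
  invisible(x)
}
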