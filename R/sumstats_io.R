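# Reading, validation and harmonization of GWAS summary statistics in the
# two dialects the pipeline accepts: PGC-style tab-separated text and
# GWAS-VCF with ES:SE:LP FORMAT fields.

#' Construct a validated GWAS study table
#'
#' Validates per-variant association records, drops rows violating the
#' contract (nonpositive SE, p outside (0,1], identical alleles, missing
#' fields), and attaches study metadata plus an exclusion ledger.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `rsid`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `n` (and
#'   optionally `z`, `chi2`, which are derived when absent).
#' @param trait_name Study label.
#' @param n_cases,n_controls Case-control counts, or `NULL`.
#' @param n_effective Effective sample size; computed from case-control
#'   counts when both are given.
#' @param genome_build Genome build label (studies must share it to be
#'   harmonized; no liftover is performed).
#' @param validate Set `FALSE` to skip row validation (internal use on
#'   already-validated tables).
#' @return A tibble of class `gwas_study` with attributes `trait_name`,
#'   `n_cases`, `n_controls`, `n_effective`, `genome_build`, `ledger`.
#' @export
new_gwas_study <- function(variants, trait_name = "trait", n_cases = NULL,
                           n_controls = NULL, n_effective = NULL,
                           genome_build = "GRCh37", validate = TRUE) {
  variants <- tibble::as_tibble(variants)
  needed <- c("chrom", "pos", "effect_allele", "other_allele",
              "beta", "se", "pvalue", "n")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols))
    abort(paste0("missing mandatory columns: ",
                 paste(missing_cols, collapse = ", ")))
  if (!"rsid" %in% names(variants)) variants$rsid <- NA_character_
  ledger <- tibble::tibble(reason = character(), n = integer())
  if (validate) {
    bad <- list(
      unparseable = !is.finite(variants$beta) | !is.finite(variants$se) |
        !is.finite(variants$pvalue) | is.na(variants$chrom) |
        is.na(variants$pos),
      nonpositive_se = is.finite(variants$se) & variants$se <= 0,
      invalid_p = is.finite(variants$pvalue) &
        (variants$pvalue <= 0 | variants$pvalue > 1),
      identical_alleles = !is.na(variants$effect_allele) &
        toupper(variants$effect_allele) == toupper(variants$other_allele)
    )
    drop <- rep(FALSE, nrow(variants))
    for (r in names(bad)) {
      hit <- bad[[r]] & !drop
      hit[is.na(hit)] <- FALSE
      if (any(hit))
        ledger <- dplyr::bind_rows(ledger,
          tibble::tibble(reason = r, n = sum(hit)))
      drop <- drop | hit
    }
    variants <- variants[!drop, , drop = FALSE]
  }
  variants$effect_allele <- toupper(variants$effect_allele)
  variants$other_allele <- toupper(variants$other_allele)
  variants$z <- variants$beta / variants$se
  variants$chi2 <- variants$z^2
  if (is.null(n_effective)) {
    n_effective <- if (!is.null(n_cases) && !is.null(n_controls))
      effective_sample_size(n_cases, n_controls)
    else
      round(stats::median(variants$n))
  }
  structure(variants,
            class = c("gwas_study", class(tibble::tibble())),
            trait_name = trait_name, n_cases = n_cases,
            n_controls = n_controls, n_effective = n_effective,
            genome_build = genome_build, ledger = ledger)
}

#' Study metadata
#' @param study A `gwas_study`.
#' @return A one-row tibble (trait_name, n_cases, n_controls, n_effective,
#'   genome_build, n_variants).
#' @export
study_meta <- function(study) {
  tibble::tibble(
    trait_name = attr(study, "trait_name") %||% NA_character_,
    n_cases = attr(study, "n_cases") %||% NA_real_,
    n_controls = attr(study, "n_controls") %||% NA_real_,
    n_effective = attr(study, "n_effective") %||% NA_real_,
    genome_build = attr(study, "genome_build") %||% NA_character_,
    n_variants = nrow(study)
  )
}

#' Exclusion ledger of a study or harmonized pair
#' @param x A `gwas_study` or `harmonized_pair`.
#' @return Tibble of exclusion reasons and counts.
#' @export
exclusion_ledger <- function(x) {
  if (inherits(x, "harmonized_pair")) x$ledger
  else attr(x, "ledger") %||% tibble::tibble(reason = character(), n = integer())
}

#' Effective sample size of a case-control study
#'
#' The equivalent balanced-design N: `4 / (1/n_cases + 1/n_controls)`,
#' rounded to the nearest integer. A balanced design returns the total N.
#'
#' @param n_cases,n_controls Positive case and control counts.
#' @return Integer effective sample size.
#' @examples
#' effective_sample_size(27205, 110881) # 87381
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  if (any(n_cases <= 0) || any(n_controls <= 0))
    abort("case and control counts must be positive")
  round(4 / (1 / n_cases + 1 / n_controls))
}

# Default logical -> physical column map for dialect A.
default_col_map <- function() {
  c(SNP = "SNP", CHR = "CHR", BP = "BP", A1 = "A1", A2 = "A2",
    BETA = "BETA", SE = "SE", P = "P", N = "N", NCAS = "NCAS", NCON = "NCON")
}

#' Read PGC-style tab-separated summary statistics (dialect A)
#'
#' Expects a TSV with logical columns SNP, CHR, BP, A1 (effect allele),
#' A2 (other allele), BETA (or OR, log-transformed on read), SE, P, and
#' either N or case-control counts NCAS/NCON. Leading `#` comment lines may
#' carry `key=value` metadata (`trait_name`, `genome_build`, `n_cases`,
#' `n_controls`).
#'
#' @param path File path.
#' @param col_map Named character vector mapping logical to physical column
#'   names (defaults cover the standard layout).
#' @return A `gwas_study`.
#' @export
read_pgc_tsv <- function(path, col_map = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  cm <- default_col_map()
  if (!is.null(col_map)) cm[names(col_map)] <- col_map
  meta <- parse_hash_meta(path)
  # read everything as text and convert with strtod (`as.numeric`), which
  # rounds correctly, so 17-digit output round-trips bit for bit
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  has_or <- !cm[["BETA"]] %in% names(raw) && "OR" %in% names(raw)
  required <- cm[c("SNP", "CHR", "BP", "A1", "A2", "SE", "P")]
  if (!has_or) required <- c(required, cm[["BETA"]])
  miss <- setdiff(unname(required), names(raw))
  if (length(miss))
    abort(paste0("mandatory column(s) missing from ", path, ": ",
                 paste(miss, collapse = ", ")))
  n_cases <- meta$n_cases
  n_controls <- meta$n_controls
  if (cm[["NCAS"]] %in% names(raw) && cm[["NCON"]] %in% names(raw)) {
    n_cases <- n_cases %||%
      round(stats::median(as.numeric(raw[[cm[["NCAS"]]]])))
    n_controls <- n_controls %||%
      round(stats::median(as.numeric(raw[[cm[["NCON"]]]])))
  }
  n_col <- if (cm[["N"]] %in% names(raw)) as.numeric(raw[[cm[["N"]]]])
    else if (!is.null(n_cases) && !is.null(n_controls))
      rep(effective_sample_size(n_cases, n_controls), nrow(raw))
    else abort("neither an N column nor case-control counts are available")
  variants <- tibble::tibble(
    chrom = as.character(raw[[cm[["CHR"]]]]),
    pos = as.integer(raw[[cm[["BP"]]]]),
    rsid = as.character(raw[[cm[["SNP"]]]]),
    effect_allele = as.character(raw[[cm[["A1"]]]]),
    other_allele = as.character(raw[[cm[["A2"]]]]),
    beta = if (has_or) log(as.numeric(raw[["OR"]]))
           else as.numeric(raw[[cm[["BETA"]]]]),
    se = as.numeric(raw[[cm[["SE"]]]]),
    pvalue = as.numeric(raw[[cm[["P"]]]]),
    n = as.numeric(n_col)
  )
  new_gwas_study(variants,
                 trait_name = meta$trait_name %||% "trait",
                 n_cases = n_cases, n_controls = n_controls,
                 genome_build = meta$genome_build %||% "GRCh37")
}

# Parse "# key=value" comment lines at the top of a dialect-A file.
parse_hash_meta <- function(path) {
  lines <- readLines(path, n = 20L)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (l in lines) {
    kv <- stringr::str_match_all(l, "(\\w+)=([^\\s]+)")[[1]]
    for (r in seq_len(nrow(kv))) out[[kv[r, 2]]] <- kv[r, 3]
  }
  for (k in c("n_cases", "n_controls"))
    if (!is.null(out[[k]])) out[[k]] <- as.numeric(out[[k]])
  out
}

#' Write a study as dialect-A TSV
#'
#' Numeric fields are written with 17 significant digits so a write/read
#' cycle preserves them bit for bit.
#'
#' @param study A `gwas_study`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgc_tsv <- function(study, path) {
  meta <- study_meta(study)
  hdr <- sprintf("# trait_name=%s genome_build=%s%s",
                 meta$trait_name, meta$genome_build,
                 if (!is.na(meta$n_cases) && !is.na(meta$n_controls))
                   sprintf(" n_cases=%d n_controls=%d",
                           as.integer(meta$n_cases),
                           as.integer(meta$n_controls)) else "")
  tab <- tibble::tibble(
    SNP = study$rsid, CHR = study$chrom, BP = study$pos,
    A1 = study$effect_allele, A2 = study$other_allele,
    BETA = fmt_full(study$beta), SE = fmt_full(study$se),
    P = fmt_full(study$pvalue), N = fmt_full(study$n)
  )
  writeLines(hdr, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Write a study as GWAS-VCF (dialect B)
#'
#' One sample column carrying ES (effect size of the ALT allele), SE, LP
#' (-log10 p) and SS (per-variant sample size). ALT is the effect allele,
#' REF the other allele.
#'
#' @param study A `gwas_study`.
#' @param path Output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_gwas_vcf <- function(study, path) {
  meta <- study_meta(study)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=ES,Number=A,Type=Float,Description=\"Effect size estimate relative to the alternative allele\">",
    "##FORMAT=<ID=SE,Number=A,Type=Float,Description=\"Standard error of effect size estimate\">",
    "##FORMAT=<ID=LP,Number=A,Type=Float,Description=\"-log10 p-value for effect estimate\">",
    "##FORMAT=<ID=SS,Number=A,Type=Float,Description=\"Sample size used to estimate genetic effect\">",
    sprintf("##trait_meta=<trait_name=%s,genome_build=%s,n_effective=%s%s>",
            meta$trait_name, meta$genome_build,
            fmt_full(meta$n_effective),
            if (!is.na(meta$n_cases) && !is.na(meta$n_controls))
              sprintf(",n_cases=%d,n_controls=%d",
                      as.integer(meta$n_cases), as.integer(meta$n_controls))
            else ""),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           meta$trait_name)
  )
  lp <- -log10(study$pvalue)
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.\tES:SE:LP:SS\t%s:%s:%s:%s",
                  study$chrom, study$pos,
                  ifelse(is.na(study$rsid), ".", study$rsid),
                  study$other_allele, study$effect_allele,
                  fmt_full(study$beta), fmt_full(study$se),
                  fmt_full(lp), fmt_full(study$n))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read GWAS-VCF summary statistics (dialect B)
#'
#' Extracts ES/SE/LP (and SS when present) from the single sample column:
#' `beta <- ES`, `se <- SE`, `pvalue <- 10^(-LP)`. ALT is taken as the
#' effect allele and REF as the other allele. Multi-allelic records are
#' skipped (ledger `multiallelic`). A p-value underflowing double precision
#' is floored at the smallest positive double, never zero.
#'
#' @param path Path to a VCF 4.x file.
#' @return A `gwas_study`.
#' @export
read_gwas_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf),
                                         stringsAsFactors = FALSE))
  meta <- parse_vcf_trait_meta(vcf@meta)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  get_fmt <- function(el) {
    v <- suppressWarnings(
      vcfR::extract.gt(vcf, element = el, as.numeric = TRUE))
    as.numeric(v[, 1])
  }
  es <- get_fmt("ES"); se <- get_fmt("SE"); lp <- get_fmt("LP")
  fmt_fields <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  ss <- if ("SS" %in% fmt_fields) get_fmt("SS") else
    rep(meta$n_effective %||% NA_real_, nrow(fix))
  p <- 10^(-lp)
  floored <- is.finite(lp) & p == 0
  p[floored] <- .Machine$double.xmin
  # LP missing but ES/SE present: recover p from z.
  fill <- is.na(p) & is.finite(es) & is.finite(se) & se > 0
  p[fill] <- 2 * pnorm(-abs(es[fill] / se[fill]))
  variants <- tibble::tibble(
    chrom = as.character(fix$CHROM), pos = as.integer(fix$POS),
    rsid = ifelse(fix$ID == ".", NA_character_, as.character(fix$ID)),
    effect_allele = as.character(fix$ALT),
    other_allele = as.character(fix$REF),
    beta = es, se = se, pvalue = p, n = ss
  )[!multi, , drop = FALSE]
  study <- new_gwas_study(variants,
                          trait_name = meta$trait_name %||% "trait",
                          n_cases = meta$n_cases,
                          n_controls = meta$n_controls,
                          n_effective = meta$n_effective,
                          genome_build = meta$genome_build %||% "GRCh37")
  if (any(multi)) {
    attr(study, "ledger") <- dplyr::bind_rows(
      attr(study, "ledger"),
      tibble::tibble(reason = "multiallelic", n = sum(multi)))
  }
  attr(study, "p_floored") <- sum(floored)
  study
}

parse_vcf_trait_meta <- function(meta_lines) {
  l <- grep("^##trait_meta=", meta_lines, value = TRUE)
  out <- list()
  if (length(l)) {
    body <- sub("^##trait_meta=<", "", sub(">\\s*$", "", l[1]))
    kv <- stringr::str_match_all(body, "(\\w+)=([^,>]+)")[[1]]
    for (r in seq_len(nrow(kv))) out[[kv[r, 2]]] <- kv[r, 3]
    for (k in c("n_cases", "n_controls", "n_effective"))
      if (!is.null(out[[k]])) out[[k]] <- as.numeric(out[[k]])
  }
  out$trait_meta <- NULL
  out
}

#' Harmonize two studies onto a shared variant set
#'
#' Matches variants on chromosome:position (rsID fallback for keys absent
#' from one side), resolves allele swaps (study 2's z and beta negated) and
#' strand flips (alleles complemented, then the same rules), drops
#' palindromic (A/T, C/G) variants whose strand cannot be resolved, and
#' records every exclusion in a ledger. Study 2's effects are re-expressed
#' relative to study 1's effect allele.
#'
#' @param a,b Two `gwas_study` tables on the same genome build.
#' @return A list of class `harmonized_pair`: `variants` (shared table with
#'   `z_a`, `z_b`, `beta_a`, `beta_b`, ... columns), `ledger` (study,
#'   reason, n), `meta_a`, `meta_b`.
#' @export
harmonize_pair <- function(a, b) {
  build_a <- attr(a, "genome_build") %||% "GRCh37"
  build_b <- attr(b, "genome_build") %||% "GRCh37"
  if (!identical(build_a, build_b))
    abort(sprintf("genome builds differ (%s vs %s); no liftover is performed",
                  build_a, build_b))
  ledger <- tibble::tibble(study = character(), reason = character(),
                           n = integer())
  note <- function(study, reason, k) {
    if (k > 0)
      ledger <<- dplyr::bind_rows(ledger,
        tibble::tibble(study = study, reason = reason, n = as.integer(k)))
  }
  prep <- function(s, label) {
    s <- tibble::as_tibble(s)
    s$key <- paste0(s$chrom, ":", s$pos)
    dup <- duplicated(s$key)
    note(label, "duplicate_key", sum(dup))
    s <- s[!dup, , drop = FALSE]
    pal <- is_palindromic(s$effect_allele, s$other_allele)
    note(label, "palindromic", sum(pal))
    s[!pal, , drop = FALSE]
  }
  ta <- prep(a, "a")
  tb <- prep(b, "b")

  matched_key <- intersect(ta$key, tb$key)
  ia <- match(matched_key, ta$key)
  ib <- match(matched_key, tb$key)

  # rsID fallback for keys absent on the chrom:pos index.
  rest_a <- ta[-ia, , drop = FALSE]
  rest_b <- tb[-ib, , drop = FALSE]
  ra <- rest_a[!is.na(rest_a$rsid) & !duplicated(rest_a$rsid), , drop = FALSE]
  rb <- rest_b[!is.na(rest_b$rsid) & !duplicated(rest_b$rsid), , drop = FALSE]
  common_rs <- intersect(ra$rsid, rb$rsid)
  n_conflict <- 0L
  if (length(common_rs)) {
    ja <- match(common_rs, ra$rsid)
    jb <- match(common_rs, rb$rsid)
    conflict <- ra$chrom[ja] != rb$chrom[jb]
    n_conflict <- sum(conflict)
    ja <- ja[!conflict]; jb <- jb[!conflict]
    ia <- c(ia, match(ra$key[ja], ta$key))
    ib <- c(ib, match(rb$key[jb], tb$key))
  }
  note("a", "position_conflict", n_conflict)
  note("b", "position_conflict", n_conflict)

  sa <- ta[ia, , drop = FALSE]
  sb <- tb[ib, , drop = FALSE]

  # Allele reconciliation against study 1's coding.
  ea <- sa$effect_allele; oa <- sa$other_allele
  eb <- sb$effect_allele; ob <- sb$other_allele
  ebc <- complement_allele(eb); obc <- complement_allele(ob)
  exact <- eb == ea & ob == oa
  swap <- eb == oa & ob == ea
  s_exact <- ebc == ea & obc == oa & !exact & !swap
  s_swap <- ebc == oa & obc == ea & !exact & !swap
  keep <- exact | swap | s_exact | s_swap
  flip <- swap | s_swap
  note("a", "allele_mismatch", sum(!keep))
  note("b", "allele_mismatch", sum(!keep))
  note("a", "unmatched", nrow(ta) - length(ia) - n_conflict)
  note("b", "unmatched", nrow(tb) - length(ib) - n_conflict)

  sa <- sa[keep, , drop = FALSE]
  sb <- sb[keep, , drop = FALSE]
  flip <- flip[keep]
  sgn <- ifelse(flip, -1, 1)
  variants <- tibble::tibble(
    key = sa$key, chrom = sa$chrom, pos = sa$pos, rsid = sa$rsid,
    effect_allele = sa$effect_allele, other_allele = sa$other_allele,
    beta_a = sa$beta, se_a = sa$se, pvalue_a = sa$pvalue, n_a = sa$n,
    z_a = sa$z,
    beta_b = sgn * sb$beta, se_b = sb$se, pvalue_b = sb$pvalue, n_b = sb$n,
    z_b = sgn * sb$z,
    flipped = flip
  )
  ledger <- ledger |>
    dplyr::group_by(.data$study, .data$reason) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  structure(list(variants = variants, ledger = ledger,
                 meta_a = study_meta(a), meta_b = study_meta(b)),
            class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("<harmonized_pair> %d shared variants (%s vs %s)\n",
              nrow(x$variants), x$meta_a$trait_name, x$meta_b$trait_name))
  if (nrow(x$ledger)) {
    cat("exclusions:\n")
    print(as.data.frame(x$ledger), row.names = FALSE)
  }
  invisible(x)
}

#' Convert one side of a harmonized pair back to a study table
#'
#' @param hp A `harmonized_pair`.
#' @param side `"a"` or `"b"`.
#' @return A `gwas_study` restricted to the shared, allele-aligned variants.
#' @export
harmonized_study <- function(hp, side = c("a", "b")) {
  side <- match.arg(side)
  v <- hp$variants
  meta <- if (side == "a") hp$meta_a else hp$meta_b
  tab <- tibble::tibble(
    chrom = v$chrom, pos = v$pos, rsid = v$rsid,
    effect_allele = v$effect_allele, other_allele = v$other_allele,
    beta = v[[paste0("beta_", side)]], se = v[[paste0("se_", side)]],
    pvalue = v[[paste0("pvalue_", side)]], n = v[[paste0("n_", side)]]
  )
  new_gwas_study(tab, trait_name = meta$trait_name,
                 n_effective = meta$n_effective,
                 genome_build = meta$genome_build, validate = FALSE)
}

#' Write the exclusion ledger of a harmonized pair as CSV
#' @param hp A `harmonized_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(hp, path) {
  readr::write_csv(hp$ledger, path, progress = FALSE)
  invisible(path)
}
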