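# Small shared helpers: allele arithmetic, seed derivation, validation.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Strand-complement alleles
#'
#' Complements single-base alleles (A<->T, C<->G). Multi-base (indel) alleles
#' are complemented base by base and reversed.
#'
#' @param allele Character vector of alleles.
#' @return Character vector of complemented alleles.
#' @keywords internal
complement_allele <- function(allele) {
  vapply(allele, function(a) {
    bases <- strsplit(a, "", fixed = TRUE)[[1]]
    paste(rev(unname(DNA_COMPLEMENT[bases])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Identify palindromic (strand-ambiguous) allele pairs
#'
#' A variant is palindromic when its two alleles are strand complements of
#' each other (A/T or C/G): the strand cannot be resolved from alleles alone.
#'
#' @param a1,a2 Character vectors of alleles.
#' @return Logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & toupper(a2) == complement_allele(toupper(a1))
}

#' Derive a reproducible sub-seed from a global seed and a label
#'
#' Each analysis layer draws from its own stream so that adding a layer never
#' shifts another layer's random numbers. The derivation is a fixed integer
#' hash of (seed, label), kept within the 32-bit range R requires.
#'
#' @param seed Integer global seed.
#' @param label Character label for the stream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 69069 + h * 7919 + 12345) %% 2147483647)
}

# Assert a scalar probability-like value.
check_prob <- function(x, name, open_left = TRUE, closed_right = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (closed_right) x <= 1 else x < 1)
  if (!ok) abort(sprintf("`%s` must be a probability in %s0,1%s, got %s",
                         name, if (open_left) "(" else "[",
                         if (closed_right) "]" else ")",
                         format(x)))
  invisible(x)
}

# Format doubles so that write -> read round-trips bit for bit.
fmt_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}
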