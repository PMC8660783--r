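#' Normalise variant alleles to a minimal anchored representation
#'
#' Different platforms (and different variant callers) may report the same
#' underlying allele with different amounts of flanking reference sequence.
#' Normalisation trims the shared suffix, then the shared prefix, always
#' keeping at least one base on each allele (the usual VCF anchor base), and
#' shifts the reported position right by the number of prefix bases removed.
#' Idempotent: normalising a normalised allele is a no-op.
#'
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of reference / alternate alleles.
#' @return A tibble with columns `pos`, `ref`, `alt`.
#' @export
#' @examples
#' normalise_alleles(100, "CAG", "CA")   # -> pos 101, AG > A
normalise_alleles <- function(pos, ref, alt) {
  n <- length(pos)
  stopifnot(length(ref) == n, length(alt) == n)
  if (any(ref == alt)) {
    abort("ref and alt alleles must differ")
  }
  out_pos <- as.integer(pos)
  out_ref <- toupper(ref)
  out_alt <- toupper(alt)
  for (i in seq_len(n)) {
    r <- out_ref[i]
    a <- out_alt[i]
    p <- out_pos[i]
    # shared suffix first
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # then shared prefix, shifting the anchor position
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    out_ref[i] <- r
    out_alt[i] <- a
    out_pos[i] <- p
  }
  tibble(pos = out_pos, ref = out_ref, alt = out_alt)
}

#' Build a joinable variant key
#'
#' The key is `chrom:pos:ref:alt` on the normalised representation, so two
#' reports of the same underlying allele from different call sets map to the
#' same key.
#'
#' @param chrom Character vector of chromosome names (used as given; the key
#'   is genome-build-agnostic).
#' @inheritParams normalise_alleles
#' @param normalise Normalise alleles first (default `TRUE`).
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt, normalise = TRUE) {
  if (normalise) {
    nm <- normalise_alleles(pos, ref, alt)
    pos <- nm$pos
    ref <- nm$ref
    alt <- nm$alt
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

# Split keys back into components.
parse_variant_key <- function(key) {
  parts <- str_split(key, stringr::fixed(":"), simplify = TRUE)
  tibble(
    chrom = parts[, 1],
    pos = as.integer(parts[, 2]),
    ref = parts[, 3],
    alt = parts[, 4]
  )
}
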