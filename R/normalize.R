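#' Normalize small variants (left-align and trim)
#'
#' Rewrites each record in its canonical minimal left-aligned form, the
#' representation-independent key used when intersecting callsets from
#' different callers: shared trailing bases are trimmed (extending the
#' alleles leftward from the genome when one allele would become empty),
#' then shared leading bases are trimmed while both alleles keep at
#' least one base. SNVs are fixed points and the operation is
#' idempotent; the reconstructed haplotype (genome with the variant
#' applied) is unchanged by normalization.
#'
#' @param variants A `small_variant_table`.
#' @param genome The [ScaffoldSet] the coordinates refer to; `ref`
#'   alleles must match it.
#' @return The normalized table (same rows, possibly new `pos`, `ref`,
#'   `alt`).
#' @export
normalize_small_variant <- function(variants, genome) {
  if (nrow(variants) == 0) return(variants)
  validate_small_variants(variants, genome = genome)
  for (i in seq_len(nrow(variants))) {
    chrom <- variants$chrom[i]
    pos <- variants$pos[i]
    ref <- variants$ref[i]
    alt <- variants$alt[i]
    repeat {
      rn <- nchar(ref); an <- nchar(alt)
      if (rn > 0 && an > 0 &&
          substr(ref, rn, rn) == substr(alt, an, an) &&
          (rn > 1 || an > 1)) {
        # drop shared last base; refill from the left if one side empties
        ref <- substr(ref, 1, rn - 1)
        alt <- substr(alt, 1, an - 1)
        if (nchar(ref) == 0 || nchar(alt) == 0) {
          if (pos == 1) { # cannot extend left; restore the base
            ref <- paste0(ref, substr(variants$ref[i], rn, rn))
            alt <- paste0(alt, substr(variants$alt[i], an, an))
            break
          }
          pos <- pos - 1
          b <- scaffold_seq(genome, chrom, pos, pos)
          ref <- paste0(b, ref)
          alt <- paste0(b, alt)
        }
        next
      }
      if (rn > 1 && an > 1 && substr(ref, 1, 1) == substr(alt, 1, 1)) {
        ref <- substr(ref, 2, rn)
        alt <- substr(alt, 2, an)
        pos <- pos + 1
        next
      }
      break
    }
    variants$pos[i] <- pos
    variants$ref[i] <- ref
    variants$alt[i] <- alt
  }
  variants
}

#' Apply small variants to a genome (haplotype reconstruction)
#'
#' Builds the mutated sequence of one scaffold by substituting each
#' variant's alt allele for its ref allele. Variants must not overlap.
#' Used both by the simulator and as the ground truth that
#' [normalize_small_variant()] must preserve.
#'
#' @param genome A [ScaffoldSet].
#' @param variants A `small_variant_table` restricted to one scaffold.
#' @param chrom Scaffold to mutate.
#' @return The mutated sequence as a character string.
#' @export
apply_small_variants <- function(genome, variants, chrom) {
  v <- variants[variants$chrom == chrom, , drop = FALSE]
  s <- scaffold_seq(genome, chrom)
  if (nrow(v) == 0) return(s)
  v <- v[order(v$pos), , drop = FALSE]
  if (any(v$pos[-1] <= v$pos[-nrow(v)] + nchar(v$ref[-nrow(v)]) - 1))
    stop("overlapping variants cannot be applied")
  pieces <- character(0)
  cur <- 1
  for (i in seq_len(nrow(v))) {
    if (v$pos[i] > cur)
      pieces <- c(pieces, substr(s, cur, v$pos[i] - 1))
    obs <- substr(s, v$pos[i], v$pos[i] + nchar(v$ref[i]) - 1)
    if (obs != v$ref[i])
      stop("ref mismatch at ", chrom, ":", v$pos[i])
    pieces <- c(pieces, v$alt[i])
    cur <- v$pos[i] + nchar(v$ref[i])
  }
  if (cur <= nchar(s)) pieces <- c(pieces, substr(s, cur, nchar(s)))
  paste(pieces, collapse = "")
}
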