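#' Rotate a circular contig to a canonical anchor
#'
#' Mitochondrial genomes are circular, so two correctly assembled
#' copies can begin at arbitrary offsets and on either strand. This
#' locates `anchor_seq` (>= 20 bp, e.g. the first bases of a reference
#' mitogenome) in the contig or its reverse complement, allowing up to
#' `max_mismatch` substitutions, and returns the strand-corrected
#' contig rotated to begin at the anchor. The anchor must occur exactly
#' once on the circle.
#'
#' @param contig Circular contig sequence (character).
#' @param anchor_seq Anchor sequence, at least 20 bp.
#' @param max_mismatch Substitutions tolerated when locating the anchor
#'   (default 2).
#' @return The rotated sequence (same length as `contig`).
#' @export
rotate_circular_to_anchor <- function(contig, anchor_seq,
                                      max_mismatch = 2L) {
  contig <- toupper(contig)
  anchor_seq <- toupper(anchor_seq)
  k <- nchar(anchor_seq)
  if (k < 20) stop("anchor must be at least 20 bp")
  L <- nchar(contig)
  if (k > L) stop("anchor longer than contig")
  find_starts <- function(s) {
    # search the doubled sequence so anchors crossing the origin are
    # found; report distinct circular offsets only
    doubled <- paste0(s, substr(s, 1, k - 1))
    m <- Biostrings::matchPattern(anchor_seq,
                                  Biostrings::DNAString(doubled),
                                  max.mismatch = max_mismatch)
    sort(unique((Biostrings::start(m) - 1L) %% L + 1L))
  }
  fwd <- find_starts(contig)
  rc <- revcomp(contig)
  rev <- find_starts(rc)
  hits <- length(fwd) + length(rev)
  if (hits == 0) stop("anchor not found in contig (either strand)")
  if (hits > 1) stop("anchor located ", hits, " times; cannot orient")
  if (length(fwd)) {
    p <- fwd[1]
    s <- contig
  } else {
    p <- rev[1]
    s <- rc
  }
  if (p == 1) return(s)
  paste0(substr(s, p, L), substr(s, 1, p - 1))
}

#' Compare two anchored mitogenomes
#'
#' Globally aligns two rotated mitochondrial sequences (banded
#' affine-gap alignment; the band is sized from the length difference)
#' and reports substitution columns, with indel runs listed separately
#' and excluded from the substitution list. Substitution positions are
#' 1-based on sequence `a` (the anchor coordinate system).
#'
#' @param seq_a,seq_b Sequences rotated to the same anchor; lengths
#'   must agree within 1%.
#' @return A list of class `mito_comparison`: `substitutions` (data
#'   frame `pos`, `base_a`, `base_b`), `indels` (data frame `pos`,
#'   `type`, `length`), `alignment_len`, `n_match`.
#' @export
compare_mitogenomes <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  la <- nchar(seq_a)
  lb <- nchar(seq_b)
  if (abs(la - lb) > 0.01 * max(la, lb))
    stop("sequence lengths differ by more than 1%; not comparable ",
         "as rotated mitogenomes")
  band <- max(100L, 4L * abs(la - lb))
  al <- .nw_banded(seq_a, seq_b, ALN_MATCH, ALN_MISMATCH, ALN_GAP_OPEN,
                   ALN_GAP_EXTEND, band)
  a <- strsplit(al$a_aln, "")[[1]]
  b <- strsplit(al$b_aln, "")[[1]]
  pa <- cumsum(a != "-")
  subs <- which(a != "-" & b != "-" & a != b)
  substitutions <- data.frame(pos = pa[subs], base_a = a[subs],
                              base_b = b[subs], stringsAsFactors = FALSE)
  gap <- a == "-" | b == "-"
  indels <- data.frame(pos = integer(0), type = character(0),
                       length = integer(0), stringsAsFactors = FALSE)
  if (any(gap)) {
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      col <- starts[i]
      type <- if (a[col] == "-") "insertion_in_b" else "deletion_in_b"
      indels <- rbind(indels, data.frame(
        pos = max(pa[col], 1L), type = type, length = r$lengths[i],
        stringsAsFactors = FALSE))
    }
  }
  structure(list(substitutions = substitutions, indels = indels,
                 alignment_len = al$aln_len, n_match = al$n_match),
            class = "mito_comparison")
}

#' @export
print.mito_comparison <- function(x, ...) {
  cat("mito_comparison:", nrow(x$substitutions), "substitution(s),",
      nrow(x$indels), "indel run(s) over", x$alignment_len,
      "alignment columns\n")
  if (nrow(x$substitutions)) {
    lab <- sprintf("%s%d%s", x$substitutions$base_a,
                   x$substitutions$pos, x$substitutions$base_b)
    cat(" ", paste(lab, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Label substitutions with gene intervals
#'
#' Optional annotation step: given a user-supplied gene interval table
#' (columns `gene`, `start`, `end`, anchor coordinates), labels each
#' substitution with the overlapping gene (or NA).
#'
#' @param comparison A `mito_comparison`.
#' @param gene_table Data frame with `gene`, `start`, `end`.
#' @return The substitution data frame with a `gene` column.
#' @export
annotate_mito_substitutions <- function(comparison, gene_table) {
  s <- comparison$substitutions
  s$gene <- NA_character_
  for (i in seq_len(nrow(s))) {
    hit <- which(gene_table$start <= s$pos[i] & gene_table$end >= s$pos[i])
    if (length(hit)) s$gene[i] <- gene_table$gene[hit[1]]
  }
  s
}
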