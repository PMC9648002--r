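# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: alignment goes through Biostrings'
# dynamic-programming engine, clustering through an adjacency-matrix
# closure, and contiguity statistics through a literal sort-and-scan.

suppressPackageStartupMessages(library(Biostrings))

.sub_matrix <- nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                            baseOnly = TRUE)

# drop leading/trailing runs of gap-free columns whose net score is
# zero: a local optimum is only defined up to such zero-net extensions
# (the DP score passes through exactly 0 there), so both routes are
# reduced to the canonical (shortest) co-optimal alignment before
# their statistics are compared
canonical_aln_stats <- function(q_aln, t_aln, score,
                                match = 1, mismatch = -2) {
  q <- strsplit(q_aln, "")[[1]]
  t <- strsplit(t_aln, "")[[1]]
  colscore <- function(qc, tc)
    if (qc == tc && qc != "N") match else mismatch
  trim_zero_net <- function(idx_order) {
    # longest gap-free zero-net run at one end, in scan order
    drop <- 0
    run <- 0
    for (k in seq_along(idx_order)) {
      j <- idx_order[k]
      if (q[j] == "-" || t[j] == "-") break
      run <- run + colscore(q[j], t[j])
      if (run == 0) drop <- k
      if (run < 0) break # a negative run cannot sit in an optimum
    }
    drop
  }
  L <- length(q)
  d_tail <- trim_zero_net(rev(seq_len(L)))
  if (d_tail > 0) {
    q <- q[seq_len(L - d_tail)]
    t <- t[seq_len(L - d_tail)]
    L <- length(q)
  }
  d_head <- trim_zero_net(seq_len(L))
  if (d_head > 0) {
    q <- q[-seq_len(d_head)]
    t <- t[-seq_len(d_head)]
  }
  nm <- sum(q != "-" & t != "-" & q == t & q != "N")
  nx <- sum(q != "-" & t != "-" & (q != t | q == "N"))
  ng <- sum(q == "-" | t == "-")
  list(score = score, n_match = nm, n_mismatch = nx, n_gap = ng,
       aln_len = length(q),
       identity_pct = 100 * nm / length(q))
}

# full Smith-Waterman oracle with the package's scoring scheme,
# reported in canonical form
oracle_local_align <- function(query, target) {
  al <- pairwiseAlignment(DNAString(query), DNAString(target),
                          substitutionMatrix = .sub_matrix,
                          gapOpening = 2.5, gapExtension = 2.5,
                          type = "local")
  canonical_aln_stats(as.character(alignedPattern(al)),
                      as.character(alignedSubject(al)), score(al))
}

# brute-force single-linkage clustering: adjacency matrix + transitive
# closure by repeated boolean multiplication
oracle_single_linkage <- function(records, criteria) {
  n <- nrow(records)
  if (n == 0) return(integer(0))
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      same_chrom <- records$chrom[i] == records$chrom[j]
      same_type <- !criteria$type_aware ||
        harmonize_sv_types(records$sv_type[i]) ==
        harmonize_sv_types(records$sv_type[j])
      close <- abs(records$start[i] - records$start[j]) <=
        criteria$max_breakpoint_dist_bp &&
        abs(records$end[i] - records$end[j]) <=
        criteria$max_breakpoint_dist_bp
      adj[i, j] <- same_chrom && same_type && close
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[adj[i, ]] <- cid
    }
  }
  comp
}

# literal sort-and-cumulative-scan contiguity oracle
oracle_scaffold_stats <- function(lengths, top_k = 50) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(s)
  run <- 0
  l50 <- 0
  for (i in seq_along(s)) {
    run <- run + s[i]
    if (run >= tot / 2) { l50 <- i; break }
  }
  list(total = tot, n50 = s[l50], l50 = l50,
       top = sum(s[seq_len(min(top_k, length(s)))]), largest = s[1])
}

# enumerate all representations of an indel equivalent to (pos, ref,
# alt) on `seq` by replaying the haplotype; returns the mutated
# sequence so normalization can be checked to preserve it
oracle_apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(seq, 1, pos - 1), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate) {
  n <- nchar(s)
  k <- rbinom(1, n, rate)
  if (k == 0) return(s)
  ch <- strsplit(s, "")[[1]]
  for (p in sample.int(n, k))
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

small_study_config <- function(seed = 11) {
  simulation_config(
    seed = seed, scaffold_length = 150000L,
    somatic_snv_profile = c(clean = 12, flanked = 8, destroyed = 4),
    somatic_sv_counts = c(DEL = 3, DUP = 1, INS = 1, INV = 1),
    caller_profiles = list(a = noise_free_profile("a"),
                           b = noise_free_profile("b")))
}
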