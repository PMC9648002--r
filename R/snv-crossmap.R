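#' Build flank queries for SNV cross-assembly mapping
#'
#' For each single-base substitution, extracts the reference-allele and
#' alternate-allele queries: the allele base with `flank` bp of source
#' assembly sequence on each side (default 50, giving 101 bp queries
#' with the allele at center position `flank + 1`). SNVs whose window
#' is truncated by a scaffold edge are excluded and reported via the
#' `excluded` attribute.
#'
#' @param snvs A `small_variant_table` of single-base substitutions.
#' @param genome The source [ScaffoldSet].
#' @param flank Flank length in bp.
#' @return The input rows (minus edge exclusions) with `ref_query`,
#'   `alt_query` and `center_offset` columns; attribute `excluded`
#'   holds the dropped rows.
#' @export
build_snv_queries <- function(snvs, genome, flank = 50L) {
  if (any(nchar(snvs$ref) != 1 | nchar(snvs$alt) != 1))
    stop("flank queries are defined for single-base substitutions only")
  lens <- scaffold_lengths(genome)
  edge <- snvs$pos - flank < 1 | snvs$pos + flank > lens[snvs$chrom]
  if (any(edge))
    message(sum(edge), " SNV(s) excluded: flank window truncated by ",
            "scaffold edge")
  excluded <- snvs[edge, , drop = FALSE]
  out <- snvs[!edge, , drop = FALSE]
  n <- nrow(out)
  rq <- aq <- character(n)
  for (i in seq_len(n)) {
    win <- scaffold_seq(genome, out$chrom[i], out$pos[i] - flank,
                        out$pos[i] + flank)
    if (substr(win, flank + 1, flank + 1) != out$ref[i])
      stop("ref allele mismatch vs genome at ", out$chrom[i], ":",
           out$pos[i])
    rq[i] <- win
    substr(win, flank + 1, flank + 1) <- out$alt[i]
    aq[i] <- win
  }
  out$ref_query <- rq
  out$alt_query <- aq
  out$center_offset <- rep(flank + 1L, n)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

# target-assembly position aligned to a query position, walking the
# aligned strings of `hit`; NA when the position falls in a gap column
# or outside the aligned span. `qpos_oriented` is on the orientation
# the query was aligned in (reverse complement for minus-strand hits).
aligned_target_pos <- function(hit, qpos_oriented, qlen) {
  oq_start <- if (hit$strand == "+") hit$q_start else
    qlen - hit$q_end + 1L
  q <- strsplit(hit$q_aln, "")[[1]]
  t <- strsplit(hit$t_aln, "")[[1]]
  qp <- oq_start - 1L
  tp <- hit$t_start - 1L
  for (i in seq_along(q)) {
    if (q[i] != "-") qp <- qp + 1L
    if (t[i] != "-") tp <- tp + 1L
    if (q[i] != "-" && qp == qpos_oriented)
      return(if (t[i] == "-") NA_integer_ else tp)
  }
  NA_integer_
}

#' Two-step cross-assembly mapping of SNV flank queries
#'
#' Maps both allele queries of each SNV onto the target assembly. Step
#' 1 demands stringent agreement (default: identity >= 99% and
#' alignment length >= 101 columns for both queries' best hits); SNVs
#' failing it are retried in step 2 with lower thresholds (95%, 95).
#' In both steps the two queries' best hits must land on the same
#' scaffold with identical start and end positions on the same strand;
#' the mapped center is the target base aligned to the query center.
#' SNVs failing both steps are unmapped.
#'
#' @param queries Output of [build_snv_queries()].
#' @param index A `SeedIndex` over the target genome.
#' @param target_genome The target [ScaffoldSet].
#' @param step1,step2 [mapping_criteria()] for the two steps.
#' @return `queries` with columns `step` (1, 2 or NA),
#'   `mapped_chrom`, `mapped_pos`, `mapped_strand`,
#'   `flank_mismatch_count`, `flank_gap_count`, `full_span` (logical:
#'   the ref query aligned end-to-end).
#' @export
map_snv_two_step <- function(queries, index, target_genome,
                             step1 = mapping_criteria(99, 101),
                             step2 = mapping_criteria(95, 95)) {
  n <- nrow(queries)
  step <- rep(NA_integer_, n)
  mchrom <- rep(NA_character_, n)
  mpos <- rep(NA_integer_, n)
  mstrand <- rep(NA_character_, n)
  fmm <- rep(NA_integer_, n)
  fgap <- rep(NA_integer_, n)
  full <- rep(NA, n)
  loose <- mapping_criteria(
    min(step1$min_identity_pct, step2$min_identity_pct),
    min(step1$min_alignment_len_bp, step2$min_alignment_len_bp))
  qlen <- nchar(queries$ref_query[1])
  for (i in seq_len(n)) {
    rb <- select_best_hit(local_align_query(queries$ref_query[i], index,
                                            target_genome, loose))
    ab <- select_best_hit(local_align_query(queries$alt_query[i], index,
                                            target_genome, loose))
    if (is.null(rb) || is.null(ab)) next
    same <- rb$scaffold == ab$scaffold && rb$t_start == ab$t_start &&
      rb$t_end == ab$t_end && rb$strand == ab$strand
    if (!same) next
    meets <- function(h, cr) h$identity_pct >= cr$min_identity_pct &&
      h$aln_len >= cr$min_alignment_len_bp
    st <- if (meets(rb, step1) && meets(ab, step1)) 1L
    else if (meets(rb, step2) && meets(ab, step2)) 2L
    else next
    co <- queries$center_offset[i]
    qo <- if (rb$strand == "+") co else qlen - co + 1L
    cp <- aligned_target_pos(rb, qo, qlen)
    if (is.na(cp)) next # center deleted on target: not a mapped SNV
    step[i] <- st
    mchrom[i] <- rb$scaffold
    mpos[i] <- cp
    mstrand[i] <- rb$strand
    # flank accounting from the ref-allele query alignment: the center
    # column is exempted (it carries the somatic allele difference)
    center_mm <- center_column_mismatch(rb, qo, qlen)
    fmm[i] <- rb$n_mismatch - center_mm
    fgap[i] <- rb$n_gap
    full[i] <- rb$q_start == 1L && rb$q_end == qlen
  }
  queries$step <- step
  queries$mapped_chrom <- mchrom
  queries$mapped_pos <- mpos
  queries$mapped_strand <- mstrand
  queries$flank_mismatch_count <- fmm
  queries$flank_gap_count <- fgap
  queries$full_span <- full
  queries
}

center_column_mismatch <- function(hit, qpos_oriented, qlen) {
  oq_start <- if (hit$strand == "+") hit$q_start else
    qlen - hit$q_end + 1L
  q <- strsplit(hit$q_aln, "")[[1]]
  t <- strsplit(hit$t_aln, "")[[1]]
  qp <- oq_start - 1L
  for (i in seq_along(q)) {
    if (q[i] != "-") qp <- qp + 1L
    if (q[i] != "-" && qp == qpos_oriented)
      return(as.integer(t[i] != "-" && q[i] != t[i]))
  }
  0L
}

#' Classify mapped SNVs against the target consensus callset
#'
#' Assigns each SNV exactly one category: `unmapped` (failed both
#' mapping steps), `mapped_no_call` (mapped, but no target consensus
#' SNV with matching alleles at the mapped center), `identical`
#' (matching call, and the flanks align end-to-end with zero non-center
#' mismatches and no gaps), or `equivalent` (matching call with
#' flanking differences - the signature of germline variation between
#' the assemblies). Alleles are complemented before matching when the
#' mapping strand is minus.
#'
#' @param results Output of [map_snv_two_step()].
#' @param target_consensus A `small_variant_table` of consensus SNVs on
#'   the target assembly.
#' @return `results` with a `category` factor column.
#' @export
classify_snv_mapping <- function(results, target_consensus) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  key <- paste(target_consensus$chrom, target_consensus$pos,
               target_consensus$ref, target_consensus$alt)
  n <- nrow(results)
  cat <- character(n)
  for (i in seq_len(n)) {
    if (is.na(results$step[i])) { cat[i] <- "unmapped"; next }
    ref <- results$ref[i]; alt <- results$alt[i]
    if (results$mapped_strand[i] == "-") {
      ref <- comp[[ref]]; alt <- comp[[alt]]
    }
    k <- paste(results$mapped_chrom[i], results$mapped_pos[i], ref, alt)
    if (!(k %in% key)) { cat[i] <- "mapped_no_call"; next }
    clean <- isTRUE(results$full_span[i]) &&
      results$flank_mismatch_count[i] == 0 &&
      results$flank_gap_count[i] == 0
    cat[i] <- if (clean) "identical" else "equivalent"
  }
  results$category <- factor(cat, levels = c("identical", "equivalent",
                                             "mapped_no_call",
                                             "unmapped"))
  results
}

#' Intersect two callers' callsets
#'
#' Returns the records present in both callsets under (chrom,
#' normalized position, ref, alt) equality, after left-aligning and
#' trimming both against the same genome so representation differences
#' cannot break the match. SNVs and indels are intersected separately
#' and returned together with a `variant_class` column.
#'
#' @param callset_a,callset_b `small_variant_table`s from two callers.
#' @param genome The [ScaffoldSet] both callsets were called against.
#' @return The consensus `small_variant_table` (payload columns from
#'   `callset_a`).
#' @export
intersect_caller_callsets <- function(callset_a, callset_b, genome) {
  a <- normalize_small_variant(callset_a, genome)
  b <- normalize_small_variant(callset_b, genome)
  is_snv <- function(x) nchar(x$ref) == 1 & nchar(x$alt) == 1
  out <- list()
  for (cls in c("snv", "indel")) {
    ai <- a[if (cls == "snv") is_snv(a) else !is_snv(a), , drop = FALSE]
    bi <- b[if (cls == "snv") is_snv(b) else !is_snv(b), , drop = FALSE]
    hit <- paste(ai$chrom, ai$pos, ai$ref, ai$alt) %in%
      paste(bi$chrom, bi$pos, bi$ref, bi$alt)
    sub <- ai[hit, , drop = FALSE]
    if (nrow(sub)) sub$variant_class <- cls
    out[[cls]] <- sub
  }
  res <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(res)) {
    res <- empty_small_variants()
    res$variant_class <- character(0)
  }
  rownames(res) <- NULL
  class(res) <- c("small_variant_table", "data.frame")
  res
}

#' Full SNV cross-assembly comparison
#'
#' Convenience pipeline over one `dual_assembly_study`: simulates the
#' two-caller somatic callsets on each assembly with the configured
#' caller profiles, forms per-assembly consensus sets, maps the
#' source-assembly consensus SNVs onto the target assembly and
#' classifies them against the target consensus.
#'
#' @param study A `dual_assembly_study` from [simulate_study()].
#' @param source,target Which assembly plays which role (defaults:
#'   reference as source, personal as target).
#' @param flank Flank length for queries.
#' @param step1,step2 Mapping criteria for the two steps.
#' @param seed Seed for callset simulation noise.
#' @return A list: `results` (classified per-SNV table), `summary` (a
#'   [classification_report()]).
#' @export
crossmap_somatic_snvs <- function(study, source = "reference",
                                  target = "personal", flank = 50L,
                                  step1 = mapping_criteria(99, 101),
                                  step2 = mapping_criteria(95, 95),
                                  seed = study$config$seed + 1000L) {
  set.seed(seed)
  genomes <- list(reference = study$reference, personal = study$personal)
  profiles <- study$config$caller_profiles
  consensus <- list()
  for (asm in c(source, target)) {
    calls <- lapply(profiles, function(p)
      simulate_caller_callset(study$somatic, asm, p,
                              genomes[[asm]])$small)
    cons <- calls[[1]]
    for (j in seq_along(calls)[-1])
      cons <- intersect_caller_callsets(cons, calls[[j]], genomes[[asm]])
    consensus[[asm]] <- cons
  }
  src <- consensus[[source]]
  src <- src[nchar(src$ref) == 1 & nchar(src$alt) == 1, , drop = FALSE]
  queries <- build_snv_queries(src, genomes[[source]], flank = flank)
  idx <- index_genome(genomes[[target]])
  mapped <- map_snv_two_step(queries, idx, genomes[[target]],
                             step1 = step1, step2 = step2)
  results <- classify_snv_mapping(mapped, consensus[[target]])
  counts <- table(results$category)
  list(results = results,
       summary = classification_report(setNames(as.integer(counts),
                                                names(counts))))
}
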