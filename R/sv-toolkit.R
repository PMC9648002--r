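#' SV callset filter profile
#'
#' The ordered pre-filters applied to a raw SV callset: PASS-only,
#' per-caller minimum quality (conventionally 20 for assembly-free
#' k-mer callers such as novoBreak), imprecise/shadowed removal,
#' minimum SV length (50 bp; breakends are exempt), intra-chromosomal
#' breakend removal, and region exclusion.
#'
#' @param min_sv_len_bp Minimum |SVLEN| in bp (default 50).
#' @param drop_intra_chrom_bnd Drop BND records whose mate lies on the
#'   same scaffold.
#' @param min_quality Named per-caller minimum quality (e.g.
#'   `c(novobreak = 20)`); callers not named are not quality-filtered.
#' @param require_pass Keep PASS records only.
#' @param drop_imprecise Drop records flagged IMPRECISE.
#' @param drop_shadowed Drop records with FILTER `SHADOWED`.
#' @param region_rules A [region_rules()] object or NULL.
#' @return A list of class `sv_filter_profile`.
#' @export
sv_filter_profile <- function(min_sv_len_bp = 50L,
                              drop_intra_chrom_bnd = TRUE,
                              min_quality = c(novobreak = 20),
                              require_pass = TRUE,
                              drop_imprecise = TRUE,
                              drop_shadowed = TRUE,
                              region_rules = NULL) {
  stopifnot(min_sv_len_bp >= 1)
  structure(list(min_sv_len_bp = min_sv_len_bp,
                 drop_intra_chrom_bnd = drop_intra_chrom_bnd,
                 min_quality = min_quality, require_pass = require_pass,
                 drop_imprecise = drop_imprecise,
                 drop_shadowed = drop_shadowed,
                 region_rules = region_rules),
            class = "sv_filter_profile")
}

#' Filter an SV callset
#'
#' Applies the profile's filters in a fixed, logged order: PASS,
#' quality, IMPRECISE/SHADOWED, SVLEN, intra-chromosomal BND, region
#' exclusion. TRA/BND records are exempt from the SVLEN filter. The
#' output is always a subset of the input and the operation is
#' idempotent; the per-stage removal counts are attached as the
#' `filter_log` attribute.
#'
#' @param records An `sv_table`.
#' @param profile An [sv_filter_profile()].
#' @return The retained `sv_table`.
#' @export
filter_sv_callset <- function(records, profile) {
  log <- c()
  n0 <- nrow(records)
  if (profile$require_pass)
    records <- records[records$filter == "PASS", , drop = FALSE]
  log["pass"] <- n0 - nrow(records)
  n0 <- nrow(records)
  if (length(profile$min_quality) && "caller" %in% names(records)) {
    for (cl in names(profile$min_quality)) {
      hit <- !is.na(records$caller) & records$caller == cl &
        (is.na(records$qual) | records$qual < profile$min_quality[[cl]])
      records <- records[!hit, , drop = FALSE]
    }
  }
  log["quality"] <- n0 - nrow(records)
  n0 <- nrow(records)
  if (profile$drop_imprecise)
    records <- records[!records$imprecise %in% TRUE, , drop = FALSE]
  if (profile$drop_shadowed)
    records <- records[records$filter != "SHADOWED", , drop = FALSE]
  log["imprecise_shadowed"] <- n0 - nrow(records)
  n0 <- nrow(records)
  bndlike <- records$sv_type %in% c("TRA", "BND")
  short <- !bndlike & !is.na(records$sv_len) &
    records$sv_len < profile$min_sv_len_bp
  records <- records[!short, , drop = FALSE]
  log["svlen"] <- n0 - nrow(records)
  n0 <- nrow(records)
  if (profile$drop_intra_chrom_bnd) {
    intra <- records$sv_type %in% c("TRA", "BND") &
      !is.na(records$mate_chrom) & records$mate_chrom == records$chrom
    records <- records[!intra, , drop = FALSE]
  }
  log["intra_bnd"] <- n0 - nrow(records)
  n0 <- nrow(records)
  if (!is.null(profile$region_rules))
    records <- apply_region_exclusions(records, profile$region_rules)
  log["region"] <- n0 - nrow(records)
  rownames(records) <- NULL
  attr(records, "filter_log") <- log
  records
}

#' Harmonize SV type labels across callers
#'
#' Assembly-to-assembly callers report repeat/tandem contractions and
#' expansions where read-based callers report deletions and
#' insertions of the same event. For comparison, contractions are
#' pooled with DEL and expansions with INS; optionally DUP and INS are
#' pooled as `"DUP/INS"` for reporting. Other types pass through;
#' unknown labels are an error.
#'
#' @param records An `sv_table` (or character vector of type labels).
#' @param pool_dup_ins Pool DUP and INS as `"DUP/INS"`.
#' @return Records with harmonized `sv_type`.
#' @export
harmonize_sv_types <- function(records, pool_dup_ins = FALSE) {
  types <- if (is.character(records)) records else records$sv_type
  unknown <- setdiff(unique(types), sv_types_known)
  if (length(unknown))
    stop("unknown sv_type: ", paste(unknown, collapse = ", "))
  out <- types
  out[types %in% c("repeat_contraction", "tandem_contraction")] <- "DEL"
  out[types %in% c("repeat_expansion", "tandem_expansion")] <- "INS"
  if (pool_dup_ins) out[out %in% c("DUP", "INS")] <- "DUP/INS"
  if (is.character(records)) return(out)
  records$sv_type <- out
  records
}

#' Somatic SV selection criteria for jointly genotyped callsets
#'
#' Two rules identify somatic SVs from a jointly genotyped tumor-normal
#' callset, based on genotypes, alternate allele counts and allele
#' fractions. Rule 1: the normal sample is genotyped reference (0/0)
#' and the tumor 0/1 or 1/1 with at least `min_tumor_alt` alternate
#' reads and tumor allele fraction at least `min_tumor_af`. Rule 2
#' (loss of the reference allele on a germline heterozygous
#' background): normal 0/1, tumor 1/1 with alternate count >= 10,
#' tumor allele fraction >= 0.85, and a tumor-normal allele fraction
#' difference of at least 0.45. The germline-subtraction gate keeps
#' only normal-sample SVs with allele fraction >= 0.1 and alternate
#' count >= 5 as subtraction evidence.
#'
#' @param rule1,rule2,germline_subtract Named lists of thresholds (see
#'   defaults).
#' @return A list of class `somatic_selection_criteria`.
#' @export
somatic_selection_criteria <- function(
    rule1 = list(min_tumor_alt = 5, min_tumor_af = 0.2),
    rule2 = list(min_tumor_alt = 10, min_tumor_af = 0.85,
                 min_af_diff = 0.45),
    germline_subtract = list(min_af = 0.1, min_alt = 5)) {
  structure(list(rule1 = rule1, rule2 = rule2,
                 germline_subtract = germline_subtract),
            class = "somatic_selection_criteria")
}

#' Select somatic SVs from a jointly genotyped callset
#'
#' Retains a record iff rule 1 or rule 2 of the criteria is satisfied
#' (see [somatic_selection_criteria()]). Records lacking a genotype in
#' either sample are dropped with a warning.
#'
#' @param joint_records An `sv_table` with `gt_tumor`/`gt_normal`,
#'   `alt_depth_tumor`, `af_tumor`, `af_normal` columns.
#' @param criteria A [somatic_selection_criteria()].
#' @return The selected subset.
#' @export
select_somatic_sv_joint <- function(joint_records,
                                    criteria =
                                      somatic_selection_criteria()) {
  need <- c("gt_tumor", "gt_normal", "alt_depth_tumor", "af_tumor",
            "af_normal")
  miss <- setdiff(need, names(joint_records))
  if (length(miss))
    stop("joint callset lacks column(s): ", paste(miss, collapse = ", "))
  nogeno <- is.na(joint_records$gt_tumor) |
    is.na(joint_records$gt_normal) |
    joint_records$gt_tumor == "./." | joint_records$gt_normal == "./."
  if (any(nogeno))
    warning(sum(nogeno), " record(s) dropped: missing genotype")
  r <- joint_records[!nogeno, , drop = FALSE]
  r1 <- criteria$rule1
  r2 <- criteria$rule2
  keep1 <- r$gt_normal == "0/0" & r$gt_tumor %in% c("0/1", "1/1") &
    r$alt_depth_tumor >= r1$min_tumor_alt & r$af_tumor >= r1$min_tumor_af
  # tiny epsilon so the inclusive difference boundary survives binary
  # floating point (e.g. 0.85 - 0.40 < 0.45 exactly)
  keep2 <- r$gt_normal == "0/1" & r$gt_tumor == "1/1" &
    r$alt_depth_tumor >= r2$min_tumor_alt &
    r$af_tumor >= r2$min_tumor_af &
    (r$af_tumor - r$af_normal) >= r2$min_af_diff - 1e-9
  out <- r[keep1 | keep2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus merge criteria
#'
#' @param max_breakpoint_dist_bp Maximum distance between corresponding
#'   breakpoints for two records to cluster (default 1000).
#' @param min_support Minimum number of distinct supporting labels for
#'   a consensus record (default 2).
#' @param min_size_bp Minimum SV size taken into account (default 50).
#' @param type_aware Cluster only records of compatible harmonized
#'   type.
#' @return A list of class `merge_criteria`.
#' @export
merge_criteria <- function(max_breakpoint_dist_bp = 1000L,
                           min_support = 2L, min_size_bp = 50L,
                           type_aware = TRUE) {
  stopifnot(max_breakpoint_dist_bp > 0, min_support >= 1,
            min_size_bp > 0)
  structure(list(max_breakpoint_dist_bp = max_breakpoint_dist_bp,
                 min_support = min_support, min_size_bp = min_size_bp,
                 type_aware = type_aware),
            class = "merge_criteria")
}

sv_cluster_compatible <- function(a, b, criteria) {
  if (a$chrom != b$chrom) return(FALSE)
  d <- criteria$max_breakpoint_dist_bp
  if (criteria$type_aware &&
      harmonize_sv_types(a$sv_type) != harmonize_sv_types(b$sv_type))
    return(FALSE)
  if (a$sv_type %in% c("TRA", "BND")) {
    if (is.na(a$mate_chrom) || is.na(b$mate_chrom) ||
        a$mate_chrom != b$mate_chrom) return(FALSE)
    abs(a$start - b$start) <= d && abs(a$mate_pos - b$mate_pos) <= d
  } else {
    abs(a$start - b$start) <= d && abs(a$end - b$end) <= d
  }
}

# single-linkage clustering by pairwise breakpoint compatibility
# (union-find; O(n^2) pair tests, which is ample at desk scale)
sv_single_linkage <- function(records, criteria) {
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        if (find(i) == find(j)) next
        if (sv_cluster_compatible(records[i, ], records[j, ], criteria))
          parent[find(j)] <- find(i)
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Merge labeled SV callsets into consensus records
#'
#' Pools the labeled callsets, drops records below `min_size_bp`
#' (breakends exempt), clusters them by single linkage (two records
#' link when their start and end breakpoints each differ by at most
#' `max_breakpoint_dist_bp`, on the same scaffold, and - when
#' `type_aware` - with compatible harmonized types; breakends link via
#' both endpoint pairs), and keeps clusters supported by at least
#' `min_support` distinct labels. The representative record is the
#' member from the earliest label in `names(callsets)` (ties by
#' position), making the output deterministic.
#'
#' @param callsets A named list of `sv_table`s (names are the caller or
#'   replicate labels).
#' @param criteria A [merge_criteria()].
#' @return A `consensus_sv` data frame: representative coordinates plus
#'   `support` (distinct label count), `supporters`
#'   (comma-separated labels) and `cluster_id`; the full member table
#'   is attached as attribute `members`.
#' @export
merge_sv_callsets <- function(callsets, criteria = merge_criteria()) {
  stopifnot(length(callsets) >= 1, !is.null(names(callsets)))
  pooled <- do.call(rbind, lapply(names(callsets), function(lb) {
    x <- as.data.frame(callsets[[lb]])
    if (nrow(x) == 0) return(NULL)
    x$label <- lb
    x
  }))
  if (is.null(pooled) || nrow(pooled) == 0) return(empty_consensus())
  keep <- pooled$sv_type %in% c("TRA", "BND") | is.na(pooled$sv_len) |
    pooled$sv_len >= criteria$min_size_bp
  pooled <- pooled[keep, , drop = FALSE]
  if (nrow(pooled) == 0) return(empty_consensus())
  pooled <- pooled[order(match(pooled$label, names(callsets)),
                         pooled$chrom, pooled$start), , drop = FALSE]
  rownames(pooled) <- NULL
  cl <- sv_single_linkage(pooled, criteria)
  pooled$cluster_id <- match(cl, unique(cl))
  reps <- list()
  for (cid in sort(unique(pooled$cluster_id))) {
    m <- pooled[pooled$cluster_id == cid, , drop = FALSE]
    labels <- unique(m$label)
    if (length(labels) < criteria$min_support) next
    rep_row <- m[1, , drop = FALSE] # earliest label, smallest position
    rep_row$support <- length(labels)
    rep_row$supporters <- paste(sort(labels), collapse = ",")
    reps[[length(reps) + 1]] <- rep_row
  }
  if (!length(reps)) return(empty_consensus(members = pooled))
  out <- do.call(rbind, reps)
  out$label <- NULL
  rownames(out) <- NULL
  class(out) <- c("consensus_sv", "sv_table", "data.frame")
  attr(out, "members") <- pooled
  out
}

empty_consensus <- function(members = NULL) {
  out <- empty_svs()
  out$caller <- character(0)
  out$cluster_id <- integer(0)
  out$support <- integer(0)
  out$supporters <- character(0)
  class(out) <- c("consensus_sv", "sv_table", "data.frame")
  attr(out, "members") <- members
  out
}

#' Require support across replicates
#'
#' Same clustering as [merge_sv_callsets()], with support counted over
#' replicate callsets of one caller: an SV is retained when called in
#' at least `min_reps` replicates.
#'
#' @param replicate_callsets Named list of `sv_table`s, one per
#'   replicate.
#' @param min_reps Minimum number of supporting replicates (default 2).
#' @param criteria A [merge_criteria()] (its `min_support` is
#'   overridden by `min_reps`).
#' @return A `consensus_sv` data frame.
#' @export
require_replicate_support <- function(replicate_callsets, min_reps = 2L,
                                      criteria = merge_criteria()) {
  criteria$min_support <- min_reps
  merge_sv_callsets(replicate_callsets, criteria)
}

#' Subtract germline SVs from a tumor callset
#'
#' The germline evidence set is first reduced to normal-sample records
#' meeting the allele-fraction/alternate-count gate (defaults 0.1 and
#' 5); a tumor record is then dropped iff a reduced germline record of
#' compatible harmonized type lies within the merge radius (both
#' breakpoints within `max_breakpoint_dist_bp`).
#'
#' @param tumor_svs Tumor `sv_table`.
#' @param normal_svs Normal-sample `sv_table` with `af_normal` (or
#'   `af_tumor` as the single-sample fraction) and matching alt-depth
#'   column.
#' @param criteria A [somatic_selection_criteria()] (its
#'   `germline_subtract` element is used).
#' @param merge_crit A [merge_criteria()] providing the radius.
#' @return The tumor records with no qualifying germline neighbor.
#' @export
subtract_germline_svs <- function(tumor_svs, normal_svs,
                                  criteria = somatic_selection_criteria(),
                                  merge_crit = merge_criteria()) {
  if (is.null(normal_svs) || nrow(normal_svs) == 0) return(tumor_svs)
  gs <- criteria$germline_subtract
  af <- if ("af_normal" %in% names(normal_svs) &&
            !all(is.na(normal_svs$af_normal))) normal_svs$af_normal
  else normal_svs$af_tumor
  alt <- if ("alt_depth_normal" %in% names(normal_svs) &&
             !all(is.na(normal_svs$alt_depth_normal)))
    normal_svs$alt_depth_normal
  else normal_svs$alt_depth_tumor
  evid <- normal_svs[!is.na(af) & af >= gs$min_af &
                       !is.na(alt) & alt >= gs$min_alt, , drop = FALSE]
  if (nrow(evid) == 0) return(tumor_svs)
  drop <- vapply(seq_len(nrow(tumor_svs)), function(i) {
    any(vapply(seq_len(nrow(evid)), function(j)
      sv_cluster_compatible(tumor_svs[i, ], evid[j, ], merge_crit),
      TRUE))
  }, TRUE)
  out <- tumor_svs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build flank queries for SV cross-assembly mapping
#'
#' Extracts `flank` bp (default 100) of source-assembly sequence
#' immediately upstream of the SV start and immediately downstream of
#' the SV end, for DEL/DUP/INS/INV records only (breakend and
#' translocation records are out of mapping scope). For insertions the
#' two flanks abut the insertion point. SVs whose flank windows are
#' truncated by a scaffold edge are excluded with a message.
#'
#' @param svs An `sv_table`.
#' @param genome The source [ScaffoldSet].
#' @param flank Flank length in bp.
#' @return `svs` (minus exclusions) with `up_query` and `down_query`
#'   columns; attribute `excluded` holds the dropped rows.
#' @export
build_sv_flank_queries <- function(svs, genome, flank = 100L) {
  if (any(svs$sv_type %in% c("TRA", "BND")))
    stop("TRA/BND records are excluded from cross-assembly SV mapping")
  lens <- scaffold_lengths(genome)
  edge <- svs$start - flank < 1 | svs$end + flank > lens[svs$chrom]
  if (any(edge))
    message(sum(edge), " SV(s) excluded: flank window truncated by ",
            "scaffold edge")
  out <- svs[!edge, , drop = FALSE]
  n <- nrow(out)
  up <- dn <- character(n)
  for (i in seq_len(n)) {
    up[i] <- scaffold_seq(genome, out$chrom[i], out$start[i] - flank,
                          out$start[i] - 1L)
    dn[i] <- scaffold_seq(genome, out$chrom[i], out$end[i] + 1L,
                          out$end[i] + flank)
  }
  out$up_query <- up
  out$down_query <- dn
  rownames(out) <- NULL
  attr(out, "excluded") <- svs[edge, , drop = FALSE]
  out
}

#' Map SV flank queries onto a target assembly
#'
#' Each SV is "mapped" when both flanks' best hits meet the criteria
#' (default 98% identity, 90 bp alignment), land on one scaffold on
#' the same strand, in consistent order and orientation; the mapped
#' target interval spans between the inner hit ends. Otherwise the SV
#' is "unmapped".
#'
#' @param queries Output of [build_sv_flank_queries()].
#' @param index A `SeedIndex` over the target genome.
#' @param target_genome The target [ScaffoldSet].
#' @param criteria A [mapping_criteria()] (default `(98, 90)`).
#' @param max_span Sanity cap on the mapped interval span in bp
#'   (default 1e6): flanks landing absurdly far apart are unmapped.
#' @return `queries` with `sv_mapped` (logical), `mapped_chrom`,
#'   `mapped_start`, `mapped_end`, `mapped_strand` columns.
#' @export
map_sv_flanks <- function(queries, index, target_genome,
                          criteria = mapping_criteria(98, 90),
                          max_span = 1000000L) {
  n <- nrow(queries)
  mapped <- rep(FALSE, n)
  mchrom <- rep(NA_character_, n)
  mstart <- mend <- rep(NA_integer_, n)
  mstrand <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ub <- select_best_hit(local_align_query(queries$up_query[i], index,
                                            target_genome, criteria))
    db <- select_best_hit(local_align_query(queries$down_query[i], index,
                                            target_genome, criteria))
    if (is.null(ub) || is.null(db)) next
    if (ub$scaffold != db$scaffold || ub$strand != db$strand) next
    if (ub$strand == "+") {
      st <- ub$t_end + 1L
      en <- db$t_start - 1L
    } else { # minus strand: target order is flipped
      st <- db$t_end + 1L
      en <- ub$t_start - 1L
    }
    if (en < st - 1L) next # inconsistent ordering
    if (en - st + 1L > max_span) next
    mapped[i] <- TRUE
    mchrom[i] <- ub$scaffold
    mstart[i] <- st
    mend[i] <- max(en, st)
    mstrand[i] <- ub$strand
  }
  queries$sv_mapped <- mapped
  queries$mapped_chrom <- mchrom
  queries$mapped_start <- mstart
  queries$mapped_end <- mend
  queries$mapped_strand <- mstrand
  queries
}

#' Match mapped SVs against the target assembly's SV callset
#'
#' A mapped SV is `matched` when a target SV of compatible harmonized
#' type has both breakpoints within the merge radius of the mapped
#' interval; otherwise it is `mapped_without_match`. Unmapped records
#' stay `unmapped`, so every SV receives exactly one of the three
#' categories.
#'
#' @param results Output of [map_sv_flanks()].
#' @param target_svs `sv_table` of SVs called on the target assembly.
#' @param criteria A [merge_criteria()] providing radius and type
#'   awareness.
#' @return `results` with a `category` factor column.
#' @export
match_mapped_sv <- function(results, target_svs,
                            criteria = merge_criteria()) {
  n <- nrow(results)
  cat <- rep("unmapped", n)
  for (i in seq_len(n)) {
    if (!results$sv_mapped[i]) next
    probe <- data.frame(chrom = results$mapped_chrom[i],
                        start = results$mapped_start[i],
                        end = results$mapped_end[i],
                        sv_type = results$sv_type[i],
                        mate_chrom = NA, mate_pos = NA,
                        stringsAsFactors = FALSE)
    hit <- FALSE
    if (!is.null(target_svs) && nrow(target_svs)) {
      for (j in seq_len(nrow(target_svs))) {
        if (sv_cluster_compatible(probe, target_svs[j, ], criteria)) {
          hit <- TRUE
          break
        }
      }
    }
    cat[i] <- if (hit) "matched" else "mapped_without_match"
  }
  results$category <- factor(cat, levels = c("matched",
                                             "mapped_without_match",
                                             "unmapped"))
  results
}

#' Flag personal-assembly SVs with no reference-based counterpart
#'
#' Maps each personal-genome consensus SV back onto the reference
#' assembly and matches it against the reference-based SV set; records
#' that are unmapped or mapped without a matching reference SV are
#' flagged `personal_only` - the novel-SV class that motivates using a
#' personal assembly in the first place (e.g. somatic deletions inside
#' repeat copies absent from the reference).
#'
#' @param personal_svs `sv_table` of personal-genome consensus SVs.
#' @param personal_genome,reference_genome The two assemblies.
#' @param reference_svs `sv_table` of reference-based SVs.
#' @param flank,criteria,merge_crit Mapping and matching parameters.
#' @return `personal_svs` with `category` and `personal_only` (logical)
#'   columns.
#' @export
flag_personal_only_svs <- function(personal_svs, personal_genome,
                                   reference_genome, reference_svs,
                                   flank = 100L,
                                   criteria = mapping_criteria(98, 90),
                                   merge_crit = merge_criteria()) {
  queries <- build_sv_flank_queries(personal_svs, personal_genome,
                                    flank = flank)
  idx <- index_genome(reference_genome)
  mapped <- map_sv_flanks(queries, idx, reference_genome,
                          criteria = criteria)
  res <- match_mapped_sv(mapped, reference_svs, criteria = merge_crit)
  res$personal_only <- res$category != "matched"
  res
}
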