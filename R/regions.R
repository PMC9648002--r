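#' Region exclusion rules
#'
#' Variant comparisons are restricted to regions where both assemblies
#' are reliably diploid and placed. Rules come in two forms:
#' whole-scaffold name patterns (regular expressions) and sub-scaffold
#' comparator rules of the form (scaffold, `<` or `>`, coordinate),
#' mirroring the usual "coordinates below/above X" phrasing of such
#' filters. [default_region_rules()] encodes the conventional exclusion
#' set for a human tumor-normal comparison: chrX, chrY,
#' unlocalized/unplaced/decoy scaffolds, chr6p (coordinates below
#' 58,500,000) and chr16q (coordinates above 38,400,000).
#'
#' @param whole_patterns Character vector of scaffold-name regular
#'   expressions excluded entirely.
#' @param partial Data frame with columns `chrom`, `op` (`"<"` or
#'   `">"`), `coord`; a position matches when `pos < coord` (or
#'   `> coord`).
#' @return A list of class `region_rules`.
#' @export
region_rules <- function(whole_patterns = character(0),
                         partial = data.frame(chrom = character(0),
                                              op = character(0),
                                              coord = numeric(0))) {
  stopifnot(all(partial$op %in% c("<", ">")))
  structure(list(whole_patterns = whole_patterns, partial = partial),
            class = "region_rules")
}

#' @rdname region_rules
#' @export
default_region_rules <- function() {
  region_rules(
    whole_patterns = c("^chrX$", "^chrY$", "^chrUn_", "_random", "_decoy"),
    partial = data.frame(chrom = c("chr6", "chr16"), op = c("<", ">"),
                         coord = c(58500000, 38400000),
                         stringsAsFactors = FALSE))
}

position_excluded <- function(rules, chrom, pos) {
  out <- rep(FALSE, length(chrom))
  for (pat in rules$whole_patterns)
    out <- out | grepl(pat, chrom)
  if (nrow(rules$partial)) {
    for (i in seq_len(nrow(rules$partial))) {
      r <- rules$partial[i, ]
      hit <- chrom == r$chrom &
        (if (r$op == "<") pos < r$coord else pos > r$coord)
      out <- out | hit
    }
  }
  out
}

#' Apply region exclusions to a variant table
#'
#' Drops every record for which any rule matches. Small variants are
#' tested at `pos`; SVs at both `start` and `end`; breakend/translocation
#' records additionally at their mate coordinates, so a TRA is dropped
#' when either endpoint falls in an excluded region. Unknown scaffold
#' names pass through unless a name pattern matches them. The operation
#' is idempotent and its output is always a subset of its input.
#'
#' @param records A `small_variant_table` or `sv_table`.
#' @param rules A [region_rules()] object.
#' @return The retained subset of `records`.
#' @export
apply_region_exclusions <- function(records, rules) {
  if (nrow(records) == 0) return(records)
  if ("pos" %in% names(records) && !"start" %in% names(records)) {
    drop <- position_excluded(rules, records$chrom, records$pos)
  } else {
    drop <- position_excluded(rules, records$chrom, records$start) |
      position_excluded(rules, records$chrom, records$end)
    if (all(c("mate_chrom", "mate_pos") %in% names(records))) {
      hasmate <- !is.na(records$mate_chrom) & !is.na(records$mate_pos)
      if (any(hasmate))
        drop[hasmate] <- drop[hasmate] |
          position_excluded(rules, records$mate_chrom[hasmate],
                            records$mate_pos[hasmate])
    }
  }
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export comparator rules as BED intervals
#'
#' Converts the sub-scaffold comparator rules into 0-based half-open BED
#' intervals; whole-scaffold patterns are expanded against the supplied
#' scaffold lengths.
#'
#' @param rules A [region_rules()] object.
#' @param scaffold_lengths Named vector of scaffold lengths in bp.
#' @return A data frame with columns `chrom`, `start`, `end` (BED
#'   convention).
#' @export
region_rules_as_bed <- function(rules, scaffold_lengths) {
  out <- list()
  for (pat in rules$whole_patterns) {
    hit <- grepl(pat, names(scaffold_lengths))
    if (any(hit))
      out[[length(out) + 1]] <- data.frame(
        chrom = names(scaffold_lengths)[hit], start = 0,
        end = unname(scaffold_lengths[hit]), stringsAsFactors = FALSE)
  }
  if (nrow(rules$partial)) {
    for (i in seq_len(nrow(rules$partial))) {
      r <- rules$partial[i, ]
      len <- scaffold_lengths[[r$chrom]]
      if (is.null(len)) next
      if (r$op == "<")
        out[[length(out) + 1]] <- data.frame(chrom = r$chrom, start = 0,
                                             end = r$coord - 1,
                                             stringsAsFactors = FALSE)
      else
        out[[length(out) + 1]] <- data.frame(chrom = r$chrom,
                                             start = r$coord, end = len,
                                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  do.call(rbind, out)
}
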