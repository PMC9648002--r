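#' Build a small-variant table
#'
#' Small variants (SNVs and indels) are kept in plain data frames with a
#' fixed column contract: `chrom`, `pos` (1-based position of the first
#' reference base), `ref`, `alt`, `qual`, `filter`, and optional
#' per-sample genotype columns `gt_<role>`, `alt_depth_<role>`,
#' `af_<role>` for roles `tumor` and `normal`.
#'
#' @param chrom,pos,ref,alt Vectors defining the records; `ref` and `alt`
#'   must be non-empty A/C/G/T/N strings and `pos >= 1`.
#' @param qual,filter Optional quality and filter status (default PASS).
#' @param ... Optional genotype columns (e.g. `gt_tumor`, `af_tumor`).
#' @param genome Optional [ScaffoldSet]; when given, `ref` is checked
#'   against the genome at `pos`.
#' @return A data frame of class `small_variant_table`.
#' @export
small_variant_table <- function(chrom, pos, ref, alt, qual = NA_real_,
                                filter = "PASS", ..., genome = NULL) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   qual = as.numeric(qual),
                   filter = as.character(filter),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_small_variants(df, genome = genome)
  class(df) <- c("small_variant_table", "data.frame")
  df
}

validate_small_variants <- function(df, genome = NULL) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$pos < 1)) stop("pos must be >= 1")
  if (any(!nzchar(df$ref)) || any(!nzchar(df$alt)))
    stop("ref and alt alleles must be non-empty")
  if (any(grepl("[^ACGTN]", df$ref)) || any(grepl("[^ACGTN]", df$alt)))
    stop("alleles restricted to A/C/G/T/N")
  if (!is.null(genome)) {
    lens <- scaffold_lengths(genome)
    unknown <- setdiff(unique(df$chrom), names(lens))
    if (length(unknown))
      stop("variants on scaffolds absent from genome: ",
           paste(unknown, collapse = ", "))
    if (any(df$pos + nchar(df$ref) - 1L > lens[df$chrom]))
      stop("variant extends past scaffold end")
    obs <- vapply(seq_len(nrow(df)), function(i)
      scaffold_seq(genome, df$chrom[i], df$pos[i],
                   df$pos[i] + nchar(df$ref[i]) - 1L), "")
    bad <- obs != df$ref
    if (any(bad))
      stop("ref allele mismatch vs genome at ",
           paste(df$chrom[bad], df$pos[bad], sep = ":", collapse = ", "))
  }
  # genotype consistency: AF within 0.01 of alt/(ref+alt) when both given
  for (role in c("tumor", "normal")) {
    afc <- paste0("af_", role); adc <- paste0("alt_depth_", role)
    rdc <- paste0("ref_depth_", role)
    if (all(c(afc, adc, rdc) %in% names(df))) {
      tot <- df[[adc]] + df[[rdc]]
      ok <- is.na(df[[afc]]) | tot == 0 |
        abs(df[[afc]] - df[[adc]] / tot) <= 0.01
      if (!all(ok))
        stop("allele_fraction inconsistent with depths for sample ", role)
    }
  }
  invisible(df)
}

#' Build a structural-variant table
#'
#' SVs use the column contract `chrom`, `start`, `end` (1-based inclusive
#' breakpoint span), `sv_type` (DEL/DUP/INS/INV/TRA/BND or an assembly
#' caller's repeat/tandem contraction/expansion labels), `sv_len`
#' (absolute length in bp; NA allowed for breakends), `qual`, `filter`,
#' `imprecise`, `mate_chrom`/`mate_pos` (breakend partners), plus
#' optional `caller` and genotype columns as in
#' [small_variant_table()].
#'
#' @param chrom,start,end,sv_type,sv_len Core SV fields.
#' @param qual,filter,imprecise,mate_chrom,mate_pos Optional fields.
#' @param ... Further columns (e.g. `caller`, `gt_tumor`).
#' @return A data frame of class `sv_table`.
#' @export
sv_table <- function(chrom, start, end, sv_type, sv_len = NA_real_,
                     qual = NA_real_, filter = "PASS", imprecise = FALSE,
                     mate_chrom = NA_character_, mate_pos = NA_integer_,
                     ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), sv_type = as.character(sv_type),
                   sv_len = abs(as.numeric(sv_len)),
                   qual = as.numeric(qual), filter = as.character(filter),
                   imprecise = as.logical(imprecise),
                   mate_chrom = as.character(mate_chrom),
                   mate_pos = as.integer(mate_pos),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_svs(df)
  class(df) <- c("sv_table", "data.frame")
  df
}

sv_types_known <- c("DEL", "DUP", "INS", "INV", "TRA", "BND",
                    "repeat_contraction", "repeat_expansion",
                    "tandem_contraction", "tandem_expansion")

validate_svs <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  unknown <- setdiff(unique(df$sv_type), sv_types_known)
  if (length(unknown))
    stop("unknown sv_type: ", paste(unknown, collapse = ", "))
  tra <- df$sv_type %in% c("TRA", "BND")
  if (any(df$end[!tra] < df$start[!tra]))
    stop("end must be >= start for non-breakend SVs")
  if (any(!is.na(df$sv_len) & df$sv_len < 1))
    stop("|sv_len| must be >= 1")
  if (any(tra & (is.na(df$mate_chrom) | is.na(df$mate_pos))))
    stop("TRA/BND records must carry mate coordinates")
  invisible(df)
}
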