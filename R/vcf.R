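#' Describe a caller's VCF dialect
#'
#' Different SV/SNV callers put the modeled quantities under different
#' INFO/FORMAT keys. A dialect names, for one caller, which keys carry
#' the SV type, length, end, imprecision flag, genotype, allele depths
#' and allele fraction, which sample column is the tumor and which the
#' normal, and whether non-PASS records and multi-allelic sites are kept.
#'
#' @param name Caller label stored in the `caller` column.
#' @param pass_only Drop records whose FILTER is not PASS (default TRUE).
#' @param split_multiallelic Split multi-allelic rows into bi-allelic
#'   records on read (default TRUE).
#' @param svtype,svlen,end,chr2,imprecise INFO keys.
#' @param gt,ad,af FORMAT keys; when `af` is `NA` the allele fraction is
#'   derived from the allele depths.
#' @param tumor,normal Sample column names; `NA` means "first sample is
#'   tumor, second (if present) is normal".
#' @return A list of class `vcf_dialect`.
#' @export
vcf_dialect <- function(name = "generic", pass_only = TRUE,
                        split_multiallelic = TRUE,
                        svtype = "SVTYPE", svlen = "SVLEN", end = "END",
                        chr2 = "CHR2", imprecise = "IMPRECISE",
                        gt = "GT", ad = "AD", af = NA_character_,
                        tumor = NA_character_, normal = NA_character_) {
  structure(list(name = name, pass_only = pass_only,
                 split_multiallelic = split_multiallelic,
                 svtype = svtype, svlen = svlen, end = end, chr2 = chr2,
                 imprecise = imprecise, gt = gt, ad = ad, af = af,
                 tumor = tumor, normal = normal),
            class = "vcf_dialect")
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

info_flag <- function(info, key) {
  grepl(paste0("(?:^|;)", key, "(?:;|$|=)"), info)
}

#' Read a VCF into small-variant and SV tables
#'
#' Parses a (plain or bgzipped) VCF via \pkg{vcfR} and maps the fields
#' named by the dialect onto the package's column contracts. Records
#' carrying the dialect's SVTYPE INFO key become [sv_table()] rows; all
#' others become [small_variant_table()] rows. Unknown keys are ignored;
#' a write/read round trip is lossless for the modeled fields.
#'
#' @param path VCF file path.
#' @param dialect A [vcf_dialect()].
#' @return A list with elements `small` (a `small_variant_table`) and
#'   `sv` (an `sv_table`); either may have zero rows.
#' @export
read_vcf <- function(path, dialect = vcf_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(list(small = empty_small_variants(), sv = empty_svs()))
  need <- c("CHROM", "POS", "REF", "ALT")
  if (!all(need %in% names(fix)))
    stop("VCF missing mandatory column(s): ",
         paste(setdiff(need, names(fix)), collapse = ", "))
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) stop("unparseable POS at VCF data row ",
                       which(is.na(pos))[1])
  df <- data.frame(chrom = fix$CHROM, pos = pos, ref = toupper(fix$REF),
                   alt = fix$ALT,
                   qual = suppressWarnings(as.numeric(fix$QUAL)),
                   filter = ifelse(is.na(fix$FILTER) | fix$FILTER == ".",
                                   "PASS", fix$FILTER),
                   info = ifelse(is.na(fix$INFO), "", fix$INFO),
                   stringsAsFactors = FALSE)
  # per-sample FORMAT payload
  samp_names <- colnames(v@gt)
  samp_names <- samp_names[samp_names != "FORMAT"]
  roles <- character(0)
  if (length(samp_names)) {
    tum <- if (!is.na(dialect$tumor)) dialect$tumor else samp_names[1]
    nor <- if (!is.na(dialect$normal)) dialect$normal else
      if (length(samp_names) >= 2) samp_names[2] else NA_character_
    if (tum %in% samp_names) roles[["tumor"]] <- tum
    if (!is.na(nor) && nor %in% samp_names) roles[["normal"]] <- nor
    for (role in names(roles)) {
      sm <- roles[[role]]
      gt <- vcfR::extract.gt(v, element = dialect$gt,
                             return.alleles = FALSE)[, sm]
      df[[paste0("gt_", role)]] <- ifelse(is.na(gt), "./.",
                                          gsub("\\|", "/", gt))
      ad <- vcfR::extract.gt(v, element = dialect$ad)[, sm]
      adm <- strsplit(ifelse(is.na(ad), "", ad), ",")
      df[[paste0("ref_depth_", role)]] <- suppressWarnings(
        as.integer(vapply(adm, function(x)
          if (length(x) >= 1) x[1] else NA_character_, "")))
      df[[paste0("alt_depth_", role)]] <- suppressWarnings(
        as.integer(vapply(adm, function(x)
          if (length(x) >= 2) x[2] else NA_character_, "")))
      if (!is.na(dialect$af)) {
        af <- vcfR::extract.gt(v, element = dialect$af)[, sm]
        df[[paste0("af_", role)]] <- suppressWarnings(as.numeric(af))
      } else {
        tot <- df[[paste0("ref_depth_", role)]] +
          df[[paste0("alt_depth_", role)]]
        df[[paste0("af_", role)]] <-
          ifelse(!is.na(tot) & tot > 0,
                 df[[paste0("alt_depth_", role)]] / tot, NA_real_)
      }
    }
  }
  if (dialect$pass_only) df <- df[df$filter == "PASS", , drop = FALSE]
  if (dialect$split_multiallelic && nrow(df)) {
    alts <- strsplit(df$alt, ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(df)), lengths(alts))
    df <- df[idx, , drop = FALSE]
    df$alt <- unlist(alts)
    rownames(df) <- NULL
  }
  svtype <- info_field(df$info, dialect$svtype)
  is_sv <- !is.na(svtype) | grepl("^<", df$alt) |
    grepl("[][]", df$alt)
  small <- df[!is_sv, , drop = FALSE]
  small$info <- NULL
  small <- small[grepl("^[ACGTN]+$", small$ref) &
                   grepl("^[ACGTN,]+$", toupper(small$alt)), ,
                 drop = FALSE]
  small$alt <- toupper(small$alt)
  rownames(small) <- NULL
  class(small) <- c("small_variant_table", "data.frame")
  sv <- df[is_sv, , drop = FALSE]
  if (nrow(sv)) {
    st <- svtype[is_sv]
    st[is.na(st)] <- sub("^<([A-Za-z_/]+)>$", "\\1", sv$alt[is.na(st)])
    st[grepl("[][]", sv$alt) & (is.na(st) | grepl("[][]", st))] <- "BND"
    sv$sv_type <- st
    svlen <- suppressWarnings(as.numeric(info_field(sv$info, dialect$svlen)))
    endv <- suppressWarnings(as.integer(info_field(sv$info, dialect$end)))
    sv$sv_len <- abs(svlen)
    sv$start <- sv$pos
    sv$end <- ifelse(!is.na(endv), endv,
                     ifelse(sv$sv_type %in% c("INS", "TRA", "BND"), sv$pos,
                            sv$pos + ifelse(is.na(sv$sv_len), 0,
                                            sv$sv_len) - 1L))
    sv$imprecise <- info_flag(sv$info, dialect$imprecise)
    chr2 <- info_field(sv$info, dialect$chr2)
    mate <- parse_bnd_alt(sv$alt)
    sv$mate_chrom <- ifelse(!is.na(chr2), chr2, mate$chrom)
    sv$mate_pos <- ifelse(!is.na(chr2), endv, mate$pos)
    sv$caller <- dialect$name
    keep <- c("chrom", "start", "end", "sv_type", "sv_len", "qual",
              "filter", "imprecise", "mate_chrom", "mate_pos", "caller",
              grep("^(gt|ref_depth|alt_depth|af)_", names(sv), value = TRUE))
    sv <- sv[, keep, drop = FALSE]
    rownames(sv) <- NULL
  } else {
    sv <- empty_svs()
  }
  class(sv) <- c("sv_table", "data.frame")
  list(small = small, sv = sv)
}

parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec("[][]([^][:]+):([0-9]+)[][]", alt,
                               perl = TRUE))
  chrom <- vapply(m, function(x) if (length(x) == 3) x[2] else
    NA_character_, "")
  pos <- suppressWarnings(as.integer(vapply(m, function(x)
    if (length(x) == 3) x[3] else NA_character_, "")))
  list(chrom = chrom, pos = pos)
}

empty_small_variants <- function() {
  structure(data.frame(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       qual = numeric(0), filter = character(0),
                       stringsAsFactors = FALSE),
            class = c("small_variant_table", "data.frame"))
}

empty_svs <- function() {
  structure(data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), sv_type = character(0),
                       sv_len = numeric(0), qual = numeric(0),
                       filter = character(0), imprecise = logical(0),
                       mate_chrom = character(0), mate_pos = integer(0),
                       stringsAsFactors = FALSE),
            class = c("sv_table", "data.frame"))
}

#' Write small-variant and SV tables as VCF 4.2
#'
#' Emits the modeled fields only (SVTYPE/SVLEN/END/IMPRECISE in INFO;
#' GT:AD:AF per sample), as plain uncompressed VCF text so the output is
#' readable by any standard toolchain and by [read_vcf()].
#'
#' @param small A `small_variant_table` or NULL.
#' @param sv An `sv_table` or NULL.
#' @param path Output path.
#' @param contigs Optional named vector of scaffold lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(path, small = NULL, sv = NULL, contigs = NULL) {
  roles <- character(0)
  for (role in c("tumor", "normal")) {
    has <- function(df) !is.null(df) && nrow(df) &&
      paste0("gt_", role) %in% names(df)
    if (has(small) || has(sv)) roles <- c(roles, role)
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=persoma",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
           "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(roles)) cols <- c(cols, "FORMAT", toupper(roles))
  sample_fields <- function(df, i) {
    vapply(roles, function(role) {
      gt <- df[[paste0("gt_", role)]][i]
      rd <- df[[paste0("ref_depth_", role)]]
      ad <- df[[paste0("alt_depth_", role)]]
      af <- df[[paste0("af_", role)]]
      rd <- if (is.null(rd)) NA else rd[i]
      ad <- if (is.null(ad)) NA else ad[i]
      af <- if (is.null(af)) NA else af[i]
      sprintf("%s:%s,%s:%s",
              if (is.null(gt) || is.na(gt)) "./." else gt,
              if (is.na(rd)) "." else rd, if (is.na(ad)) "." else ad,
              if (is.na(af)) "." else format(af, digits = 6))
    }, "")
  }
  lines <- character(0)
  if (!is.null(small) && nrow(small)) {
    for (i in seq_len(nrow(small))) {
      row <- c(small$chrom[i], small$pos[i], ".", small$ref[i],
               small$alt[i],
               if (is.na(small$qual[i])) "." else small$qual[i],
               small$filter[i], ".")
      if (length(roles)) row <- c(row, "GT:AD:AF", sample_fields(small, i))
      lines <- c(lines, paste(row, collapse = "\t"))
    }
  }
  if (!is.null(sv) && nrow(sv)) {
    for (i in seq_len(nrow(sv))) {
      info <- sprintf("SVTYPE=%s;END=%d", sv$sv_type[i],
                      as.integer(sv$end[i]))
      if (!is.na(sv$sv_len[i]))
        info <- paste0(info, ";SVLEN=",
                       if (sv$sv_type[i] %in%
                           c("DEL", "repeat_contraction",
                             "tandem_contraction"))
                         -as.integer(sv$sv_len[i]) else
                           as.integer(sv$sv_len[i]))
      if (isTRUE(sv$imprecise[i])) info <- paste0(info, ";IMPRECISE")
      alt <- if (sv$sv_type[i] %in% c("TRA", "BND") &&
                 !is.na(sv$mate_chrom[i]))
        sprintf("N[%s:%d[", sv$mate_chrom[i], as.integer(sv$mate_pos[i]))
      else paste0("<", sv$sv_type[i], ">")
      row <- c(sv$chrom[i], sv$start[i], ".", "N", alt,
               if (is.na(sv$qual[i])) "." else sv$qual[i],
               sv$filter[i], info)
      if (length(roles)) row <- c(row, "GT:AD:AF", sample_fields(sv, i))
      lines <- c(lines, paste(row, collapse = "\t"))
    }
  }
  writeLines(c(hdr, paste(cols, collapse = "\t"), lines), path)
  invisible(path)
}
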