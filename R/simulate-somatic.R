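#' Plant somatic variants on the personal genome
#'
#' Draws somatic SNV sites and somatic SVs on the personal (normal)
#' genome, assigning each SNV a mutant allele fraction from the
#' configured mixture. When `sites` is supplied (as [simulate_study()]
#' does) those reference-coordinate sites and flanking-context labels
#' are used verbatim; otherwise sites are sampled uniformly away from
#' germline edits. Somatic records carry coordinates on both assemblies
#' via the lift map; records planted inside personal-only insertions
#' have `NA` reference coordinates and are flagged
#' `context = "personal_only"`.
#'
#' @param personal Personal [ScaffoldSet].
#' @param config A [simulation_config()].
#' @param lift Lift map relating the assemblies.
#' @param reference Reference [ScaffoldSet] (for allele lookups).
#' @param germline Germline truth from [derive_personal_genome()].
#' @param sites Optional data frame (`chrom`, `ref_pos`, `context`) of
#'   pre-chosen SNV sites.
#' @param seed Seed; `NULL` continues the current stream.
#' @return A list with data frames `snv` and `sv` (the somatic truth).
#' @export
plant_somatic_variants <- function(personal, config, lift, reference,
                                   germline = NULL, sites = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- paste0("chr", seq_len(config$n_scaffolds))
  if (is.null(sites)) {
    avoid <- somatic_avoid_intervals(germline)
    sites <- list()
    for (ctx in names(config$somatic_snv_profile)) {
      k <- config$somatic_snv_profile[[ctx]]
      if (k == 0) next
      per_chr <- table(factor(rep_len(chroms, k), levels = chroms))
      for (chrom in chroms) {
        if (per_chr[[chrom]] == 0) next
        av <- avoid[avoid$chrom == chrom, c("start", "end"),
                    drop = FALSE]
        p <- sample_positions(per_chr[[chrom]], 200,
                              scaffold_lengths(reference)[[chrom]] - 200,
                              min_sep = 150, avoid = av)
        sites[[length(sites) + 1]] <- data.frame(
          chrom = chrom, ref_pos = p, context = ctx,
          stringsAsFactors = FALSE)
      }
    }
    sites <- do.call(rbind, sites)
  }
  n <- nrow(sites)
  maf <- sample(config$somatic_maf_values, n, replace = TRUE,
                prob = config$somatic_maf_weights)
  per_pos <- lift_position(lift, sites$chrom, sites$ref_pos)
  ref_base <- vapply(seq_len(n), function(i)
    if (is.na(per_pos[i])) NA_character_ else
      scaffold_seq(personal, sites$chrom[i], per_pos[i], per_pos[i]), "")
  snv <- data.frame(chrom = sites$chrom, ref_pos = sites$ref_pos,
                    per_pos = per_pos, ref = ref_base,
                    alt = other_base(ref_base), maf = maf,
                    context = sites$context, stringsAsFactors = FALSE)
  # somatic SVs away from everything already planted
  avoid <- rbind(somatic_avoid_intervals(germline),
                 data.frame(chrom = snv$chrom, start = snv$ref_pos - 200,
                            end = snv$ref_pos + 200))
  sv_rows <- list()
  counts <- config$somatic_sv_counts
  j <- 0
  for (tp in names(counts)) {
    for (k in seq_len(counts[[tp]])) {
      j <- j + 1
      chrom <- chroms[1 + (j - 1) %% length(chroms)]
      av <- avoid[avoid$chrom == chrom, c("start", "end"), drop = FALSE]
      len <- sample(60:1000, 1)
      p <- sample_positions(1, 5000,
                            scaffold_lengths(reference)[[chrom]] - 5000,
                            min_sep = 1, avoid = av)
      ref_start <- p
      ref_end <- if (tp == "INS") p else p + len - 1L
      sv_rows[[length(sv_rows) + 1]] <- data.frame(
        chrom = chrom, ref_start = ref_start, ref_end = ref_end,
        per_start = lift_position(lift, chrom, ref_start),
        per_end = lift_position(lift, chrom, ref_end),
        sv_type = tp, sv_len = len,
        maf = sample(config$somatic_maf_values, 1,
                     prob = config$somatic_maf_weights),
        context = "shared", stringsAsFactors = FALSE)
      avoid <- rbind(avoid, data.frame(chrom = chrom,
                                       start = ref_start - 2500,
                                       end = ref_end + 2500))
    }
  }
  # somatic DELs inside personal-only insertions: callable/mappable only
  # against the personal genome (no reference coordinates exist)
  if (config$somatic_sv_personal_only > 0 && !is.null(germline) &&
      nrow(germline$sv)) {
    cand <- germline$sv[germline$sv$personal_only &
                          germline$sv$sv_len >= 150, , drop = FALSE]
    k <- min(config$somatic_sv_personal_only, nrow(cand))
    if (k < config$somatic_sv_personal_only)
      warning("only ", k, " personal-only insertions available to host ",
              "somatic deletions")
    for (i in seq_len(k)) {
      host <- cand[i, ]
      # delete an interior slice of the inserted copy
      margin <- 25L
      avail <- host$per_end - host$per_start + 1L - 2L * margin
      len <- min(100L, avail)
      st <- host$per_start + margin
      sv_rows[[length(sv_rows) + 1]] <- data.frame(
        chrom = host$chrom, ref_start = NA_integer_,
        ref_end = NA_integer_, per_start = st,
        per_end = st + len - 1L, sv_type = "DEL", sv_len = len,
        maf = 1.0, context = "personal_only", stringsAsFactors = FALSE)
    }
  }
  sv <- if (length(sv_rows)) do.call(rbind, sv_rows) else
    data.frame(chrom = character(0), ref_start = integer(0),
               ref_end = integer(0), per_start = integer(0),
               per_end = integer(0), sv_type = character(0),
               sv_len = integer(0), maf = numeric(0),
               context = character(0), stringsAsFactors = FALSE)
  list(snv = snv, sv = sv)
}

somatic_avoid_intervals <- function(germline) {
  out <- data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0))
  if (is.null(germline)) return(out)
  if (nrow(germline$small))
    out <- rbind(out, data.frame(chrom = germline$small$chrom,
                                 start = germline$small$pos - 120,
                                 end = germline$small$pos + 120))
  if (nrow(germline$sv))
    out <- rbind(out, data.frame(chrom = germline$sv$chrom,
                                 start = germline$sv$ref_start - 2500,
                                 end = germline$sv$ref_end + 2500))
  out
}

#' Simulate a complete dual-assembly study
#'
#' The top-level generator: builds the reference genome, chooses somatic
#' SNV sites together with their engineered flanking contexts, samples a
#' germline edit script honouring those contexts (clean flanks kept free
#' of germline edits; `flanked` sites given 1-3 germline flank SNVs;
#' `destroyed` sites given unrelated flanking sequence in the personal
#' genome), derives the personal genome and lift map, and plants somatic
#' SNV/SV truth on both coordinate systems.
#'
#' @param config A [simulation_config()].
#' @return A list of class `dual_assembly_study`: `reference`,
#'   `personal`, `lift`, `edits`, `germline`, `somatic`, `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  set.seed(config$seed)
  reference <- generate_reference_genome(config, seed = NULL)
  chroms <- paste0("chr", seq_len(config$n_scaffolds))
  # 1. somatic SNV sites and contexts, spread over scaffolds; sites
  # keep clear of planted repeat copies so every flank query maps to a
  # unique locus (paralogous copies would otherwise capture best hits)
  sites <- list()
  pl <- attr(reference, "repeat_placements")
  taken <- if (!is.null(pl) && nrow(pl))
    data.frame(chrom = pl$scaffold, start = pl$start - 120,
               end = pl$end + 120)
  else data.frame(chrom = character(0), start = numeric(0),
                  end = numeric(0))
  for (ctx in names(config$somatic_snv_profile)) {
    k <- config$somatic_snv_profile[[ctx]]
    if (k == 0) next
    per_chr <- table(factor(rep_len(chroms, k), levels = chroms))
    for (chrom in chroms) {
      if (per_chr[[chrom]] == 0) next
      av <- taken[taken$chrom == chrom, c("start", "end"), drop = FALSE]
      p <- sample_positions(per_chr[[chrom]], 500,
                            config$scaffold_length - 500,
                            min_sep = 250, avoid = av)
      sites[[length(sites) + 1]] <- data.frame(chrom = chrom,
                                               ref_pos = p, context = ctx,
                                               stringsAsFactors = FALSE)
      taken <- rbind(taken, data.frame(chrom = chrom, start = p - 250,
                                       end = p + 250))
    }
  }
  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL
  # 2. engineered flank edits + background germline kept off all flanks
  flank_edits <- list()
  for (i in which(sites$context == "flanked")) {
    n_mm <- sample(1:3, 1)
    # offsets within the 50 bp flanks but >= 5 bp from the center and
    # >= 5 bp from the query edges, so local alignment never trims them
    off <- sample(c(-(45:5), 5:45), n_mm)
    for (o in off) {
      p <- sites$ref_pos[i] + o
      b <- scaffold_seq(reference, sites$chrom[i], p, p)
      flank_edits[[length(flank_edits) + 1]] <-
        edit_script_row(sites$chrom[i], p, "sub", 1, other_base(b),
                        id = paste0("flank_snv_site", i))
    }
  }
  for (i in which(sites$context == "destroyed")) {
    for (side in c(-1, 1)) {
      st <- if (side < 0) sites$ref_pos[i] - 50L else sites$ref_pos[i] + 1L
      flank_edits[[length(flank_edits) + 1]] <-
        edit_script_row(sites$chrom[i], st, "sub", 50,
                        random_seq(50, config$gc),
                        id = paste0("flank_rewrite_site", i))
    }
  }
  flank_edits <- if (length(flank_edits)) do.call(rbind, flank_edits)
  else NULL
  # background germline must stay clear of every somatic flank window
  avoid <- data.frame(chrom = sites$chrom, start = sites$ref_pos - 60,
                      end = sites$ref_pos + 60)
  bg <- sample_germline_edits(reference, config, chroms, avoid = avoid)
  edits <- sort_edits(rbind(bg, flank_edits))
  pg <- derive_personal_genome(reference, config, edits = edits)
  somatic <- plant_somatic_variants(pg$genome, config, pg$lift, reference,
                                    germline = pg$germline, sites = sites)
  structure(list(reference = reference, personal = pg$genome,
                 lift = pg$lift, edits = pg$edits,
                 germline = pg$germline, somatic = somatic,
                 config = config),
            class = "dual_assembly_study")
}

#' @export
print.dual_assembly_study <- function(x, ...) {
  cat("dual_assembly_study (seed", x$config$seed, ")\n")
  cat("  reference:", length(x$reference), "scaffolds,",
      format(sum(scaffold_lengths(x$reference)), big.mark = ","), "bp\n")
  cat("  personal: ", length(x$personal), "scaffolds,",
      format(sum(scaffold_lengths(x$personal)), big.mark = ","), "bp\n")
  cat("  germline truth:", nrow(x$germline$small), "small,",
      nrow(x$germline$sv), "SV\n")
  cat("  somatic truth: ", nrow(x$somatic$snv), "SNV,",
      nrow(x$somatic$sv), "SV\n")
  invisible(x)
}

#' Simulate one caller's somatic callset against a chosen assembly
#'
#' Projects the somatic truth onto the target assembly's coordinates
#' (records private to the other assembly are dropped by construction),
#' then applies the caller profile: each truth record is dropped with
#' probability `fn_rate`, `Poisson(fp_rate * n)` false positive records
#' are added at random positions, SV breakpoints are jittered with the
#' configured standard deviation, and caller-specific quality scores are
#' stamped. With a noise-free profile the callset equals the truth.
#'
#' @param somatic Somatic truth list (`snv`, `sv`) from a study.
#' @param target `"reference"` or `"personal"`.
#' @param profile A [caller_profile()].
#' @param genome The target assembly (for false-positive alleles).
#' @param seed Seed; `NULL` continues the current stream.
#' @return A list with `small` (a `small_variant_table`) and `sv` (an
#'   `sv_table`), both carrying tumor/normal genotype columns.
#' @export
simulate_caller_callset <- function(somatic, target = c("reference",
                                                        "personal"),
                                    profile, genome, seed = NULL) {
  target <- match.arg(target)
  if (!is.null(seed)) set.seed(seed)
  poscol <- if (target == "reference") "ref_pos" else "per_pos"
  stcol <- if (target == "reference") "ref_start" else "per_start"
  encol <- if (target == "reference") "ref_end" else "per_end"
  depth <- 50L
  snv <- somatic$snv[!is.na(somatic$snv[[poscol]]), , drop = FALSE]
  keep <- runif(nrow(snv)) >= profile$fn_rate
  snv <- snv[keep, , drop = FALSE]
  n_fp <- if (profile$fp_rate > 0) rpois(1, profile$fp_rate * nrow(snv))
  else 0L
  small <- genotyped_small(snv$chrom, snv[[poscol]], snv$ref, snv$alt,
                           snv$maf, depth, profile)
  if (n_fp > 0) {
    lens <- scaffold_lengths(genome)
    lens <- lens[grep("^chr[0-9]+$", names(lens))]
    chrom <- sample(names(lens), n_fp, replace = TRUE)
    pos <- vapply(chrom, function(ch) sample(seq(100, lens[[ch]] - 100), 1),
                  1L)
    refb <- vapply(seq_len(n_fp), function(i)
      scaffold_seq(genome, chrom[i], pos[i], pos[i]), "")
    fp <- genotyped_small(chrom, pos, refb, other_base(refb),
                          runif(n_fp, 0.2, 0.6), depth, profile)
    small <- rbind(small, fp)
  }
  sv <- somatic$sv[!is.na(somatic$sv[[stcol]]), , drop = FALSE]
  keep <- runif(nrow(sv)) >= profile$fn_rate
  sv <- sv[keep, , drop = FALSE]
  jit <- function(n) if (profile$jitter_sd > 0)
    as.integer(round(stats::rnorm(n, 0, profile$jitter_sd))) else
      rep(0L, n)
  st <- sv[[stcol]] + jit(nrow(sv))
  en <- sv[[encol]] + jit(nrow(sv))
  en <- pmax(en, st) # jitter must not invert the span
  svt <- if (nrow(sv)) sv_table(
    chrom = sv$chrom, start = st, end = en, sv_type = sv$sv_type,
    sv_len = sv$sv_len,
    qual = round(stats::rnorm(nrow(sv), profile$qual_mean,
                              profile$qual_sd), 1),
    caller = profile$name,
    gt_tumor = ifelse(sv$maf >= 0.75, "1/1", "0/1"),
    alt_depth_tumor = as.integer(round(depth * sv$maf)),
    ref_depth_tumor = as.integer(depth - round(depth * sv$maf)),
    af_tumor = round(depth * sv$maf) / depth,
    gt_normal = "0/0", alt_depth_normal = 0L,
    ref_depth_normal = depth, af_normal = 0) else empty_svs()
  list(small = small, sv = svt)
}

genotyped_small <- function(chrom, pos, ref, alt, maf, depth, profile) {
  if (!length(chrom)) return(empty_small_variants())
  ad <- as.integer(round(depth * maf))
  small_variant_table(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    qual = round(stats::rnorm(length(chrom), profile$qual_mean,
                              profile$qual_sd), 1),
    gt_tumor = ifelse(maf >= 0.75, "1/1", "0/1"),
    alt_depth_tumor = ad, ref_depth_tumor = depth - ad,
    af_tumor = ad / depth,
    gt_normal = "0/0", alt_depth_normal = 0L, ref_depth_normal = depth,
    af_normal = 0)
}

#' Simulate a jointly genotyped tumor+normal SV callset
#'
#' Emulates joint tumor-normal SV calling: germline SVs are genotyped in
#' both samples (heterozygous or homozygous), somatic SVs are genotyped
#' `0/0` in the normal sample and according to their mutant allele
#' fraction in the tumor. Allele depths are derived from the allele
#' fractions at the configured depth, so the depth/fraction consistency
#' invariant holds exactly; a noisy profile jitters breakpoints and
#' drops/adds records as in [simulate_caller_callset()].
#'
#' @param germline_sv,somatic_sv Truth data frames (personal-genome
#'   coordinates are used when available, falling back to reference).
#' @param profile A [caller_profile()].
#' @param target Coordinate system to emit.
#' @param depth Simulated depth.
#' @param seed Seed; `NULL` continues the current stream.
#' @return An `sv_table` with tumor and normal genotype columns and a
#'   `germline_truth` logical column (for scoring only).
#' @export
simulate_joint_genotyped_sv_vcf <- function(germline_sv, somatic_sv,
                                            profile = noise_free_profile(),
                                            target = c("personal",
                                                       "reference"),
                                            depth = 50L, seed = NULL) {
  target <- match.arg(target)
  if (!is.null(seed)) set.seed(seed)
  stcol <- if (target == "reference") "ref_start" else "per_start"
  encol <- if (target == "reference") "ref_end" else "per_end"
  rows <- list()
  gdepth <- function(af) as.integer(round(depth * af))
  if (!is.null(germline_sv) && nrow(germline_sv)) {
    g <- germline_sv[!is.na(germline_sv[[stcol]]), , drop = FALSE]
    zyg <- if ("zygosity" %in% names(g)) g$zygosity else
      sample(c("het", "hom"), nrow(g), replace = TRUE,
             prob = c(0.7, 0.3))
    af <- ifelse(zyg == "het", 0.5, 1.0)
    st <- g[[stcol]]
    en <- pmax(g[[encol]], st)
    rows[[1]] <- sv_table(
      chrom = g$chrom, start = st, end = en, sv_type = g$sv_type,
      sv_len = g$sv_len,
      qual = round(stats::rnorm(nrow(g), profile$qual_mean,
                                profile$qual_sd), 1),
      caller = profile$name,
      gt_tumor = ifelse(zyg == "het", "0/1", "1/1"),
      alt_depth_tumor = gdepth(af), ref_depth_tumor = depth - gdepth(af),
      af_tumor = gdepth(af) / depth,
      gt_normal = ifelse(zyg == "het", "0/1", "1/1"),
      alt_depth_normal = gdepth(af),
      ref_depth_normal = depth - gdepth(af),
      af_normal = gdepth(af) / depth,
      germline_truth = TRUE)
  }
  if (!is.null(somatic_sv) && nrow(somatic_sv)) {
    s <- somatic_sv[!is.na(somatic_sv[[stcol]]), , drop = FALSE]
    af <- s$maf
    st <- s[[stcol]]
    en <- pmax(s[[encol]], st)
    rows[[2]] <- sv_table(
      chrom = s$chrom, start = st, end = en, sv_type = s$sv_type,
      sv_len = s$sv_len,
      qual = round(stats::rnorm(nrow(s), profile$qual_mean,
                                profile$qual_sd), 1),
      caller = profile$name,
      gt_tumor = ifelse(af >= 0.75, "1/1", "0/1"),
      alt_depth_tumor = gdepth(af), ref_depth_tumor = depth - gdepth(af),
      af_tumor = gdepth(af) / depth,
      gt_normal = "0/0", alt_depth_normal = 0L, ref_depth_normal = depth,
      af_normal = 0, germline_truth = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) return(empty_svs())
  if (profile$jitter_sd > 0) {
    out$start <- out$start +
      as.integer(round(stats::rnorm(nrow(out), 0, profile$jitter_sd)))
    out$end <- pmax(out$end + as.integer(
      round(stats::rnorm(nrow(out), 0, profile$jitter_sd))), out$start)
  }
  if (profile$fn_rate > 0)
    out <- out[runif(nrow(out)) >= profile$fn_rate, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sv_table", "data.frame")
  out
}

#' Write the planted truth as a tab-separated table
#'
#' Columns: `class` (germline/somatic), `kind` (snv/indel/sv), `chrom`,
#' reference and personal coordinates, alleles or SV type/length, `maf`
#' and flanking `context` for somatic records.
#'
#' @param study A `dual_assembly_study`.
#' @param path Output path.
#' @export
write_truth_table <- function(study, path) {
  g <- study$germline
  s <- study$somatic
  rows <- list()
  if (nrow(g$small))
    rows[[1]] <- data.frame(class = "germline", kind = g$small$kind,
                            chrom = g$small$chrom,
                            ref_start = g$small$pos, ref_end = g$small$pos,
                            per_start = g$small$per_pos,
                            per_end = g$small$per_pos,
                            ref = g$small$ref, alt = g$small$alt,
                            sv_type = NA, sv_len = NA, maf = NA,
                            context = NA, stringsAsFactors = FALSE)
  if (nrow(g$sv))
    rows[[2]] <- data.frame(class = "germline", kind = "sv",
                            chrom = g$sv$chrom, ref_start = g$sv$ref_start,
                            ref_end = g$sv$ref_end,
                            per_start = g$sv$per_start,
                            per_end = g$sv$per_end, ref = NA, alt = NA,
                            sv_type = g$sv$sv_type, sv_len = g$sv$sv_len,
                            maf = NA, context = NA,
                            stringsAsFactors = FALSE)
  if (nrow(s$snv))
    rows[[3]] <- data.frame(class = "somatic", kind = "snv",
                            chrom = s$snv$chrom,
                            ref_start = s$snv$ref_pos,
                            ref_end = s$snv$ref_pos,
                            per_start = s$snv$per_pos,
                            per_end = s$snv$per_pos, ref = s$snv$ref,
                            alt = s$snv$alt, sv_type = NA, sv_len = NA,
                            maf = s$snv$maf, context = s$snv$context,
                            stringsAsFactors = FALSE)
  if (nrow(s$sv))
    rows[[4]] <- data.frame(class = "somatic", kind = "sv",
                            chrom = s$sv$chrom, ref_start = s$sv$ref_start,
                            ref_end = s$sv$ref_end,
                            per_start = s$sv$per_start,
                            per_end = s$sv$per_end, ref = NA, alt = NA,
                            sv_type = s$sv$sv_type, sv_len = s$sv$sv_len,
                            maf = s$sv$maf, context = s$sv$context,
                            stringsAsFactors = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
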