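#' Simulation configuration
#'
#' Defines the study conditions for the dual-assembly simulator: a
#' random background genome carrying planted repeat elements, a personal
#' genome derived from it by germline variation (SNVs, indels, repeat
#' insertions/deletions, tandem expansions, homopolymer-length changes),
#' tumor somatic variants with allele fractions, and per-caller error
#' profiles. All downstream randomness flows from `seed` through one
#' documented stream, so a fixed configuration reproduces byte-identical
#' genomes and callsets.
#'
#' @param seed Integer master seed.
#' @param n_scaffolds,scaffold_length Autosome-like scaffolds and their
#'   length in bp (default 2 x 1 Mb).
#' @param include_chrM Add a 16,569 bp circular chrM scaffold.
#' @param gc Background GC fraction.
#' @param germline_snv_rate,germline_indel_rate Per-bp germline rates.
#' @param germline_sv_counts Named counts of germline SVs by kind:
#'   `alu_ins` (personal-only Alu-like insertions), `del`,
#'   `tandem_expansion`, `homopolymer_expansion`.
#' @param repeat_library Named list of repeat motif specs
#'   (`list(length=, copies=)`); copies are planted in the reference
#'   with 0.5-2% per-copy divergence.
#' @param somatic_snv_profile Named counts of somatic SNVs by flanking
#'   context: `clean` (flanks identical between assemblies), `flanked`
#'   (1-3 germline SNVs within the 50 bp flanks), `destroyed` (flanks
#'   replaced by unrelated sequence in the personal genome).
#' @param somatic_maf_values,somatic_maf_weights Mixture describing the
#'   somatic mutant allele fraction (default 0.5 clonal heterozygous /
#'   1.0 homozygous-LOH with weights 0.8/0.2).
#' @param somatic_sv_counts Named counts of somatic SVs by type.
#' @param somatic_sv_personal_only Number of somatic DELs planted inside
#'   personal-only repeat insertions (detectable only against the
#'   personal genome).
#' @param caller_profiles Named list of [caller_profile()]s.
#' @param read_depth Simulated sample depth used to derive allele
#'   depths from allele fractions.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 20394L,
                              n_scaffolds = 2L,
                              scaffold_length = 1000000L,
                              include_chrM = TRUE,
                              gc = 0.41,
                              germline_snv_rate = 1e-3,
                              germline_indel_rate = 1e-4,
                              germline_sv_counts = c(alu_ins = 4,
                                                     del = 3,
                                                     tandem_expansion = 2,
                                                     homopolymer_expansion = 1),
                              repeat_library = list(
                                alu_like = list(length = 300L, copies = 6L),
                                ltr_like = list(length = 500L, copies = 3L),
                                sva_like = list(length = 1600L, copies = 2L),
                                simple_at = list(length = 60L, copies = 4L)),
                              somatic_snv_profile = c(clean = 300,
                                                      flanked = 150,
                                                      destroyed = 50),
                              somatic_maf_values = c(0.5, 1.0),
                              somatic_maf_weights = c(0.8, 0.2),
                              somatic_sv_counts = c(DEL = 10, DUP = 4,
                                                    INS = 4, INV = 2),
                              somatic_sv_personal_only = 1L,
                              caller_profiles = list(
                                caller_a = caller_profile("caller_a"),
                                caller_b = caller_profile("caller_b")),
                              read_depth = 50L) {
  stopifnot(germline_snv_rate >= 0, germline_snv_rate <= 1,
            germline_indel_rate >= 0, germline_indel_rate <= 1,
            all(germline_sv_counts >= 0), all(somatic_snv_profile >= 0),
            all(somatic_sv_counts >= 0),
            abs(sum(somatic_maf_weights) - 1) < 1e-9,
            all(somatic_maf_values > 0 & somatic_maf_values <= 1))
  structure(as.list(environment()), class = "simulation_config")
}

#' Caller error profile
#'
#' @param name Caller label.
#' @param fn_rate Per-record false-negative (drop) probability.
#' @param fp_rate False positives as a fraction of the truth count
#'   (Poisson mean = `fp_rate * n_truth`).
#' @param jitter_sd Breakpoint jitter standard deviation in bp (SVs
#'   only; well below the 1000 bp consensus merge radius).
#' @param qual_mean,qual_sd Emitted quality score distribution.
#' @return A list of class `caller_profile`.
#' @export
caller_profile <- function(name, fn_rate = 0.05, fp_rate = 0.02,
                           jitter_sd = 30, qual_mean = 60, qual_sd = 10) {
  stopifnot(fn_rate >= 0, fn_rate <= 1, fp_rate >= 0, jitter_sd >= 0)
  structure(list(name = name, fn_rate = fn_rate, fp_rate = fp_rate,
                 jitter_sd = jitter_sd, qual_mean = qual_mean,
                 qual_sd = qual_sd),
            class = "caller_profile")
}

#' @rdname caller_profile
#' @export
noise_free_profile <- function(name = "noise_free")
  caller_profile(name, fn_rate = 0, fp_rate = 0, jitter_sd = 0)

random_seq <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

diverge_seq <- function(s, rate) {
  n <- nchar(s)
  k <- rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

other_base <- function(b) vapply(b, function(x)
  sample(setdiff(c("A", "C", "G", "T"), x), 1), "", USE.NAMES = FALSE)

# sample `n` positions in [lo, hi] pairwise >= min_sep apart and outside
# `avoid` (data.frame start/end); rejection sampling with a hard cap.
sample_positions <- function(n, lo, hi, min_sep, avoid = NULL) {
  out <- integer(0)
  tries <- 0
  while (length(out) < n) {
    tries <- tries + 1
    if (tries > 1000 * max(n, 10))
      stop("could not place ", n, " positions in [", lo, ", ", hi, "]")
    p <- sample(seq.int(lo, hi), 1)
    if (length(out) && min(abs(out - p)) < min_sep) next
    if (!is.null(avoid) && nrow(avoid) &&
        any(p >= avoid$start & p <= avoid$end)) next
    out <- c(out, p)
  }
  sort(out)
}

#' Generate the reference genome
#'
#' Builds `n_scaffolds` i.i.d. background scaffolds (named `chr1`,
#' `chr2`, ...) with the configured GC, plants every repeat-library copy
#' at recorded non-overlapping positions with 0.5-2% per-copy
#' divergence, and appends a circular `chrM` scaffold. Deterministic
#' given the seed.
#'
#' @param config A [simulation_config()].
#' @param seed Seed; `NULL` continues the current RNG stream (used by
#'   [simulate_study()]).
#' @return A [ScaffoldSet] with attributes `repeat_placements` (data
#'   frame: scaffold, start, end, motif, copy) and `motifs` (the master
#'   motif sequences).
#' @export
generate_reference_genome <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n_rep <- sum(vapply(config$repeat_library, function(x)
    as.integer(x$copies), 1L))
  max_rep <- if (length(config$repeat_library))
    max(vapply(config$repeat_library, function(x) as.integer(x$length),
               1L)) else 0L
  if (config$scaffold_length < 10000 + n_rep * (max_rep + 2000))
    stop("scaffold_length too small to host the configured repeats")
  motifs <- list()
  for (nm in names(config$repeat_library)) {
    spec <- config$repeat_library[[nm]]
    motifs[[nm]] <- if (nm == "simple_at")
      substr(strrep("AT", ceiling(spec$length / 2)), 1, spec$length)
    else random_seq(spec$length, config$gc)
  }
  seqs <- character(0)
  placements <- list()
  for (i in seq_len(config$n_scaffolds)) {
    chrom <- paste0("chr", i)
    s <- random_seq(config$scaffold_length, config$gc)
    # spread copies across scaffolds round-robin
    for (nm in names(config$repeat_library)) {
      spec <- config$repeat_library[[nm]]
      copies_here <- sum(seq_len(spec$copies) %% config$n_scaffolds ==
                           i %% config$n_scaffolds)
      if (copies_here == 0) next
      have <- do.call(rbind, placements[vapply(placements, function(p)
        p$scaffold[1] == chrom, TRUE)])
      avoid <- if (!is.null(have))
        data.frame(start = have$start - 2000, end = have$end + 2000)
      else NULL
      pos <- sample_positions(copies_here, 5000,
                              config$scaffold_length - 5000 - spec$length,
                              min_sep = spec$length + 4000, avoid = avoid)
      for (j in seq_along(pos)) {
        copy <- diverge_seq(motifs[[nm]], runif(1, 0.005, 0.02))
        substr(s, pos[j], pos[j] + nchar(copy) - 1) <- copy
        placements[[length(placements) + 1]] <-
          data.frame(scaffold = chrom, start = pos[j],
                     end = pos[j] + nchar(copy) - 1, motif = nm,
                     copy = paste0(nm, "_", chrom, "_", j),
                     stringsAsFactors = FALSE)
      }
    }
    seqs[[chrom]] <- s
  }
  circ <- NULL
  if (config$include_chrM) {
    seqs[["chrM"]] <- random_seq(16569, 0.44)
    circ <- c(chrM = TRUE)
  }
  out <- ScaffoldSet(seqs, circular = circ)
  attr(out, "repeat_placements") <- if (length(placements))
    do.call(rbind, placements)
  else data.frame(scaffold = character(0), start = integer(0),
                  end = integer(0), motif = character(0),
                  copy = character(0))
  attr(out, "motifs") <- motifs
  out
}

## ---- edit scripts and the coordinate lift map -------------------------

# An edit script row edits one reference interval:
#   type "sub": ref_len == alt_len, sequence replaced in place
#   type "ins": alt_seq inserted AFTER ref_pos (ref_len == 0)
#   type "del": ref_len bases starting at ref_pos removed (alt_len == 0)
# Rows must be non-overlapping in reference coordinates.

edit_script_row <- function(chrom, ref_pos, type, ref_len, alt_seq,
                            id = NA_character_) {
  data.frame(chrom = chrom, ref_pos = as.integer(ref_pos), type = type,
             ref_len = as.integer(ref_len), alt_seq = alt_seq,
             alt_len = nchar(alt_seq), id = id, stringsAsFactors = FALSE)
}

empty_edit_script <- function() {
  data.frame(chrom = character(0), ref_pos = integer(0),
             type = character(0), ref_len = integer(0),
             alt_seq = character(0), alt_len = integer(0),
             id = character(0), stringsAsFactors = FALSE)
}

sort_edits <- function(edits) {
  if (is.null(edits) || nrow(edits) == 0) return(empty_edit_script())
  edits <- edits[order(edits$chrom, edits$ref_pos,
                       edits$ref_len == 0), , drop = FALSE]
  rownames(edits) <- NULL
  edits
}

edits_overlap <- function(edits) {
  for (chrom in unique(edits$chrom)) {
    e <- edits[edits$chrom == chrom, , drop = FALSE]
    e <- e[order(e$ref_pos), , drop = FALSE]
    if (nrow(e) < 2) next
    # an insertion occupies the boundary after ref_pos; treat its span
    # as [ref_pos + 0.5, ref_pos + 0.5]
    s <- ifelse(e$ref_len == 0, e$ref_pos + 0.5, e$ref_pos)
    en <- ifelse(e$ref_len == 0, e$ref_pos + 0.5,
                 e$ref_pos + e$ref_len - 1)
    if (any(s[-1] <= en[-nrow(e)])) return(TRUE)
  }
  FALSE
}

apply_edit_script <- function(reference, edits) {
  seqs <- setNames(as.character(reference$seq), scaffold_names(reference))
  edits <- sort_edits(edits)
  if (edits_overlap(edits)) stop("overlapping edits")
  for (chrom in unique(edits$chrom)) {
    e <- edits[edits$chrom == chrom, , drop = FALSE]
    s <- seqs[[chrom]]
    pieces <- character(0)
    cur <- 1L
    for (i in seq_len(nrow(e))) {
      if (e$ref_len[i] == 0) { # insertion after ref_pos
        if (e$ref_pos[i] >= cur)
          pieces <- c(pieces, substr(s, cur, e$ref_pos[i]))
        pieces <- c(pieces, e$alt_seq[i])
        cur <- e$ref_pos[i] + 1L
      } else {
        if (e$ref_pos[i] > cur)
          pieces <- c(pieces, substr(s, cur, e$ref_pos[i] - 1L))
        pieces <- c(pieces, e$alt_seq[i]) # "" for deletions
        cur <- e$ref_pos[i] + e$ref_len[i]
      }
    }
    if (cur <= nchar(s)) pieces <- c(pieces, substr(s, cur, nchar(s)))
    seqs[[chrom]] <- paste(pieces, collapse = "")
  }
  ScaffoldSet(seqs, circular = reference$circular)
}

# Aligned-block map between reference and personal coordinates: one row
# per maximal stretch where positions correspond 1:1 (identity or
# in-place substitution). Deleted reference bases and inserted personal
# bases fall between blocks.
build_lift_map <- function(edits, ref_lengths) {
  edits <- sort_edits(edits)
  out <- list()
  for (chrom in names(ref_lengths)) {
    e <- edits[edits$chrom == chrom, , drop = FALSE]
    L <- ref_lengths[[chrom]]
    blocks <- list()
    ref_cur <- 1L
    shift <- 0L
    brk <- function(ref_from, ref_to) {
      if (ref_to >= ref_from)
        blocks[[length(blocks) + 1]] <<- data.frame(
          chrom = chrom, ref_start = ref_from, ref_end = ref_to,
          per_start = ref_from + shift, per_end = ref_to + shift)
    }
    for (i in seq_len(nrow(e))) {
      if (e$ref_len[i] == e$alt_len[i]) next # sub: 1:1, no block break
      if (e$ref_len[i] == 0) { # insertion after ref_pos
        brk(ref_cur, e$ref_pos[i])
        shift <- shift + e$alt_len[i]
        ref_cur <- e$ref_pos[i] + 1L
      } else { # deletion (alt_len == 0)
        brk(ref_cur, e$ref_pos[i] - 1L)
        shift <- shift - e$ref_len[i]
        ref_cur <- e$ref_pos[i] + e$ref_len[i]
      }
    }
    brk(ref_cur, L)
    out[[chrom]] <- do.call(rbind, blocks)
  }
  structure(out, class = "lift_map")
}

#' Lift positions between assemblies
#'
#' Translates 1-based positions along the germline edit script relating
#' the reference and personal genomes. Positions falling in sequence
#' private to the source assembly (deleted in, or inserted relative to,
#' the target) return `NA`. The map is exactly invertible on all
#' positions it defines.
#'
#' @param lift A lift map from [derive_personal_genome()].
#' @param chrom,pos Vectors of coordinates.
#' @param from `"reference"` or `"personal"`: the assembly `pos` refers
#'   to.
#' @return Integer vector of target-assembly positions (NA where
#'   undefined).
#' @export
lift_position <- function(lift, chrom, pos, from = c("reference",
                                                     "personal")) {
  from <- match.arg(from)
  chrom <- rep_len(chrom, length(pos))
  out <- rep(NA_integer_, length(pos))
  for (i in seq_along(pos)) {
    b <- lift[[chrom[i]]]
    if (is.null(b)) next
    if (from == "reference") {
      hit <- which(b$ref_start <= pos[i] & b$ref_end >= pos[i])
      if (length(hit))
        out[i] <- b$per_start[hit[1]] + (pos[i] - b$ref_start[hit[1]])
    } else {
      hit <- which(b$per_start <= pos[i] & b$per_end >= pos[i])
      if (length(hit))
        out[i] <- b$ref_start[hit[1]] + (pos[i] - b$per_start[hit[1]])
    }
  }
  out
}

#' Derive the personal genome from the reference
#'
#' Applies germline variation to the reference: background SNVs and
#' short indels at the configured per-bp rates, plus germline SVs
#' (personal-only Alu-like insertions taken from the repeat library,
#' deletions, tandem expansions, and a homopolymer-run extension).
#' Overlapping candidate edits are rejected and resampled. When an
#' explicit `edits` script is supplied (as [simulate_study()] does, to
#' engineer somatic flanking contexts) it is applied verbatim instead.
#'
#' @param reference A [ScaffoldSet] from [generate_reference_genome()].
#' @param config A [simulation_config()].
#' @param edits Optional explicit edit script.
#' @param seed Seed; `NULL` continues the current stream.
#' @return A list: `genome` (personal [ScaffoldSet]), `edits` (the edit
#'   script), `lift` (coordinate lift map), `germline` (germline truth:
#'   `small` and `sv` data frames with coordinates on both assemblies).
#' @export
derive_personal_genome <- function(reference, config, edits = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  auto <- paste0("chr", seq_len(config$n_scaffolds))
  if (is.null(edits))
    edits <- sample_germline_edits(reference, config, auto)
  edits <- sort_edits(edits)
  personal <- apply_edit_script(reference, edits)
  lift <- build_lift_map(edits, as.list(scaffold_lengths(reference)))
  germ <- edits_to_truth(reference, edits, lift)
  list(genome = personal, edits = edits, lift = lift, germline = germ)
}

sample_germline_edits <- function(reference, config, chroms,
                                  avoid = NULL) {
  motifs <- attr(reference, "motifs")
  rows <- list()
  add <- function(r) rows[[length(rows) + 1]] <<- r
  # germline SVs are placed first (their footprints are the largest),
  # spread over scaffolds; small variants then avoid the SV footprints
  svc <- config$germline_sv_counts
  existing_sv <- function() {
    if (!length(rows)) return(NULL)
    e <- do.call(rbind, rows)
    data.frame(chrom = e$chrom, start = e$ref_pos - 1500,
               end = e$ref_pos + e$ref_len + 1500)
  }
  place_sv <- function(kind, k) {
    for (j in seq_len(k)) {
      chrom <- chroms[1 + (j - 1) %% length(chroms)]
      L <- scaffold_lengths(reference)[[chrom]]
      ex <- existing_sv()
      # pad avoided windows on the left so an SV starting before a
      # window cannot extend into it (max germline SV footprint ~600 bp)
      av0 <- if (!is.null(avoid)) {
        a <- avoid[avoid$chrom == chrom, c("start", "end"), drop = FALSE]
        a$start <- a$start - 600
        a
      }
      av <- rbind(
        if (!is.null(ex))
          ex[ex$chrom == chrom, c("start", "end"), drop = FALSE],
        av0)
      p <- sample_positions(1, 5000, L - 5000, min_sep = 1,
                            avoid = av)
      if (kind == "alu_ins") {
        alu <- diverge_seq(motifs$alu_like, runif(1, 0.005, 0.02))
        add(edit_script_row(chrom, p, "ins", 0, alu,
                            id = paste0("germline_alu_ins_", j)))
      } else if (kind == "del") {
        len <- sample(200:500, 1)
        add(edit_script_row(chrom, p, "del", len, "",
                            id = paste0("germline_del_", j)))
      } else if (kind == "tandem_expansion") {
        len <- sample(50:200, 1)
        unit <- scaffold_seq(reference, chrom, p, p + len - 1)
        add(edit_script_row(chrom, p + len - 1, "ins", 0, unit,
                            id = paste0("germline_tandem_exp_", j)))
      } else if (kind == "homopolymer_expansion") {
        extra <- sample(10:20, 1)
        add(edit_script_row(chrom, p, "ins", 0, strrep("A", extra),
                            id = paste0("germline_homopol_", j)))
      }
    }
  }
  for (kind in names(svc)) place_sv(kind, svc[[kind]])
  sv_footprints <- if (length(rows)) {
    e <- do.call(rbind, rows)
    data.frame(chrom = e$chrom, start = e$ref_pos - 20,
               end = e$ref_pos + e$ref_len + 20)
  } else NULL
  for (chrom in chroms) {
    L <- scaffold_lengths(reference)[[chrom]]
    av <- rbind(
      if (!is.null(avoid))
        avoid[avoid$chrom == chrom, c("start", "end"), drop = FALSE],
      if (!is.null(sv_footprints))
        sv_footprints[sv_footprints$chrom == chrom,
                      c("start", "end"), drop = FALSE])
    n_snv <- rbinom(1, L, config$germline_snv_rate)
    n_ind <- rbinom(1, L, config$germline_indel_rate)
    pos <- sample_positions(n_snv + n_ind, 200, L - 200, min_sep = 25,
                            avoid = av)
    pos <- sample(pos) # shuffle before splitting into SNVs/indels
    snv_pos <- sort(head(pos, n_snv))
    ind_pos <- sort(head(pos[-seq_len(n_snv)], n_ind))
    for (p in snv_pos) {
      b <- scaffold_seq(reference, chrom, p, p)
      add(edit_script_row(chrom, p, "sub", 1, other_base(b),
                          id = "germline_snv"))
    }
    for (p in ind_pos) {
      len <- sample(1:10, 1)
      if (runif(1) < 0.5)
        add(edit_script_row(chrom, p, "ins", 0,
                            random_seq(len, config$gc),
                            id = "germline_indel"))
      else
        add(edit_script_row(chrom, p, "del", len, "",
                            id = "germline_indel"))
    }
  }
  edits <- sort_edits(do.call(rbind, rows))
  # overlap is precluded by the avoidance margins, but resample
  # defensively if it ever occurs
  tries <- 0
  while (edits_overlap(edits)) {
    tries <- tries + 1
    if (tries > 10) stop("could not sample a non-overlapping edit script")
    message("overlapping germline edits; resampling")
    edits <- Recall(reference, config, chroms, avoid)
  }
  edits
}

edits_to_truth <- function(reference, edits, lift) {
  small <- edits[edits$ref_len <= 1 & edits$alt_len <= 1 &
                   !(edits$ref_len == 0 & edits$alt_len == 0) &
                   (edits$ref_len + edits$alt_len <= 2) &
                   edits$type == "sub", , drop = FALSE]
  is_small_indel <- edits$type %in% c("ins", "del") &
    pmax(edits$ref_len, edits$alt_len) < 50
  is_sv <- edits$type %in% c("ins", "del") & !is_small_indel
  sm <- data.frame(chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   per_pos = integer(0), kind = character(0),
                   stringsAsFactors = FALSE)
  if (nrow(small)) {
    sm <- data.frame(chrom = small$chrom, pos = small$ref_pos,
                     ref = vapply(seq_len(nrow(small)), function(i)
                       scaffold_seq(reference, small$chrom[i],
                                    small$ref_pos[i], small$ref_pos[i]),
                       ""),
                     alt = small$alt_seq,
                     per_pos = lift_position(lift, small$chrom,
                                             small$ref_pos),
                     kind = small$id, stringsAsFactors = FALSE)
  }
  # small indels in VCF-anchored representation (anchor base included)
  ind <- edits[is_small_indel, , drop = FALSE]
  if (nrow(ind)) {
    indf <- do.call(rbind, lapply(seq_len(nrow(ind)), function(i) {
      e <- ind[i, ]
      if (e$type == "ins") {
        anchor <- scaffold_seq(reference, e$chrom, e$ref_pos, e$ref_pos)
        data.frame(chrom = e$chrom, pos = e$ref_pos, ref = anchor,
                   alt = paste0(anchor, e$alt_seq),
                   per_pos = lift_position(lift, e$chrom, e$ref_pos),
                   kind = e$id, stringsAsFactors = FALSE)
      } else {
        anchor_pos <- e$ref_pos - 1L
        anchor <- scaffold_seq(reference, e$chrom, anchor_pos, anchor_pos)
        data.frame(chrom = e$chrom, pos = anchor_pos,
                   ref = paste0(anchor,
                                scaffold_seq(reference, e$chrom,
                                             e$ref_pos,
                                             e$ref_pos + e$ref_len - 1L)),
                   alt = anchor,
                   per_pos = lift_position(lift, e$chrom, anchor_pos),
                   kind = e$id, stringsAsFactors = FALSE)
      }
    }))
    sm <- rbind(sm, indf)
  }
  sv <- edits[is_sv, , drop = FALSE]
  svdf <- data.frame(chrom = character(0), ref_start = integer(0),
                     ref_end = integer(0), per_start = integer(0),
                     per_end = integer(0), sv_type = character(0),
                     sv_len = integer(0), id = character(0),
                     personal_only = logical(0), stringsAsFactors = FALSE)
  if (nrow(sv)) {
    svdf <- do.call(rbind, lapply(seq_len(nrow(sv)), function(i) {
      e <- sv[i, ]
      if (e$type == "ins") {
        per_ins <- lift_position(lift, e$chrom, e$ref_pos) + 1L
        data.frame(chrom = e$chrom, ref_start = e$ref_pos,
                   ref_end = e$ref_pos,
                   per_start = per_ins, per_end = per_ins + e$alt_len - 1L,
                   sv_type = "INS", sv_len = e$alt_len, id = e$id,
                   personal_only = TRUE, stringsAsFactors = FALSE)
      } else {
        data.frame(chrom = e$chrom, ref_start = e$ref_pos,
                   ref_end = e$ref_pos + e$ref_len - 1L,
                   per_start = lift_position(lift, e$chrom,
                                             e$ref_pos - 1L) + 1L,
                   per_end = lift_position(lift, e$chrom,
                                           e$ref_pos - 1L),
                   sv_type = "DEL", sv_len = e$ref_len, id = e$id,
                   personal_only = FALSE, stringsAsFactors = FALSE)
      }
    }))
  }
  list(small = sm, sv = svdf)
}
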