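tiny_config <- function(seed = 21, ...) {
  simulation_config(
    seed = seed, scaffold_length = 60000L,
    germline_snv_rate = 5e-4, germline_indel_rate = 5e-5,
    germline_sv_counts = c(alu_ins = 2, del = 1, tandem_expansion = 1,
                           homopolymer_expansion = 1),
    repeat_library = list(alu_like = list(length = 300L, copies = 2L),
                          simple_at = list(length = 60L, copies = 1L)),
    somatic_snv_profile = c(clean = 6, flanked = 3, destroyed = 2),
    somatic_sv_counts = c(DEL = 2, DUP = 1, INS = 1, INV = 1),
    caller_profiles = list(a = noise_free_profile("a"),
                           b = noise_free_profile("b")),
    ...)
}

test_that("reference generation is deterministic and records repeats", {
  cfg <- tiny_config()
  g1 <- generate_reference_genome(cfg)
  g2 <- generate_reference_genome(cfg)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  pl <- attr(g1, "repeat_placements")
  expect_equal(sum(pl$motif == "alu_like"), 2)
  expect_equal(nrow(pl), 3)
  # placements point at near-copies of the motif (0.5-2% divergence)
  motifs <- attr(g1, "motifs")
  for (i in seq_len(nrow(pl))) {
    copy <- scaffold_seq(g1, pl$scaffold[i], pl$start[i], pl$end[i])
    motif <- motifs[[pl$motif[i]]]
    mm <- sum(strsplit(copy, "")[[1]] != strsplit(motif, "")[[1]])
    expect_true(mm / nchar(motif) <= 0.03)
  }
  expect_true(g1$circular[["chrM"]])
  expect_equal(scaffold_lengths(g1)[["chrM"]], 16569)
  cfg0 <- tiny_config()
  cfg0$repeat_library <- list()
  g0 <- generate_reference_genome(cfg0)
  expect_equal(nrow(attr(g0, "repeat_placements")), 0)
  small <- tiny_config()
  small$scaffold_length <- 3000L
  expect_error(generate_reference_genome(small), "too small")
})

test_that("personal genome length bookkeeping is exact", {
  cfg <- tiny_config()
  ref <- generate_reference_genome(cfg)
  pg <- derive_personal_genome(ref, cfg, seed = cfg$seed + 1)
  net <- sum(pg$edits$alt_len - pg$edits$ref_len)
  expect_equal(sum(scaffold_lengths(pg$genome)),
               sum(scaffold_lengths(ref)) + net)
  # zero-rate config: personal genome identical, lift is the identity
  cfg0 <- tiny_config()
  cfg0$germline_snv_rate <- 0
  cfg0$germline_indel_rate <- 0
  cfg0$germline_sv_counts[] <- 0
  ref0 <- generate_reference_genome(cfg0)
  pg0 <- derive_personal_genome(ref0, cfg0, seed = 1)
  expect_identical(as.character(pg0$genome$seq),
                   as.character(ref0$seq))
  expect_equal(lift_position(pg0$lift, "chr1", c(1, 999, 60000)),
               c(1L, 999L, 60000L))
})

test_that("the lift map is exactly invertible on planted positions", {
  cfg <- tiny_config(seed = 22)
  ref <- generate_reference_genome(cfg)
  pg <- derive_personal_genome(ref, cfg, seed = cfg$seed + 1)
  g <- pg$germline$small
  expect_true(nrow(g) > 10)
  back <- lift_position(pg$lift, g$chrom, g$per_pos, from = "personal")
  expect_equal(back, g$pos)
  # lifted germline SNVs show the alt base on the personal genome
  snvs <- g[g$kind == "germline_snv", ]
  for (i in seq_len(min(20, nrow(snvs)))) {
    expect_equal(scaffold_seq(pg$genome, snvs$chrom[i],
                              snvs$per_pos[i], snvs$per_pos[i]),
                 snvs$alt[i])
  }
  # positions inside a personal-only insertion have no reference image
  ins <- pg$germline$sv[pg$germline$sv$personal_only, ]
  expect_true(nrow(ins) >= 2)
  mid <- ins$per_start[1] + 5L
  expect_true(is.na(lift_position(pg$lift, ins$chrom[1], mid,
                                  from = "personal")))
})

test_that("an explicit single insertion shifts downstream coordinates", {
  cfg <- tiny_config()
  ref <- generate_reference_genome(cfg)
  edits <- persoma:::edit_script_row("chr1", 5000L, "ins", 0,
                                     strrep("ACGT", 75))
  pg <- derive_personal_genome(ref, cfg, edits = edits)
  expect_equal(scaffold_lengths(pg$genome)[["chr1"]],
               scaffold_lengths(ref)[["chr1"]] + 300L)
  expect_equal(lift_position(pg$lift, "chr1", 5000L), 5000L)
  expect_equal(lift_position(pg$lift, "chr1", 5001L), 5301L)
  expect_identical(scaffold_seq(pg$genome, "chr1", 1, 5000),
                   scaffold_seq(ref, "chr1", 1, 5000))
})

test_that("somatic truth carries both coordinate systems and MAFs", {
  st <- simulate_study(tiny_config(seed = 23))
  snv <- st$somatic$snv
  expect_equal(nrow(snv), 11)
  expect_true(all(snv$maf %in% c(0.5, 1.0)))
  expect_true(all(snv$ref != snv$alt))
  # personal coordinates agree with the lift of reference coordinates
  expect_equal(snv$per_pos,
               lift_position(st$lift, snv$chrom, snv$ref_pos))
  # the somatic allele is absent from both (normal) assemblies
  for (i in seq_len(nrow(snv))) {
    expect_equal(scaffold_seq(st$reference, snv$chrom[i],
                              snv$ref_pos[i], snv$ref_pos[i]), snv$ref[i])
    expect_equal(scaffold_seq(st$personal, snv$chrom[i],
                              snv$per_pos[i], snv$per_pos[i]), snv$ref[i])
  }
  sv <- st$somatic$sv
  po <- sv[sv$context == "personal_only", ]
  expect_equal(nrow(po), 1)
  expect_true(is.na(po$ref_start))
  expect_false(is.na(po$per_start))
})

test_that("noise-free callsets equal the truth; FN rate is binomial", {
  st <- simulate_study(tiny_config(seed = 24))
  cs <- simulate_caller_callset(st$somatic, "personal",
                                noise_free_profile(), st$personal,
                                seed = 1)
  expect_equal(nrow(cs$small), nrow(st$somatic$snv))
  expect_equal(sort(cs$small$pos), sort(st$somatic$snv$per_pos))
  expect_equal(nrow(cs$sv), nrow(st$somatic$sv))
  # reference-target callset omits personal-only records
  cr <- simulate_caller_callset(st$somatic, "reference",
                                noise_free_profile(), st$reference,
                                seed = 1)
  expect_equal(nrow(cr$sv),
               sum(!is.na(st$somatic$sv$ref_start)))
  # FN draws are binomial: 1000 records at fn = 0.1 over 60 seeds
  truth <- list(snv = data.frame(
    chrom = "chr1", ref_pos = seq(1000, by = 50, length.out = 1000),
    per_pos = seq(1000, by = 50, length.out = 1000),
    ref = "A", alt = "G", maf = 0.5, context = "clean",
    stringsAsFactors = FALSE),
    sv = st$somatic$sv[0, ])
  prof <- caller_profile("x", fn_rate = 0.1, fp_rate = 0,
                         jitter_sd = 0)
  dropped <- vapply(1:60, function(s) {
    cs <- simulate_caller_callset(truth, "personal", prof,
                                  st$personal, seed = s)
    1000 - nrow(cs$small)
  }, 1)
  expect_equal(simulate_caller_callset(truth, "personal", prof,
                                       st$personal, seed = 7)$small,
               simulate_caller_callset(truth, "personal", prof,
                                       st$personal, seed = 7)$small)
  expect_true(abs(mean(dropped) - 100) < 4 * sqrt(1000 * .1 * .9 / 60))
})

test_that("joint genotyped SVs separate germline from somatic", {
  st <- simulate_study(tiny_config(seed = 25))
  joint <- simulate_joint_genotyped_sv_vcf(st$germline$sv,
                                           st$somatic$sv,
                                           noise_free_profile(),
                                           seed = 2)
  g <- joint[joint$germline_truth, ]
  s <- joint[!joint$germline_truth, ]
  expect_true(all(g$gt_normal %in% c("0/1", "1/1")))
  expect_true(all(g$gt_normal == g$gt_tumor))
  expect_true(all(s$gt_normal == "0/0"))
  expect_true(all(s$af_normal == 0))
  expect_true(all(abs(s$af_tumor - round(50 * s$af_tumor) / 50) < 1e-9))
  # depth/fraction consistency invariant holds exactly
  tot <- s$alt_depth_tumor + s$ref_depth_tumor
  expect_true(all(abs(s$af_tumor - s$alt_depth_tumor / tot) <= 0.01))
})

test_that("truth tables round-trip through the TSV export", {
  st <- simulate_study(tiny_config(seed = 26))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(st, f)
  tab <- read.table(f, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  expect_setequal(unique(tab$class), c("germline", "somatic"))
  expect_equal(sum(tab$class == "somatic" & tab$kind == "snv"),
               nrow(st$somatic$snv))
  expect_true(all(c("ref_start", "per_start", "maf", "context") %in%
                    names(tab)))
})
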