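test_that("FASTA round trip preserves names, order and content", {
  ss <- ScaffoldSet(c(alpha = "ACGTACGTAC", beta = "GGGCCCAAATTT"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ss, f, width = 5)
  back <- read_fasta(f)
  expect_identical(scaffold_names(back), c("alpha", "beta"))
  expect_identical(as.character(back$seq), as.character(ss$seq))
})

test_that("FASTA reading uppercases and rejects empty records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "acgtn"), f)
  expect_identical(scaffold_seq(read_fasta(f), "x"), "ACGTN")
  writeLines(c(">x", "", ">y", "ACGT"), f)
  expect_error(read_fasta(f), "non-empty")
  expect_error(read_fasta("/no/such/file.fa"), "no such file")
})

test_that("ScaffoldSet enforces unique names and the ACGTN alphabet", {
  expect_error(ScaffoldSet(c(a = "ACGT", a = "GGTT")), "unique")
  expect_error(ScaffoldSet(c(a = "ACGU")), "A/C/G/T/N")
  expect_error(ScaffoldSet(setNames("ACGT", NULL)), "named")
  ss <- ScaffoldSet(c(chrM = "ACGT"), circular = c(chrM = TRUE))
  expect_true(ss$circular[["chrM"]])
})

test_that("VCF round trip is lossless for modeled fields", {
  small <- small_variant_table(
    chrom = c("chr1", "chr1"), pos = c(100, 250), ref = c("A", "TG"),
    alt = c("G", "T"), qual = c(50, 60),
    gt_tumor = c("0/1", "1/1"), alt_depth_tumor = c(25L, 50L),
    ref_depth_tumor = c(25L, 0L), af_tumor = c(0.5, 1),
    gt_normal = c("0/0", "0/0"), alt_depth_normal = c(0L, 0L),
    ref_depth_normal = c(50L, 50L), af_normal = c(0, 0))
  sv <- sv_table(chrom = "chr2", start = 1000, end = 1310,
                 sv_type = "DEL", sv_len = -311, qual = 99,
                 gt_tumor = "0/1", alt_depth_tumor = 20L,
                 ref_depth_tumor = 30L, af_tumor = 0.4,
                 gt_normal = "0/0", alt_depth_normal = 0L,
                 ref_depth_normal = 50L, af_normal = 0)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(f, small = small, sv = sv,
            contigs = c(chr1 = 10000, chr2 = 10000))
  back <- read_vcf(f)
  expect_equal(back$small$pos, small$pos)
  expect_equal(back$small$ref, small$ref)
  expect_equal(back$small$alt, small$alt)
  expect_equal(back$small$gt_tumor, small$gt_tumor)
  expect_equal(back$small$af_tumor, small$af_tumor, tolerance = 1e-6)
  expect_equal(back$sv$sv_type, "DEL")
  expect_equal(back$sv$sv_len, 311)  # |SVLEN| from SVLEN=-311
  expect_equal(back$sv$start, 1000L)
  expect_equal(back$sv$end, 1310L)
  expect_equal(back$sv$gt_normal, "0/0")
})

test_that("VCF dialect options control PASS filtering and splitting", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t10\t.\tA\tG\t50\tPASS\t.",
    "chr1\t20\t.\tC\tT,G\t50\tPASS\t.",
    "chr1\t30\t.\tG\tA\t50\tLowQual\t."), f)
  got <- read_vcf(f)$small
  expect_equal(nrow(got), 3)  # PASS-only + multiallelic split
  expect_equal(got$alt, c("G", "T", "G"))
  keepall <- read_vcf(f, vcf_dialect(pass_only = FALSE,
                                     split_multiallelic = FALSE))$small
  expect_equal(nrow(keepall), 3)
  expect_true("T,G" %in% keepall$alt)
})

test_that("unparseable coordinates raise a parse error", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\toops\t.\tA\tG\t50\tPASS\t."), f)
  expect_error(suppressWarnings(read_vcf(f)), "POS")
})

test_that("region exclusions reproduce the documented boundaries", {
  rules <- default_region_rules()
  snv <- function(chrom, pos)
    small_variant_table(chrom = chrom, pos = pos, ref = "A", alt = "G")
  expect_equal(nrow(apply_region_exclusions(snv("chr6", 58000000),
                                            rules)), 0)
  expect_equal(nrow(apply_region_exclusions(snv("chr6", 59000000),
                                            rules)), 1)
  expect_equal(nrow(apply_region_exclusions(snv("chr16", 39000000),
                                            rules)), 0)
  expect_equal(nrow(apply_region_exclusions(snv("chr16", 38000000),
                                            rules)), 1)
  expect_equal(nrow(apply_region_exclusions(snv("chrX", 123), rules)), 0)
  expect_equal(nrow(apply_region_exclusions(
    snv("chrUn_KI270302v1", 5), rules)), 0)
  expect_equal(nrow(apply_region_exclusions(snv("chr1", 5), rules)), 1)
})

test_that("region exclusion is idempotent, subsetting, and TRA-aware", {
  rules <- default_region_rules()
  sv <- sv_table(chrom = c("chr1", "chr2"), start = c(100, 200),
                 end = c(100, 200), sv_type = c("TRA", "TRA"),
                 sv_len = NA, mate_chrom = c("chrX", "chr3"),
                 mate_pos = c(500, 500))
  kept <- apply_region_exclusions(sv, rules)
  expect_equal(kept$chrom, "chr2")  # TRA with excluded mate dropped
  twice <- apply_region_exclusions(kept, rules)
  expect_identical(twice$chrom, kept$chrom)
  set.seed(42)
  big <- small_variant_table(
    chrom = sample(c("chr1", "chr6", "chr16", "chrX"), 50, TRUE),
    pos = sample.int(1e8, 50), ref = "A", alt = "C")
  out <- apply_region_exclusions(big, rules)
  expect_true(all(paste(out$chrom, out$pos) %in%
                    paste(big$chrom, big$pos)))
})

test_that("comparator rules convert to BED intervals", {
  bed <- region_rules_as_bed(default_region_rules(),
                             c(chr6 = 1e8, chr16 = 9e7, chrX = 5e7))
  x <- bed[bed$chrom == "chrX", ]
  expect_equal(c(x$start, x$end), c(0, 5e7))
  p6 <- bed[bed$chrom == "chr6", ]
  expect_equal(c(p6$start, p6$end), c(0, 58499999))
  p16 <- bed[bed$chrom == "chr16", ]
  expect_equal(c(p16$start, p16$end), c(38400000, 9e7))
})

test_that("normalization left-aligns and trims indels", {
  # context ...TCAAA...: pos 5 REF=CAA ALT=CA is a 1 bp A-deletion whose
  # leftmost minimal representation anchors at the C (pos 5, CA > C)
  g <- ScaffoldSet(c(chr1 = "AGGTCAAAGTCA"))
  v <- small_variant_table(chrom = "chr1", pos = 5, ref = "CAA",
                           alt = "CA")
  norm <- normalize_small_variant(v, g)
  expect_equal(norm$pos, 5)
  expect_equal(norm$ref, "CA")
  expect_equal(norm$alt, "C")
  # a right-shifted spelling of the same deletion normalizes identically
  v2 <- small_variant_table(chrom = "chr1", pos = 6, ref = "AA",
                            alt = "A")
  norm2 <- normalize_small_variant(v2, g)
  expect_equal(norm2[, c("pos", "ref", "alt")],
               norm[, c("pos", "ref", "alt")])
  # SNVs are fixed points; normalization is idempotent
  snv <- small_variant_table(chrom = "chr1", pos = 4, ref = "T",
                             alt = "G")
  expect_equal(normalize_small_variant(snv, g), snv)
  expect_equal(normalize_small_variant(norm, g), norm)
  bad <- small_variant_table(chrom = "chr1", pos = 5, ref = "GAA",
                             alt = "G")
  expect_error(normalize_small_variant(bad, g), "mismatch")
})

test_that("normalization preserves the reconstructed haplotype", {
  set.seed(99)
  for (rep in 1:25) {
    s <- random_dna(60)
    g <- ScaffoldSet(c(c1 = s))
    pos <- sample(10:40, 1)
    rl <- sample(1:4, 1)
    al <- sample(1:4, 1)
    ref <- substr(s, pos, pos + rl - 1)
    alt <- if (al == rl) next else
      paste0(substr(ref, 1, 1), random_dna(max(al - 1, 0)))
    v <- small_variant_table(chrom = "c1", pos = pos, ref = ref,
                             alt = alt)
    n <- normalize_small_variant(v, g)
    expect_identical(
      oracle_apply_variant(s, n$pos, n$ref, n$alt),
      oracle_apply_variant(s, v$pos, v$ref, v$alt))
  }
})

test_that("genotype entries must be consistent with depths", {
  expect_error(
    small_variant_table(chrom = "c", pos = 1, ref = "A", alt = "G",
                        gt_tumor = "0/1", alt_depth_tumor = 10L,
                        ref_depth_tumor = 10L, af_tumor = 0.9),
    "inconsistent")
  ok <- small_variant_table(chrom = "c", pos = 1, ref = "A", alt = "G",
                            gt_tumor = "0/1", alt_depth_tumor = 10L,
                            ref_depth_tumor = 10L, af_tumor = 0.5)
  expect_equal(nrow(ok), 1)
})
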