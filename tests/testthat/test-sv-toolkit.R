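mk_sv <- function(...) sv_table(...)

test_that("filter boundaries sit exactly at the documented thresholds", {
  svs <- mk_sv(chrom = "chr1", start = c(100, 100, 100, 100),
               end = c(148, 149, 5000, 5000),
               sv_type = c("DEL", "DEL", "DEL", "DEL"),
               sv_len = c(49, 50, 4901, 4901),
               qual = c(99, 99, 19, 20), filter = "PASS",
               caller = c("manta", "manta", "novobreak", "novobreak"))
  out <- filter_sv_callset(svs, sv_filter_profile())
  expect_equal(out$sv_len, c(50, 4901))  # 49 bp and qual-19 dropped
  expect_equal(out$qual, c(99, 20))
  log <- attr(out, "filter_log")
  expect_equal(unname(log["svlen"]), 1)
  expect_equal(unname(log["quality"]), 1)
})

test_that("PASS, IMPRECISE and intra-chromosomal BND filters apply", {
  svs <- mk_sv(chrom = rep("chr1", 5), start = c(1, 2, 3, 4, 5) * 1000,
               end = c(2, 3, 4, 5, 6) * 1000,
               sv_type = c("DEL", "DEL", "DEL", "BND", "BND"),
               sv_len = c(1000, 1000, 1000, NA, NA),
               filter = c("PASS", "LowQual", "SHADOWED", "PASS", "PASS"),
               imprecise = c(FALSE, FALSE, FALSE, FALSE, FALSE),
               mate_chrom = c(NA, NA, NA, "chr1", "chr5"),
               mate_pos = c(NA, NA, NA, 90000, 123))
  out <- filter_sv_callset(svs, sv_filter_profile())
  expect_equal(out$sv_type, c("DEL", "BND"))
  expect_equal(out$mate_chrom[2], "chr5")  # intra-chrom BND removed
  imp <- mk_sv(chrom = "chr1", start = 1, end = 100, sv_type = "DEL",
               sv_len = 100, imprecise = TRUE)
  expect_equal(nrow(filter_sv_callset(imp, sv_filter_profile())), 0)
  # filtering is idempotent and subsetting
  again <- filter_sv_callset(out, sv_filter_profile())
  expect_equal(nrow(again), nrow(out))
})

test_that("type harmonization pools contractions/expansions", {
  expect_equal(harmonize_sv_types("repeat_contraction"), "DEL")
  expect_equal(harmonize_sv_types("tandem_contraction"), "DEL")
  expect_equal(harmonize_sv_types("repeat_expansion"), "INS")
  expect_equal(harmonize_sv_types("tandem_expansion"), "INS")
  expect_equal(harmonize_sv_types("INV"), "INV")
  expect_equal(harmonize_sv_types(c("DUP", "INS"), pool_dup_ins = TRUE),
               c("DUP/INS", "DUP/INS"))
  expect_error(harmonize_sv_types("SPLODGE"), "unknown sv_type")
  rec <- mk_sv(chrom = "chr3", start = 159539232, end = 159539900,
               sv_type = "repeat_contraction", sv_len = 668)
  h <- harmonize_sv_types(rec)
  expect_equal(h$sv_type, "DEL")
  expect_equal(h$sv_len, 668)
})

joint_sv <- function(gtn, gtt, altt, aft, afn = 0) {
  mk_sv(chrom = "chr1", start = 1000, end = 2000, sv_type = "DEL",
        sv_len = 1001, gt_tumor = gtt, gt_normal = gtn,
        alt_depth_tumor = altt, af_tumor = aft, af_normal = afn)
}

test_that("somatic selection applies the two genotype rules exactly", {
  # rule 1 boundaries
  expect_equal(nrow(select_somatic_sv_joint(
    joint_sv("0/0", "0/1", 6L, 0.25))), 1)
  expect_equal(nrow(select_somatic_sv_joint(
    joint_sv("0/0", "0/1", 5L, 0.2))), 1)
  expect_equal(nrow(select_somatic_sv_joint(
    joint_sv("0/0", "0/1", 4L, 0.25))), 0)
  expect_equal(nrow(select_somatic_sv_joint(
    joint_sv("0/0", "0/1", 6L, 0.19))), 0)
  # rule 2 boundaries (normal het, tumor hom with AF gain)
  expect_equal(nrow(select_somatic_sv_joint(
    joint_sv("0/1", "1/1", 12L, 0.90, afn = 0.40))), 1)
  expect_equal(nrow(select_somatic_sv_joint(
    joint_sv("0/1", "1/1", 12L, 0.80, afn = 0.40))), 0)
  expect_equal(nrow(select_somatic_sv_joint(
    joint_sv("0/1", "1/1", 9L, 0.90, afn = 0.40))), 0)
  expect_equal(nrow(select_somatic_sv_joint(
    joint_sv("0/1", "1/1", 12L, 0.90, afn = 0.50))), 0)  # diff only 0.40
  # het-het never qualifies
  expect_equal(nrow(select_somatic_sv_joint(
    joint_sv("0/1", "0/1", 20L, 0.5, afn = 0.5))), 0)
  expect_warning(select_somatic_sv_joint(
    joint_sv("./.", "0/1", 20L, 0.5)), "missing genotype")
})

test_that("af-difference boundary is inclusive at 0.45", {
  expect_equal(nrow(select_somatic_sv_joint(
    joint_sv("0/1", "1/1", 12L, 0.85, afn = 0.40))), 1)  # diff 0.45
  expect_equal(nrow(select_somatic_sv_joint(
    joint_sv("0/1", "1/1", 12L, 0.85, afn = 0.41))), 0)  # diff 0.44
})

test_that("germline subtraction respects the evidence gate and radius", {
  tumor <- mk_sv(chrom = "chr1", start = 10000, end = 10900,
                 sv_type = "DEL", sv_len = 901)
  near <- function(af, alt, start_off = 500)
    mk_sv(chrom = "chr1", start = 10000 + start_off,
          end = 10900 + start_off, sv_type = "DEL", sv_len = 901,
          af_normal = af, alt_depth_normal = alt,
          gt_normal = "0/1", gt_tumor = "0/1",
          af_tumor = af, alt_depth_tumor = alt)
  expect_equal(nrow(subtract_germline_svs(tumor, near(0.5, 20L))), 0)
  expect_equal(nrow(subtract_germline_svs(tumor, near(0.05, 20L))), 1)
  expect_equal(nrow(subtract_germline_svs(tumor, near(0.5, 4L))), 1)
  expect_equal(nrow(subtract_germline_svs(tumor,
                                          near(0.5, 20L, 1500))), 1)
  expect_equal(nrow(subtract_germline_svs(tumor, empty_svs <-
                                            tumor[0, ])), 1)
  # type-incompatible germline neighbor does not subtract
  inv <- near(0.5, 20L)
  inv$sv_type <- "INV"
  expect_equal(nrow(subtract_germline_svs(tumor, inv)), 1)
})

test_that("consensus merging honors the breakpoint radius and support", {
  a <- mk_sv(chrom = "chr1", start = 5000, end = 8000, sv_type = "DEL",
             sv_len = 3001)
  b_close <- mk_sv(chrom = "chr1", start = 5900, end = 8900,
                   sv_type = "DEL", sv_len = 3001)
  b_far <- mk_sv(chrom = "chr1", start = 6100, end = 9100,
                 sv_type = "DEL", sv_len = 3001)
  m1 <- merge_sv_callsets(list(x = a, y = b_close))
  expect_equal(nrow(m1), 1)
  expect_equal(m1$support, 2)
  m2 <- merge_sv_callsets(list(x = a, y = b_far))
  expect_equal(nrow(m2), 0)  # 1100 bp apart: two singleton clusters
  m3 <- merge_sv_callsets(list(x = a, y = a))
  expect_equal(nrow(m3), 1)
  expect_equal(m3$supporters, "x,y")
  expect_equal(nrow(merge_sv_callsets(list(only = a))), 0)
  m4 <- merge_sv_callsets(list(only = a),
                          merge_criteria(min_support = 1))
  expect_equal(nrow(m4), 1)
})

test_that("type awareness separates clusters unless disabled", {
  a <- mk_sv(chrom = "chr1", start = 5000, end = 8000, sv_type = "DEL",
             sv_len = 3001)
  b <- mk_sv(chrom = "chr1", start = 5000, end = 8000, sv_type = "INV",
             sv_len = 3001)
  expect_equal(nrow(merge_sv_callsets(list(x = a, y = b))), 0)
  off <- merge_sv_callsets(list(x = a, y = b),
                           merge_criteria(type_aware = FALSE))
  expect_equal(nrow(off), 1)
  # repeat_contraction clusters with DEL through harmonization
  rc <- b
  rc$sv_type <- "repeat_contraction"
  expect_equal(nrow(merge_sv_callsets(list(x = a, y = rc))), 1)
})

test_that("clustering equals the brute-force single-linkage oracle", {
  set.seed(501)
  for (rep in 1:15) {
    n <- sample(5:60, 1)
    recs <- mk_sv(
      chrom = sample(c("chr1", "chr2"), n, TRUE),
      start = st <- sample.int(50000, n, replace = TRUE),
      end = st + sample(100:3000, n, replace = TRUE),
      sv_type = sample(c("DEL", "INS", "DUP", "INV"), n, TRUE),
      sv_len = sample(60:3000, n, replace = TRUE))
    crit <- merge_criteria(min_support = 1)
    labels <- setNames(split(recs, seq_len(n)), paste0("c", seq_len(n)))
    got <- merge_sv_callsets(labels, crit)
    members <- attr(got, "members")
    oracle <- oracle_single_linkage(members, crit)
    # same partition: cluster ids must be a relabeling of the oracle's
    expect_equal(length(unique(members$cluster_id)),
                 length(unique(oracle)))
    expect_true(all(tapply(oracle, members$cluster_id,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("replicate support counts replicates, tolerating jitter", {
  base <- mk_sv(chrom = "chr1", start = 20000, end = 23000,
                sv_type = "DUP", sv_len = 3001)
  jit <- function(d) {
    x <- base
    x$start <- x$start + d
    x$end <- x$end + d
    x
  }
  reps <- list(r1 = base, r2 = jit(40), r3 = jit(-35))
  out <- require_replicate_support(reps, min_reps = 2)
  expect_equal(nrow(out), 1)
  expect_equal(out$support, 3)
  lonely <- list(r1 = base, r2 = mk_sv(chrom = "chr2", start = 1000,
                                       end = 2000, sv_type = "DUP",
                                       sv_len = 1001),
                 r3 = mk_sv(chrom = "chr2", start = 30000, end = 31000,
                            sv_type = "DUP", sv_len = 1001))
  out2 <- require_replicate_support(lonely, min_reps = 2)
  expect_equal(nrow(out2), 0)
})

test_that("SV flank queries extract the documented windows", {
  set.seed(502)
  g <- random_dna(3000)
  ss <- ScaffoldSet(c(chr = g))
  del <- mk_sv(chrom = "chr", start = 1200, end = 1510,
               sv_type = "DEL", sv_len = 311)
  q <- build_sv_flank_queries(del, ss)
  expect_equal(nchar(q$up_query), 100)
  expect_equal(nchar(q$down_query), 100)
  expect_equal(q$up_query, substr(g, 1100, 1199))
  expect_equal(q$down_query, substr(g, 1511, 1610))
  tra <- mk_sv(chrom = "chr", start = 500, end = 500, sv_type = "TRA",
               sv_len = NA, mate_chrom = "chr2", mate_pos = 1)
  expect_error(build_sv_flank_queries(tra, ss), "TRA/BND")
  edge <- mk_sv(chrom = "chr", start = 50, end = 200, sv_type = "DEL",
                sv_len = 151)
  expect_message(out <- build_sv_flank_queries(edge, ss), "excluded")
  expect_equal(nrow(out), 0)
})

test_that("SV flank mapping requires concordant flanks", {
  set.seed(503)
  src <- random_dna(6000)
  # target carries the source locus 1200..1800 verbatim at an offset
  tgt_seq <- paste0(random_dna(2000), substr(src, 1000, 2000),
                    random_dna(2000))
  src_ss <- ScaffoldSet(c(s = src))
  tgt_ss <- ScaffoldSet(c(t = tgt_seq))
  idx <- index_genome(tgt_ss)
  del <- mk_sv(chrom = "s", start = 1300, end = 1700, sv_type = "DEL",
               sv_len = 401)
  q <- build_sv_flank_queries(del, src_ss)
  m <- map_sv_flanks(q, idx, tgt_ss)
  expect_true(m$sv_mapped)
  expect_equal(m$mapped_chrom, "t")
  expect_equal(m$mapped_start, 2000 + (1300 - 1000) + 1)
  expect_equal(m$mapped_end, 2000 + (1700 - 1000) + 1)
  # flanks landing on different scaffolds: unmapped
  split_ss <- ScaffoldSet(c(a = paste0(substr(src, 1100, 1299),
                                       random_dna(500)),
                            b = paste0(random_dna(500),
                                       substr(src, 1701, 1900))))
  m2 <- map_sv_flanks(q, index_genome(split_ss), split_ss)
  expect_false(m2$sv_mapped)
  # one flank replaced by unrelated repeat-free sequence: unmapped
  tgt3 <- tgt_seq
  substr(tgt3, 2201, 2300) <- random_dna(100)
  t3 <- ScaffoldSet(c(t = tgt3))
  m3 <- map_sv_flanks(q, index_genome(t3), t3)
  expect_false(m3$sv_mapped)
})

test_that("mapped SVs match target SVs by type and radius", {
  res <- data.frame(sv_mapped = TRUE, mapped_chrom = "t",
                    mapped_start = 5000L, mapped_end = 5400L,
                    sv_type = "DEL", stringsAsFactors = FALSE)
  near <- mk_sv(chrom = "t", start = 5200, end = 5600,
                sv_type = "DEL", sv_len = 401)
  far <- mk_sv(chrom = "t", start = 6100, end = 6500, sv_type = "DEL",
               sv_len = 401)
  inv <- mk_sv(chrom = "t", start = 5200, end = 5600, sv_type = "INV",
               sv_len = 401)
  expect_equal(as.character(match_mapped_sv(res, near)$category),
               "matched")
  expect_equal(as.character(match_mapped_sv(res, far)$category),
               "mapped_without_match")
  expect_equal(as.character(match_mapped_sv(res, inv)$category),
               "mapped_without_match")
  un <- res
  un$sv_mapped <- FALSE
  expect_equal(as.character(match_mapped_sv(un, near)$category),
               "unmapped")
})
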