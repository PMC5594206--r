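test_that("read filter applies the strict >30% unconverted rule", {
  a <- fake_alignments(data.frame(
    read_id = c("r4of10", "r3of10", "r0of0"),
    transcript_id = "t1", tpos = 0L, length = 50L,
    c_total = c(10L, 10L, 0L), c_unconverted = c(4L, 3L, 0L),
    n_mismatch_non_c = 0L))
  out <- filter_reads(a, caller_config())
  expect_identical(out$n_removed, 1L)
  # 4/10 = 0.40 > 0.30 removed; 3/10 = 0.30 not > 0.30 kept; 0 Cs kept
  expect_setequal(out$alignments$alignments$read_id, c("r3of10", "r0of0"))
})

test_that("pileup counts i, j and other correctly", {
  obs <- data.frame(
    read_id = paste0("r", 1:12),
    transcript_id = "t1",
    tpos = c(rep(5L, 10), rep(9L, 2)),
    read_base = c(rep("C", 3), rep("T", 7), rep("G", 2)))
  aln <- fake_alignments(data.frame(
    read_id = paste0("r", 1:12), transcript_id = "t1", tpos = 0L,
    length = 20L, c_total = 1L, c_unconverted = 0L, n_mismatch_non_c = 0L),
    obs)
  pil <- build_pileup(aln)
  expect_identical(pil$i[pil$tpos == 5], 3L)
  expect_identical(pil$j[pil$tpos == 5], 7L)
  expect_identical(pil$other[pil$tpos == 5], 0L)
  # a position covered only by sequencing-error bases
  expect_identical(pil$i[pil$tpos == 9], 0L)
  expect_identical(pil$j[pil$tpos == 9], 0L)
  expect_identical(pil$other[pil$tpos == 9], 2L)
  expect_error(build_pileup(aln, c(t1 = "ACGTA")), "beyond")
})

test_that("pileup observation totals are conserved", {
  cfg <- sim_config(n_transcripts = 4, n_planted_sites = 10, depth = 8,
                    seed = 41)
  sim <- run_simulation(cfg)
  idx <- build_converted_index(sim$reference)
  aln <- align_reads(idx, sim$reads$read1, sim$reads$read2)
  kept <- filter_reads(aln)$alignments
  pil <- build_pileup(kept)
  expect_identical(sum(pil$i + pil$j + pil$other),
                   sum(kept$alignments$c_total))
})

test_that("conversion QC computes the spike-in rate with a strict gate", {
  pil <- data.frame(transcript_id = "Dhfr_spikein", tpos = 0:1,
                    i = c(20L, 10L), j = c(5000L, 4970L),
                    other = c(0L, 0L))
  rep1 <- conversion_qc(pil)      # 9970 / 10000
  expect_equal(rep1$rate, 0.997)
  expect_true(rep1$passed)
  pil$i <- c(30L, 20L); pil$j <- c(4990L, 4960L)   # 9950 / 10000
  rep2 <- conversion_qc(pil)
  expect_equal(rep2$rate, 0.995)
  expect_false(rep2$passed)
  expect_error(conversion_qc(pil[0, ]), "no spike-in")
})

test_that("site calling enforces all three credibility gates exactly", {
  models <- transcript_set(list(make_two_exon_model()))
  mk <- function(i, j) data.frame(transcript_id = "txA",
                                  tpos = c(10L, 60L, 110L, 150L)[seq_along(i)],
                                  i = i, j = j, other = 0L)
  # boundary case passes all three gates: cov 30, level 1/6, depth 5
  s <- call_sites(mk(5L, 25L), models)
  expect_identical(nrow(s), 1L)
  expect_equal(s$level, 5 / 30)
  expect_identical(s$coverage, 30L)
  # depth 4 < 5 fails; coverage 25 fails; level 3/30 = 0.1 passes level but
  # fails depth
  expect_identical(nrow(call_sites(mk(4L, 26L), models)), 0L)
  expect_identical(nrow(call_sites(mk(10L, 15L), models)), 0L)
  expect_identical(nrow(call_sites(mk(3L, 27L), models)), 0L)
  # level 2/30 < 0.1 fails even with depth ok
  expect_identical(nrow(call_sites(mk(2L, 28L), models)), 0L)
})

test_that("called sites carry projected genomic coordinates and annotation", {
  models <- transcript_set(list(make_two_exon_model()))
  pil <- data.frame(transcript_id = "txA", tpos = 120L, i = 10L, j = 30L,
                    other = 0L)
  s <- call_sites(pil, models)
  expect_identical(s$pos, 321L)
  expect_identical(s$chrom, "chr1")
  expect_identical(s$region, "CDS")
  expect_identical(s$gene_id, "geneA")
})

test_that("raising any caller threshold never increases the call count", {
  cfg <- sim_config(n_transcripts = 6, n_planted_sites = 25, depth = 50,
                    seed = 42)
  sim <- run_simulation(cfg)
  idx <- build_converted_index(sim$reference)
  res <- call_sample(idx, sim$reads$read1, sim$reads$read2, sim$models)
  base <- nrow(res$sites)
  stricter <- list(caller_config(min_coverage = 40),
                   caller_config(min_level = 0.2),
                   caller_config(min_methylated_depth = 10),
                   caller_config(max_unconverted_read_frac = 0.1))
  for (cc in stricter) {
    filt <- filter_reads(res$alignments, cc)
    pil <- build_pileup(filt$alignments)
    expect_lte(nrow(call_sites(pil, sim$models, cc)), base)
  }
})

test_that("failed conversion QC blocks site emission unless forced", {
  models <- transcript_set(list(make_two_exon_model()))
  pil <- data.frame(transcript_id = "txA", tpos = 120L, i = 10L, j = 30L,
                    other = 0L)
  qc <- structure(list(rate = 0.99, passed = FALSE, threshold = 0.996),
                  class = "conversion_report")
  expect_error(call_sites(pil, models, qc = qc), "conversion QC failed")
  expect_identical(nrow(call_sites(pil, models, qc = qc, force = TRUE)), 1L)
})

test_that("replicate intersection keeps shared sites with mean levels", {
  a <- make_sites(pos = c(100L, 200L, 300L), level = c(0.5, 0.20, 0.9))
  b <- make_sites(pos = c(200L, 300L, 400L), level = c(0.30, 0.7, 0.1))
  m <- intersect_replicates(a, b)
  expect_setequal(m$pos, c(200L, 300L))
  expect_equal(m$level[m$pos == 200], 0.25)
  expect_equal(m$level_rep1[m$pos == 200], 0.20)
  expect_equal(m$level_rep2[m$pos == 200], 0.30)
  # idempotence: intersect(T, T) keeps every site with unchanged level
  self <- intersect_replicates(a, a)
  expect_setequal(self$pos, a$pos)
  expect_equal(self$level[order(self$pos)], a$level[order(a$pos)])
  # pooled merging uses summed counts
  mp <- intersect_replicates(a, b, caller_config(merge_level = "pooled"))
  expect_equal(mp$level[mp$pos == 200], (10 + 15) / 100)
})

test_that("replicate intersection refuses mismatched references", {
  a <- make_sites(100L, 0.2); attr(a, "reference_id") <- "refA"
  b <- make_sites(100L, 0.3); attr(b, "reference_id") <- "refB"
  expect_error(intersect_replicates(a, b), "different references")
})
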