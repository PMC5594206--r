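test_that("region classification follows half-open CDS boundaries", {
  m <- transcript_model("t", "g", "c", "+", cbind(0L, 400L),
                        fixed_seq(400, 51), cds_start = 100L,
                        cds_end = 300L)
  expect_identical(classify_region(m, tpos = 50), "5UTR")
  expect_identical(classify_region(m, tpos = 99), "5UTR")
  expect_identical(classify_region(m, tpos = 100), "CDS")   # first CDS base
  expect_identical(classify_region(m, tpos = 299), "CDS")
  expect_identical(classify_region(m, tpos = 300), "3UTR")
  nc <- transcript_model("n", "g", "c", "+", cbind(0L, 100L),
                         fixed_seq(100, 52))
  expect_identical(classify_region(nc, tpos = 10), "ncRNA")
})

test_that("genomic positions between exons classify as intron", {
  m <- make_two_exon_model()   # exons [100,200) + [300,400)
  expect_identical(classify_region(m, gpos = 250L), "intron")
  expect_identical(classify_region(m, gpos = 150L),
                   classify_region(m, tpos = unproject_from_genome(m, 150L)))
  expect_error(classify_region(m, gpos = 50L), "outside gene span")
})

test_that("context classification reads the two downstream sense bases", {
  mk <- function(s) transcript_model("t", "g", "c", "+",
                                     cbind(0L, nchar(s)), s)
  expect_identical(classify_context(mk("ACGAT"), 1), "CG")
  expect_identical(classify_context(mk("ACAGT"), 1), "CHG")
  expect_identical(classify_context(mk("ACATT"), 1), "CHH")
  expect_identical(classify_context(mk("ACCGT"), 1), "CHG")
  # site at the last base: genomic fallback, else NA; exon covers 1-based
  # 11..15, so the downstream bases are genomic positions 16 and 17
  m_end <- transcript_model("t", "g", "c", "+", cbind(10L, 15L), "AAAAC")
  expect_identical(classify_context(m_end, 4), "NA")
  expect_identical(classify_context(
    m_end, 4, c(c = "AAAAAAAAAAAAAACGTAAA")), "CG")    # downstream GT
  expect_identical(classify_context(
    m_end, 4, c(c = "AAAAAAAAAAAAAACAGAAA")), "CHG")   # downstream AG
  expect_identical(classify_context(
    m_end, 4, c(c = "AAAAAAAAAAAAAACATAAA")), "CHH")   # downstream AT
  # minus strand fallback: downstream bases precede the exon genomically,
  # complemented; exon covers 1-based 11..15, downstream = positions 10, 9
  m_minus <- transcript_model("t", "g", "c", "-", cbind(10L, 15L), "AAAAC")
  genome3 <- c(c = "AAAAAAAACGGGGGAAAAAA")  # pos10 G, pos9 C -> "CG" -> CHG
  expect_identical(classify_context(m_minus, 4, genome3), "CHG")
  genome4 <- c(c = "AAAAAAAAACGGGGGAAAAA")  # pos10 C -> complement G -> CG
  expect_identical(classify_context(m_minus, 4, genome4), "CG")
})

test_that("transcriptome context proportions match a brute-force recount", {
  one_c <- transcript_model("t", "g", "c", "+", cbind(0L, 4L), "ACGG")
  p <- transcriptome_context_proportions(transcript_set(list(one_c)))
  expect_equal(unname(p["CG"]), 1)
  sim <- generate_transcriptome(sim_config(n_transcripts = 6, seed = 53))
  p1 <- transcriptome_context_proportions(sim$models)
  # brute force: per-base scan over every transcript
  counts <- c(CG = 0, CHG = 0, CHH = 0)
  for (m in sim$models) {
    if (m$spikein) next
    ch <- strsplit(m$sequence, "")[[1]]
    for (q in which(ch == "C")) {
      if (q + 2 > length(ch)) next
      ctx <- if (ch[q + 1] == "G") "CG"
             else if (ch[q + 2] == "G") "CHG" else "CHH"
      counts[ctx] <- counts[ctx] + 1
    }
  }
  expect_equal(p1, counts / sum(counts))
  expect_equal(sum(p1), 1)
  # invariant to transcript order
  p2 <- transcriptome_context_proportions(sim$models[rev(seq_along(sim$models))])
  expect_equal(p1, p2)
})

test_that("context normalization matches hand arithmetic", {
  out <- normalize_context_counts(c(CG = 100, CHG = 100, CHH = 100),
                                  c(CG = 0.2, CHG = 0.3, CHH = 0.5))
  # (100/0.2, 100/0.3, 100/0.5) = (500, 333.33, 200), total 1033.33
  expect_equal(unname(out$normalized_fractions),
               c(500, 1000 / 3, 200) / (500 + 1000 / 3 + 200))
  expect_equal(unname(out$normalized_fractions), c(0.484, 0.323, 0.194),
               tolerance = 1e-3)
  expect_equal(sum(out$normalized_fractions), 1)
  # uniform background leaves raw fractions unchanged
  u <- normalize_context_counts(c(CG = 30, CHG = 20, CHH = 50),
                                c(CG = 1, CHG = 1, CHH = 1) / 3)
  expect_equal(unname(u$normalized_fractions), c(0.3, 0.2, 0.5))
  # counts concentrated in one context
  one <- normalize_context_counts(c(CG = 40, CHG = 0, CHH = 0),
                                  c(CG = 0.4, CHG = 0.3, CHH = 0.3))
  expect_equal(unname(one$normalized_fractions), c(1, 0, 0))
  expect_error(normalize_context_counts(c(CG = 1, CHG = 0, CHH = 0),
                                        c(CG = 0, CHG = 0.5, CHH = 0.5)),
               "zero")
})

test_that("flank PFM has a pure-C centre and matches a letter tally", {
  sim <- generate_transcriptome(sim_config(n_transcripts = 5, seed = 54))
  cfg <- sim_config(n_transcripts = 5, n_planted_sites = 50, seed = 54)
  truth <- plant_m5c_sites(sim$models, cfg)
  sites <- data.frame(transcript_id = truth$transcript_id, tpos = truth$tpos)
  pfm <- extract_flanks(sites, sim$models)
  expect_identical(dim(pfm), c(21L, 4L))
  expect_equal(unname(pfm["0", "C"]), 1)
  expect_equal(unname(rowSums(pfm)), rep(1, 21))
  # brute-force tally
  tally <- matrix(0, 21, 4, dimnames = list(as.character(-10:10),
                                            c("A", "C", "G", "T")))
  for (k in seq_len(nrow(sites))) {
    s <- sim$models[[sites$transcript_id[k]]]$sequence
    for (d in -10:10) {
      q <- sites$tpos[k] + 1 + d
      if (q < 1 || q > nchar(s)) next
      b <- substr(s, q, q)
      tally[as.character(d), b] <- tally[as.character(d), b] + 1
    }
  }
  expect_equal(pfm, sweep(tally, 1, rowSums(tally), "/"))
  # single site gives a one-hot matrix over covered positions
  one <- extract_flanks(sites[1, ], sim$models)
  expect_true(all(one %in% c(0, 1)))
  # empty site set
  expect_identical(nrow(extract_flanks(sites[0, ], sim$models)), 0L)
})

test_that("metagene binning, conservation and smoothing behave", {
  m <- transcript_model("t", "g", "c", "+", cbind(0L, 600L),
                        fixed_seq(600, 55), cds_start = 100L,
                        cds_end = 400L)
  models <- transcript_set(list(m))
  sites <- data.frame(transcript_id = "t",
                      tpos = c(0L, 99L, 100L, 250L, 399L, 400L, 599L))
  prof <- metagene_profile(sites, models)
  expect_identical(sum(prof$count), nrow(sites))
  expect_equal(sum(prof$pct), 100)
  expect_equal(sum(prof$smoothed), 100)   # smoothing preserves mass
  g <- function(region, bin) prof$count[prof$region == region &
                                          prof$bin == bin]
  expect_identical(g("5UTR", 0), 1L)      # region offset 0 -> bin 0
  expect_identical(g("5UTR", 99), 1L)     # final base -> bin 99 (clamp)
  expect_identical(g("CDS", 0), 1L)
  expect_identical(g("CDS", 50), 1L)      # CDS offset 150 of 300 -> bin 50
  expect_identical(g("CDS", 99), 1L)
  expect_identical(g("3UTR", 0), 1L)
  expect_identical(g("3UTR", 99), 1L)
})

test_that("non-coding and spike-in sites are excluded from the metagene", {
  coding <- transcript_model("t", "g", "c", "+", cbind(0L, 300L),
                             fixed_seq(300, 56), cds_start = 50L,
                             cds_end = 250L)
  nc <- transcript_model("n", "g2", "c", "+", cbind(400L, 700L),
                         fixed_seq(300, 59))
  models <- transcript_set(list(coding, nc))
  sites <- data.frame(transcript_id = c("t", "n"), tpos = c(100L, 100L))
  prof <- metagene_profile(sites, models)
  expect_identical(sum(prof$count), 1L)     # only the coding site profiled
  expect_identical(attr(prof, "n_skipped"), 0L)
})

test_that("CDS positional histogram measures distance from start codon", {
  m <- transcript_model("t", "g", "c", "+", cbind(0L, 600L),
                        fixed_seq(600, 57), cds_start = 100L,
                        cds_end = 400L)
  models <- transcript_set(list(m))
  sites <- data.frame(transcript_id = "t", tpos = c(100L, 150L, 350L, 50L))
  h <- cds_positional_histogram(sites, models, max_offset = 200L)
  expect_identical(h$count[h$distance == 0], 1L)
  expect_identical(h$count[h$distance == 50], 1L)
  expect_identical(sum(h$count), 2L)   # 350 beyond max_offset, 50 is 5'UTR
})

test_that("background C profile equals metagene over an all-C site table", {
  sim <- generate_transcriptome(sim_config(n_transcripts = 4, seed = 58))
  bg <- background_c_profile(sim$models)
  allc <- do.call(rbind, lapply(sim$models, function(m) {
    if (is.na(m$cds_start) || m$spikein) return(NULL)
    cpos <- which(strsplit(m$sequence, "")[[1]] == "C") - 1L
    data.frame(transcript_id = m$transcript_id, tpos = cpos)
  }))
  expect_equal(as.data.frame(bg), as.data.frame(metagene_profile(allc,
                                                                 sim$models)))
  expect_identical(sum(bg$count), nrow(allc))
})
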