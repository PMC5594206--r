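# Shared fixtures and independent brute-force oracles used across tests.

# deterministic sequence with a given seed, avoiding the global RNG state
fixed_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# two-exon plus-strand coding model on a known genome
make_two_exon_model <- function(seed = 42) {
  seq <- fixed_seq(200, seed)
  transcript_model("txA", "geneA", "chr1", "+",
                   exons = cbind(c(100L, 300L), c(200L, 400L)),
                   sequence = seq, cds_start = 50L, cds_end = 170L)
}

make_minus_model <- function(seed = 43) {
  seq <- fixed_seq(100, seed)
  transcript_model("txB", "geneB", "chr1", "-",
                   exons = cbind(100L, 200L), sequence = seq,
                   cds_start = 20L, cds_end = 80L)
}

# minimal bisseq_alignments object built by hand
fake_alignments <- function(alignments, observations = NULL) {
  if (is.null(observations))
    observations <- data.frame(read_id = character(),
                               transcript_id = character(),
                               tpos = integer(), read_base = character())
  structure(list(alignments = alignments, observations = observations,
                 rejected = data.frame(read_id = character(),
                                       reason = character())),
            class = "bisseq_alignments")
}

# minimal site table for comparative/RIP tests
make_sites <- function(pos, level, gene_id = "geneA", chrom = "chr1",
                       strand = "+", transcript_id = "txA", tpos = pos) {
  n <- length(pos)
  m5cpipe:::as_site_table(data.frame(
    chrom = rep_len(chrom, n), pos = pos, strand = rep_len(strand, n),
    gene_id = rep_len(gene_id, n), transcript_id = rep_len(transcript_id, n),
    tpos = tpos, coverage = 50L, methylated_depth = round(level * 50),
    level = level, context = "CG", region = "CDS",
    stringsAsFactors = FALSE))
}

# ---- independent brute-force oracles -------------------------------------

# truth-based recount of pileups straight from read names and sequences,
# bypassing the aligner entirely; mirrors the read filter and caller gates
oracle_call <- function(sim, config) {
  ref <- sim$reference
  obs <- list(); kept <- 0L
  for (i in seq_along(sim$reads$read1)) {
    nm <- names(sim$reads$read1)[i]
    parts <- strsplit(nm, ":")[[1]]
    tid <- parts[1]
    start <- as.integer(strsplit(parts[2], "-")[[1]][1])  # 0-based
    r1 <- sim$reads$read1[[i]]
    len <- nchar(r1)
    window <- substr(ref[[tid]], start + 1L, start + len)
    wc <- strsplit(window, "")[[1]]
    rc <- strsplit(r1, "")[[1]]
    cpos <- which(wc == "C")
    n_unconv <- sum(rc[cpos] == "C")
    if (length(cpos) > 0 && n_unconv / length(cpos) >
          config$max_unconverted_read_frac) next
    kept <- kept + 1L
    if (length(cpos))
      obs[[length(obs) + 1L]] <-
        data.frame(transcript_id = tid, tpos = start + cpos - 1L,
                   base = rc[cpos])
  }
  obs <- do.call(rbind, obs)
  agg <- stats::aggregate(cbind(i = base == "C", j = base == "T") ~
                            transcript_id + tpos, data = obs, FUN = sum)
  spike <- vapply(sim$models, function(m) m$spikein, TRUE)[agg$transcript_id]
  cov <- agg$i + agg$j
  lev <- ifelse(cov > 0, agg$i / cov, 0)
  keep <- cov >= config$min_coverage & lev >= config$min_level &
    agg$i >= config$min_methylated_depth & !spike
  out <- agg[keep, c("transcript_id", "tpos", "i", "j")]
  out$level <- out$i / (out$i + out$j)
  out <- out[order(out$transcript_id, out$tpos), ]
  rownames(out) <- NULL
  out
}
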