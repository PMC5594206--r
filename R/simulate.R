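#' Simulation configuration
#'
#' Parameters of the RNA-BisSeq simulator. Reads are strand-specific 125-bp
#' pairs drawn from ~200-nt fragments of mature mRNA, matching a stranded
#' poly(A) library sequenced as paired 125-bp reads. Bisulfite chemistry is
#' modelled per fragment molecule: every planted cytosine is methylated with
#' probability equal to its stoichiometry; unmethylated C reads as T with
#' probability `p_convert_unmethylated` (near-complete conversion), methylated
#' C reads as T with probability `p_convert_methylated`.
#'
#' @param n_transcripts number of gene transcripts (the spike-in is added on
#'   top of these).
#' @param utr5_range,cds_range,utr3_range integer length ranges (nt) for the
#'   three mRNA regions.
#' @param ncrna_fraction fraction of transcripts generated without a CDS.
#' @param n_planted_sites number of m5C sites to plant across the
#'   transcriptome.
#' @param stoichiometry list describing the stoichiometry distribution:
#'   `list(type="beta", shape1=, shape2=)`, `list(type="uniform", min=, max=)`
#'   or `list(type="fixed", value=)`. The default Beta(1.5, 5) has median
#'   near 0.2, the typical bulk of mRNA m5C levels.
#' @param depth mean per-base fold-coverage contributed by read 1.
#' @param fragment_len_mean,fragment_len_sd fragment length distribution (nt).
#' @param read_len read length (nt).
#' @param p_convert_unmethylated,p_convert_methylated C-to-T conversion
#'   probabilities for unmethylated and methylated cytosines.
#' @param seq_error_rate per-base substitution error probability.
#' @param seed integer RNG seed; the whole simulation is reproducible for a
#'   fixed seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 20,
                       utr5_range = c(80, 150),
                       cds_range = c(240, 450),
                       utr3_range = c(120, 250),
                       ncrna_fraction = 0.1,
                       n_planted_sites = 50,
                       stoichiometry = list(type = "beta",
                                            shape1 = 1.5, shape2 = 5),
                       depth = 50,
                       fragment_len_mean = 200,
                       fragment_len_sd = 20,
                       read_len = 125,
                       p_convert_unmethylated = 0.999,
                       p_convert_methylated = 0.0,
                       seq_error_rate = 0.001,
                       seed = 1L) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              utr5_range = as.integer(utr5_range),
              cds_range = as.integer(cds_range),
              utr3_range = as.integer(utr3_range),
              ncrna_fraction = ncrna_fraction,
              n_planted_sites = as.integer(n_planted_sites),
              stoichiometry = stoichiometry,
              depth = depth,
              fragment_len_mean = fragment_len_mean,
              fragment_len_sd = fragment_len_sd,
              read_len = as.integer(read_len),
              p_convert_unmethylated = p_convert_unmethylated,
              p_convert_methylated = p_convert_methylated,
              seq_error_rate = seq_error_rate,
              seed = as.integer(seed))
  probs <- c(cfg$p_convert_unmethylated, cfg$p_convert_methylated,
             cfg$seq_error_rate, cfg$ncrna_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  for (r in list(cfg$utr5_range, cfg$cds_range, cfg$utr3_range)) {
    if (length(r) != 2 || any(r <= 0) || r[2] < r[1])
      stop("invalid length range")
  }
  if (cfg$n_transcripts < 1) stop("n_transcripts must be >= 1")
  structure(cfg, class = "sim_config")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rand_interval <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)

#' Generate a toy transcriptome with genome placement
#'
#' Builds `n_transcripts` gene models (a configurable fraction non-coding)
#' plus one extra unmethylatable spike-in transcript with id
#' `"Dhfr_spikein"` on its own contig, emulating the in-vitro transcribed
#' conversion control. Each gene gets 1-3 exons separated by random introns
#' and is placed along a synthetic chromosome; strands alternate randomly.
#' Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with `models` (a [transcript_set()]), `reference` (named
#'   character vector of transcript sense sequences, including the spike-in)
#'   and `genome` (named character vector of chromosome sequences).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  models <- vector("list", config$n_transcripts + 1L)
  chrom_parts <- character(0)
  cursor <- 0L
  chrom <- "chrS1"
  for (i in seq_len(config$n_transcripts)) {
    ncRNA <- stats::runif(1) < config$ncrna_fraction
    if (ncRNA) {
      L <- rand_interval(config$utr5_range) + rand_interval(config$cds_range) +
        rand_interval(config$utr3_range)
      cds <- c(NA_integer_, NA_integer_)
    } else {
      u5 <- rand_interval(config$utr5_range)
      cd <- rand_interval(config$cds_range)
      u3 <- rand_interval(config$utr3_range)
      L <- u5 + cd + u3
      cds <- c(u5, u5 + cd)
    }
    seq <- rand_seq(L)
    strand <- sample(c("+", "-"), 1)
    n_exons <- sample(1:3, 1)
    # split transcript into exon pieces, then interleave introns on the genome
    cuts <- sort(sample(seq_len(L - 1L), n_exons - 1L))
    bounds <- cbind(c(0L, cuts), c(cuts, L))          # transcript space
    introns <- if (n_exons > 1) vapply(seq_len(n_exons - 1L), function(k)
      rand_seq(sample(60:200, 1)), "") else character(0)
    pieces <- substring(seq, bounds[, 1] + 1L, bounds[, 2])
    pre <- paste0(pieces[1],
                  paste0(vapply(seq_along(introns), function(k)
                    paste0(introns[k], pieces[k + 1L]), ""), collapse = ""))
    gene_start <- cursor + 500L
    # exon intervals within the pre-mRNA block, transcript order
    w <- bounds[, 2] - bounds[, 1]
    iw <- if (n_exons > 1) nchar(introns) else integer(0)
    pre_starts <- cumsum(c(0L, w[-n_exons] + iw))
    ex_pre <- cbind(pre_starts, pre_starts + w)       # 0-based within pre
    Lpre <- nchar(pre)
    if (strand == "+") {
      block <- pre
      exons <- ex_pre + gene_start
    } else {
      block <- revcomp(pre)
      exons <- cbind(Lpre - ex_pre[, 2], Lpre - ex_pre[, 1]) + gene_start
    }
    chrom_parts <- c(chrom_parts, rand_seq(500L), block)
    cursor <- gene_start + Lpre
    models[[i]] <- transcript_model(
      sprintf("tx%03d", i), sprintf("gene%03d", i), chrom, strand, exons, seq,
      cds_start = cds[1], cds_end = cds[2])
  }
  genome <- c(paste0(chrom_parts, collapse = ""))
  names(genome) <- chrom
  # unmethylated spike-in control on its own contig
  spike_seq <- rand_seq(600L)
  models[[config$n_transcripts + 1L]] <- transcript_model(
    "Dhfr_spikein", "Dhfr_spikein", "Dhfr_spikein", "+",
    cbind(0L, 600L), spike_seq, spikein = TRUE)
  genome <- c(genome, Dhfr_spikein = spike_seq)
  models <- transcript_set(models)
  reference <- vapply(models, `[[`, "", "sequence")
  list(models = models, reference = reference, genome = genome)
}

draw_stoichiometries <- function(n, d) {
  switch(d$type,
         beta = stats::rbeta(n, d$shape1, d$shape2),
         uniform = stats::runif(n, d$min, d$max),
         fixed = rep(d$value, n),
         stop("unknown stoichiometry distribution type: ", d$type))
}

#' Plant m5C sites with known stoichiometries
#'
#' Chooses `n_planted_sites` cytosine positions uniformly at random across all
#' non-spike-in transcripts and assigns each a stoichiometry drawn from the
#' configured distribution. The spike-in never receives a site.
#'
#' @param models a [transcript_set()].
#' @param config a [sim_config()].
#' @return data.frame of class `truth_table` with columns transcript_id, tpos
#'   (0-based), gpos (1-based genomic), chrom, strand, stoichiometry.
#' @export
plant_m5c_sites <- function(models, config) {
  set.seed(config$seed + 1L)
  cand <- do.call(rbind, lapply(models, function(m) {
    if (m$spikein) return(NULL)
    cpos <- which(strsplit(m$sequence, "")[[1]] == "C") - 1L
    if (!length(cpos)) return(NULL)
    data.frame(transcript_id = m$transcript_id, tpos = cpos)
  }))
  n <- config$n_planted_sites
  if (n == 0L) {
    cand <- data.frame(transcript_id = character(), tpos = integer())
  } else {
    if (is.null(cand) || nrow(cand) < n)
      stop("requested ", n, " sites but only ",
           if (is.null(cand)) 0 else nrow(cand), " cytosines available")
    cand <- cand[sort(sample(nrow(cand), n)), , drop = FALSE]
  }
  s <- draw_stoichiometries(nrow(cand), config$stoichiometry)
  s <- pmin(pmax(s, 1e-6), 1)   # 0 < stoichiometry <= 1
  truth <- data.frame(transcript_id = as.character(cand$transcript_id),
                      tpos = cand$tpos,
                      gpos = integer(nrow(cand)),
                      chrom = character(nrow(cand)),
                      strand = character(nrow(cand)),
                      stoichiometry = s, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(truth))) {
    m <- models[[truth$transcript_id[i]]]
    truth$gpos[i] <- project_to_genome(m, truth$tpos[i])
    truth$chrom[i] <- m$chrom
    truth$strand[i] <- m$strand
  }
  rownames(truth) <- NULL
  class(truth) <- c("truth_table", "data.frame")
  truth
}

#' Simulate strand-specific paired bisulfite reads
#'
#' Fragments are drawn from the sense strand with uniform starts; read 1
#' reports the (converted) sense sequence, read 2 its reverse complement.
#' Read names encode `transcript:start-end:frag<k>` (0-based half-open
#' fragment coordinates) for oracle tests. Quality strings are constant.
#'
#' @param models a [transcript_set()].
#' @param truth a `truth_table` from [plant_m5c_sites()].
#' @param config a [sim_config()].
#' @return list with `read1`, `read2` (named character vectors of sequences)
#'   of class `bisseq_reads`.
#' @export
simulate_bisseq_reads <- function(models, truth, config) {
  if (config$depth <= 0) stop("depth must be > 0")
  set.seed(config$seed + 2L)
  rl <- config$read_len
  r1 <- list(); r2 <- list(); nm <- list()
  bases <- c("A", "C", "G", "T")
  for (m in models) {
    L <- nchar(m$sequence)
    if (L < rl) stop("transcript ", m$transcript_id,
                     " shorter than read length")
    chars <- strsplit(m$sequence, "")[[1]]
    is_c <- chars == "C"
    site_rows <- truth$transcript_id == m$transcript_id
    site_pos <- truth$tpos[site_rows] + 1L   # 1-based vector index
    site_s <- truth$stoichiometry[site_rows]
    n_frag <- max(1L, as.integer(round(config$depth * L / rl)))
    flen <- as.integer(round(stats::rnorm(n_frag, config$fragment_len_mean,
                                          config$fragment_len_sd)))
    flen <- pmin(pmax(flen, rl), L)
    fstart <- vapply(flen, function(fl)
      if (L == fl) 0L else sample.int(L - fl, 1L) - 1L, 0L)  # 0-based
    seqs1 <- character(n_frag); seqs2 <- character(n_frag)
    names_ <- character(n_frag)
    for (k in seq_len(n_frag)) {
      idx <- (fstart[k] + 1L):(fstart[k] + flen[k])
      frag <- chars[idx]
      meth <- logical(flen[k])
      hit <- site_pos >= idx[1] & site_pos <= idx[length(idx)]
      if (any(hit)) {
        rel <- site_pos[hit] - fstart[k]
        meth[rel] <- stats::runif(sum(hit)) < site_s[hit]
      }
      cpos <- which(is_c[idx])
      if (length(cpos)) {
        p <- ifelse(meth[cpos], config$p_convert_methylated,
                    config$p_convert_unmethylated)
        conv <- stats::runif(length(cpos)) < p
        frag[cpos[conv]] <- "T"
      }
      s1 <- frag[seq_len(rl)]
      s2 <- frag[(flen[k] - rl + 1L):flen[k]]
      if (config$seq_error_rate > 0) {
        for (sv in c("s1", "s2")) {
          v <- get(sv)
          err <- which(stats::runif(rl) < config$seq_error_rate)
          for (e in err) v[e] <- sample(setdiff(bases, v[e]), 1L)
          assign(sv, v)
        }
      }
      seqs1[k] <- paste0(s1, collapse = "")
      seqs2[k] <- paste0(s2, collapse = "")   # revcomp'd in batch below
      names_[k] <- sprintf("%s:%d-%d:frag%d", m$transcript_id, fstart[k],
                           fstart[k] + flen[k], k)
    }
    r1[[m$transcript_id]] <- seqs1
    r2[[m$transcript_id]] <- revcomp(seqs2)
    nm[[m$transcript_id]] <- names_
  }
  read1 <- unlist(r1, use.names = FALSE)
  read2 <- unlist(r2, use.names = FALSE)
  names(read1) <- names(read2) <- unlist(nm, use.names = FALSE)
  structure(list(read1 = read1, read2 = read2), class = "bisseq_reads")
}

#' @export
print.bisseq_reads <- function(x, ...) {
  cat(sprintf("<bisseq_reads> %d read pairs, %d nt\n",
              length(x$read1), nchar(x$read1[1])))
  invisible(x)
}

#' Write simulation outputs to a directory
#'
#' Writes `reference.fa` (transcript sequences), `genome.fa`, `annotation.tsv`
#' (BED12-like), `truth.tsv`, and gzip-free `reads_1.fastq` / `reads_2.fastq`.
#'
#' @param sim output of [run_simulation()] or the individual pieces.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$reference),
                              file.path(dir, "reference.fa"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              file.path(dir, "genome.fa"))
  write_annotation(sim$models, file.path(dir, "annotation.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fastq(sim$reads$read1, file.path(dir, "reads_1.fastq"))
  write_fastq(sim$reads$read2, file.path(dir, "reads_2.fastq"))
  invisible(dir)
}

#' @noRd
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    strrep("I", n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#' @param path FASTQ path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Run the full simulation
#'
#' Convenience wrapper: [generate_transcriptome()], [plant_m5c_sites()],
#' [simulate_bisseq_reads()].
#'
#' @param config a [sim_config()].
#' @return list with models, reference, genome, truth, reads.
#' @export
run_simulation <- function(config = sim_config()) {
  tr <- generate_transcriptome(config)
  truth <- plant_m5c_sites(tr$models, config)
  reads <- simulate_bisseq_reads(tr$models, truth, config)
  c(tr, list(truth = truth, reads = reads))
}
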