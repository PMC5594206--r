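#' Classify a site into an mRNA region
#'
#' Exonic transcript positions are classified against the CDS offsets
#' (half-open: the base at `cds_start` is the first CDS base); transcripts
#' without a CDS are `ncRNA`. A genomic position inside the gene span but
#' outside all exons is an `intron`.
#'
#' @param model a [transcript_model()].
#' @param tpos 0-based transcript offset (exonic query), or
#' @param gpos 1-based genomic position (may fall in an intron).
#' @return one of `"5UTR"`, `"CDS"`, `"intron"`, `"3UTR"`, `"ncRNA"`.
#' @export
classify_region <- function(model, tpos = NULL, gpos = NULL) {
  if (is.null(tpos)) {
    span <- gene_span(model)
    if (gpos < span[1] + 1L || gpos > span[2])
      stop("position ", gpos, " outside gene span of ", model$transcript_id)
    exonic <- any(gpos >= model$exons[, 1] + 1L & gpos <= model$exons[, 2])
    if (!exonic) return("intron")
    tpos <- unproject_from_genome(model, gpos)
  }
  if (tpos < 0L || tpos >= nchar(model$sequence))
    stop("tpos out of range for ", model$transcript_id)
  if (is.na(model$cds_start)) return("ncRNA")
  if (tpos < model$cds_start) "5UTR"
  else if (tpos < model$cds_end) "CDS"
  else "3UTR"
}

#' Classify the sequence context of a cytosine
#'
#' Contexts are defined on the transcript sense strand from the two bases
#' downstream of the site: next base G gives CG; else next-next base G gives
#' CHG; else CHH (H = A, C, or T in DNA space). At transcript ends the
#' downstream bases are taken from the genome when available; otherwise the
#' context is `"NA"` and the site is excluded from context summaries.
#'
#' @param model a [transcript_model()].
#' @param tpos 0-based transcript offset of a cytosine.
#' @param genome optional named character vector of chromosome sequences for
#'   the transcript-end fallback.
#' @return `"CG"`, `"CHG"`, `"CHH"` or `"NA"`.
#' @export
classify_context <- function(model, tpos, genome = NULL) {
  L <- nchar(model$sequence)
  down <- substr(model$sequence, tpos + 2L, tpos + 3L)
  if (nchar(down) < 2L && !is.null(genome)) {
    down <- paste0(down, genomic_downstream(model, 2L - nchar(down), genome))
  }
  if (nchar(down) < 2L) return("NA")
  b1 <- substr(down, 1L, 1L); b2 <- substr(down, 2L, 2L)
  if (b1 == "G") "CG" else if (b2 == "G") "CHG" else "CHH"
}

# sense-strand bases immediately 3' of the transcript's last base
genomic_downstream <- function(model, n, genome) {
  chrom <- as.character(genome[[model$chrom]])
  last <- model$exons[nrow(model$exons), ]
  if (model$strand == "+") {
    s <- substr(chrom, last[2] + 1L, last[2] + n)
    s
  } else {
    s <- substr(chrom, max(1L, last[1] - n + 1L), last[1])
    if (nzchar(s)) revcomp(s) else s
  }
}

context_of_strings <- function(seqs) {
  # vectorized context tally over whole sequences; returns counts
  counts <- c(CG = 0, CHG = 0, CHH = 0)
  for (s in seqs) {
    chars <- strsplit(s, "")[[1]]
    L <- length(chars)
    cpos <- which(chars == "C")
    cpos <- cpos[cpos <= L - 2L]          # need two downstream bases
    if (!length(cpos)) next
    b1 <- chars[cpos + 1L]; b2 <- chars[cpos + 2L]
    ctx <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
    t <- table(factor(ctx, levels = names(counts)))
    counts <- counts + as.numeric(t)
  }
  counts
}

#' Transcriptome-wide context proportions
#'
#' Classifies every cytosine in every distinct transcript sequence and returns
#' the fractions of CG/CHG/CHH, the background against which observed m5C
#' context counts are normalized.
#'
#' @param models a [transcript_set()] (spike-in excluded).
#' @return named numeric vector of fractions summing to 1.
#' @export
transcriptome_context_proportions <- function(models) {
  if (!length(models)) stop("no transcripts")
  seqs <- unique(vapply(models[!vapply(models, `[[`, TRUE, "spikein")],
                        `[[`, "", "sequence"))
  counts <- context_of_strings(seqs)
  counts / sum(counts)
}

#' Normalize context counts by transcriptome proportions
#'
#' Observed m5C counts per context are divided by the transcriptome proportion
#' of that context and renormalized to fractions:
#' normalized_k = (n_k / p_k) / sum_m (n_m / p_m).
#'
#' @param raw_counts named numeric vector of m5C counts per context
#'   (CG, CHG, CHH).
#' @param proportions transcriptome context proportions (same names).
#' @return list of class `context_summary` with `raw_counts`,
#'   `transcriptome_proportions`, `normalized_fractions`.
#' @export
normalize_context_counts <- function(raw_counts, proportions) {
  ctx <- c("CG", "CHG", "CHH")
  raw_counts <- raw_counts[ctx]; proportions <- proportions[ctx]
  if (any(proportions == 0 & raw_counts > 0))
    stop("context with zero transcriptome proportion but nonzero count")
  ratio <- ifelse(raw_counts == 0, 0, raw_counts / proportions)
  structure(list(raw_counts = raw_counts,
                 transcriptome_proportions = proportions,
                 normalized_fractions = ratio / sum(ratio)),
            class = "context_summary")
}

#' @export
print.context_summary <- function(x, ...) {
  cat("<context_summary>\n")
  print(rbind(count = x$raw_counts,
              background = round(x$transcriptome_proportions, 4),
              normalized = round(x$normalized_fractions, 4)))
  invisible(x)
}

#' Context summary of a site table
#'
#' @param sites a `site_table` (rows with context `"NA"` are excluded).
#' @param models a [transcript_set()].
#' @return a [normalize_context_counts()] summary.
#' @export
context_summary <- function(sites, models) {
  ctx <- sites$context[sites$context %in% c("CG", "CHG", "CHH")]
  raw <- table(factor(ctx, levels = c("CG", "CHG", "CHH")))
  normalize_context_counts(stats::setNames(as.numeric(raw), names(raw)),
                           transcriptome_context_proportions(models))
}

#' Extract 21-nt flanks around sites as a position frequency matrix
#'
#' Windows of `2*halfwidth + 1` nt centred on each site are extracted from the
#' transcript sense strand, padded with N where transcript ends intrude; N is
#' excluded from column tallies. The centre column is 100% C by construction.
#'
#' @param sites a `site_table` (needs transcript_id, tpos).
#' @param models a [transcript_set()].
#' @param halfwidth flank size on each side (default 10, i.e. 21-nt windows).
#' @return matrix of base fractions, `2*halfwidth+1` rows (positions
#'   -halfwidth..halfwidth) by 4 columns (A, C, G, T); each row sums to 1 over
#'   non-N observations. Empty site set gives a 0-row matrix.
#' @export
extract_flanks <- function(sites, models, halfwidth = 10L) {
  w <- 2L * halfwidth + 1L
  if (!nrow(sites))
    return(matrix(numeric(0), nrow = 0, ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T"))))
  counts <- matrix(0, nrow = w, ncol = 4,
                   dimnames = list(as.character(-halfwidth:halfwidth),
                                   c("A", "C", "G", "T")))
  for (k in seq_len(nrow(sites))) {
    m <- models[[sites$transcript_id[k]]]
    L <- nchar(m$sequence)
    pos <- sites$tpos[k] + 1L                      # 1-based centre
    idx <- (pos - halfwidth):(pos + halfwidth)
    chars <- rep("N", w)
    ok <- idx >= 1L & idx <= L
    chars[ok] <- strsplit(substr(m$sequence, max(1L, pos - halfwidth),
                                 min(L, pos + halfwidth)), "")[[1]]
    for (p in seq_len(w)) {
      b <- chars[p]
      if (b %in% colnames(counts)) counts[p, b] <- counts[p, b] + 1
    }
  }
  rs <- rowSums(counts)
  sweep(counts, 1, ifelse(rs == 0, 1, rs), "/")
}

region_offsets <- function(model, tpos) {
  # returns region, 0-based offset within region, region length
  L <- nchar(model$sequence)
  cs <- model$cds_start; ce <- model$cds_end
  if (tpos < cs) list(region = "5UTR", off = tpos, len = cs)
  else if (tpos < ce) list(region = "CDS", off = tpos - cs, len = ce - cs)
  else list(region = "3UTR", off = tpos - ce, len = L - ce)
}

#' Metagene profile over 5'UTR / CDS / 3'UTR percentile bins
#'
#' Each site on a CDS-bearing mRNA is converted to a position within its
#' region, divided by the region length and multiplied by 100 to give a
#' percentile bin (floor, clamped to bin 99). Bin counts are reported as
#' percentages of the total profiled sites and smoothed with a centred moving
#' average (mass-preserving via edge replication).
#'
#' @param sites a `site_table` (needs transcript_id, tpos).
#' @param models a [transcript_set()].
#' @param n_bins bins per region (default 100).
#' @param smooth_window moving-average window in bins (odd, default 3).
#' @return data.frame of class `metagene_profile` with columns region, bin,
#'   count, pct, smoothed; attribute `n_skipped` counts sites on zero-length
#'   regions.
#' @export
metagene_profile <- function(sites, models, n_bins = 100L,
                             smooth_window = 3L) {
  regions <- c("5UTR", "CDS", "3UTR")
  counts <- matrix(0L, nrow = n_bins, ncol = 3,
                   dimnames = list(NULL, regions))
  skipped <- 0L
  for (k in seq_len(nrow(sites))) {
    m <- models[[sites$transcript_id[k]]]
    if (is.na(m$cds_start) || m$spikein) next
    ro <- region_offsets(m, sites$tpos[k])
    if (ro$len == 0L) { skipped <- skipped + 1L; next }
    bin <- min(floor(ro$off / ro$len * n_bins), n_bins - 1L)
    counts[bin + 1L, ro$region] <- counts[bin + 1L, ro$region] + 1L
  }
  if (skipped) warning(skipped, " site(s) on zero-length regions skipped")
  total <- sum(counts)
  flat <- as.vector(counts)                       # 5UTR bins, CDS, 3UTR
  pct <- if (total > 0) flat / total * 100 else flat
  out <- data.frame(region = rep(regions, each = n_bins),
                    bin = rep(seq_len(n_bins) - 1L, 3),
                    count = flat, pct = pct,
                    smoothed = moving_average(pct, smooth_window))
  attr(out, "n_skipped") <- skipped
  attr(out, "window") <- smooth_window
  class(out) <- c("metagene_profile", "data.frame")
  out
}

# centred moving average with edge replication; preserves total mass exactly
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  h <- (window - 1L) %/% 2L
  padded <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(padded, rep(1 / window, window),
                           sides = 2))[(h + 1L):(h + length(x))]
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d sites over %d bins (%d skipped)\n",
              sum(x$count), nrow(x), attr(x, "n_skipped")))
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  n <- nrow(x) / 3
  plot(seq_len(nrow(x)), x$smoothed, type = "l",
       xlab = "5'UTR | CDS | 3'UTR (percentile bins)",
       ylab = "% of m5C sites (smoothed)", xaxt = "n", ...)
  graphics::abline(v = c(n, 2 * n) + 0.5, lty = 2, col = "grey")
  graphics::axis(1, at = c(n / 2, 1.5 * n, 2.5 * n),
                 labels = c("5'UTR", "CDS", "3'UTR"))
  invisible(x)
}

#' Histogram of CDS sites by distance from the translation start
#'
#' @param sites a `site_table`.
#' @param models a [transcript_set()].
#' @param max_offset largest distance (nt) retained.
#' @return data.frame with columns distance (0-based nt from CDS start) and
#'   count, covering 0..max_offset.
#' @export
cds_positional_histogram <- function(sites, models, max_offset = 500L) {
  counts <- integer(max_offset + 1L)
  for (k in seq_len(nrow(sites))) {
    m <- models[[sites$transcript_id[k]]]
    if (is.na(m$cds_start)) next
    tp <- sites$tpos[k]
    if (tp < m$cds_start || tp >= m$cds_end) next
    d <- tp - m$cds_start
    if (d <= max_offset) counts[d + 1L] <- counts[d + 1L] + 1L
  }
  data.frame(distance = 0:max_offset, count = counts)
}

#' Background metagene profile over all cytosines
#'
#' The metagene profile computed for every cytosine of every CDS-bearing mRNA,
#' the control against which m5C positional enrichment is judged.
#'
#' @param models a [transcript_set()].
#' @param n_bins,smooth_window as in [metagene_profile()].
#' @return a `metagene_profile`.
#' @export
background_c_profile <- function(models, n_bins = 100L, smooth_window = 3L) {
  rows <- lapply(models, function(m) {
    if (is.na(m$cds_start) || m$spikein) return(NULL)
    cpos <- which(strsplit(m$sequence, "")[[1]] == "C") - 1L
    if (!length(cpos)) return(NULL)
    data.frame(transcript_id = m$transcript_id, tpos = cpos)
  })
  allc <- do.call(rbind, rows)
  metagene_profile(allc, models, n_bins, smooth_window)
}
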