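#' Caller configuration
#'
#' Hard credibility gates for m5C site calling. Defaults follow the standard
#' RNA-BisSeq practice: reads with more than 30% unconverted cytosines are
#' discarded as incompletely converted; a site is credible only with coverage
#' depth >= 30, methylation level >= 0.1 and methylated-cytosine depth >= 5;
#' the library passes QC only if the spike-in global conversion rate exceeds
#' 99.6%.
#'
#' @param max_unconverted_read_frac read-level filter threshold (strict `>`).
#' @param min_coverage minimum i+j at a site.
#' @param min_level minimum methylation level i/(i+j).
#' @param min_methylated_depth minimum methylated read count i.
#' @param min_conversion_rate spike-in conversion QC gate (strict `>`).
#' @param merge_level how replicate-merged levels are reported: `"mean"` of
#'   the two replicate levels (default) or `"pooled"` counts.
#' @return list of class `caller_config`.
#' @export
caller_config <- function(max_unconverted_read_frac = 0.30,
                          min_coverage = 30L,
                          min_level = 0.10,
                          min_methylated_depth = 5L,
                          min_conversion_rate = 0.996,
                          merge_level = c("mean", "pooled")) {
  fr <- c(max_unconverted_read_frac, min_level, min_conversion_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]")
  structure(list(max_unconverted_read_frac = max_unconverted_read_frac,
                 min_coverage = as.integer(min_coverage),
                 min_level = min_level,
                 min_methylated_depth = as.integer(min_methylated_depth),
                 min_conversion_rate = min_conversion_rate,
                 merge_level = match.arg(merge_level)),
            class = "caller_config")
}

#' Filter incompletely converted reads
#'
#' A read is removed iff its fraction of unconverted cytosines (read shows C
#' at a reference-C position) over all reference Cs in its window exceeds
#' `max_unconverted_read_frac` (strict inequality: exactly 30% is kept).
#' Reads covering zero reference Cs are kept (0/0 treated as 0). The filter
#' runs before any site is known, so genuinely methylated positions count as
#' unconverted here.
#'
#' @param aln a `bisseq_alignments` object.
#' @param config a [caller_config()].
#' @return list with `alignments` (filtered `bisseq_alignments`) and
#'   `n_removed`.
#' @export
filter_reads <- function(aln, config = caller_config()) {
  a <- aln$alignments
  frac <- ifelse(a$c_total == 0L, 0, a$c_unconverted / a$c_total)
  keep <- frac <= config$max_unconverted_read_frac
  out <- aln
  out$alignments <- a[keep, , drop = FALSE]
  out$observations <-
    aln$observations[aln$observations$read_id %in% a$read_id[keep], ,
                     drop = FALSE]
  list(alignments = out, n_removed = sum(!keep))
}

#' Build per-cytosine pileups
#'
#' Counts, at every reference cytosine covered by at least one kept read, the
#' number of reads showing C (`i`, methylated), T (`j`, unmethylated) and any
#' other base (`other`, sequencing error; excluded from i and j).
#'
#' @param aln a `bisseq_alignments` object (after [filter_reads()]).
#' @param reference named character vector of reference sequences, used for an
#'   integrity check on positions.
#' @return data.frame of class `site_pileup` with columns transcript_id, tpos,
#'   i, j, other.
#' @export
build_pileup <- function(aln, reference = NULL) {
  obs <- aln$observations
  if (!is.null(reference) && nrow(aln$alignments)) {
    ends <- aln$alignments$tpos + aln$alignments$length
    lens <- nchar(reference)[aln$alignments$transcript_id]
    if (any(ends > lens)) stop("alignment extends beyond transcript end")
  }
  if (!nrow(obs)) {
    out <- data.frame(transcript_id = character(), tpos = integer(),
                      i = integer(), j = integer(), other = integer())
    class(out) <- c("site_pileup", "data.frame")
    return(out)
  }
  dt <- data.table::as.data.table(obs)
  pil <- dt[, list(i = sum(read_base == "C"),
                   j = sum(read_base == "T"),
                   other = sum(!read_base %in% c("C", "T"))),
            by = c("transcript_id", "tpos")]
  data.table::setorder(pil, transcript_id, tpos)
  out <- as.data.frame(pil)
  class(out) <- c("site_pileup", "data.frame")
  out
}

#' Spike-in conversion QC
#'
#' Global conversion rate from the unmethylated spike-in: total T observations
#' over total (C+T) observations at spike-in reference cytosines. The library
#' passes iff the rate strictly exceeds `min_conversion_rate`.
#'
#' @param pileup a `site_pileup` (full, or already restricted to the
#'   spike-in).
#' @param config a [caller_config()].
#' @param spikein_id transcript id of the spike-in control.
#' @return list of class `conversion_report` with fields
#'   `total_spikein_c_observations`, `converted`, `rate`, `passed`.
#' @export
conversion_qc <- function(pileup, config = caller_config(),
                          spikein_id = "Dhfr_spikein") {
  sp <- pileup[pileup$transcript_id == spikein_id, , drop = FALSE]
  total <- sum(sp$i + sp$j)
  if (total == 0L) stop("no spike-in observations for ", spikein_id)
  converted <- sum(sp$j)
  rate <- converted / total
  structure(list(total_spikein_c_observations = total,
                 converted = converted, rate = rate,
                 passed = rate > config$min_conversion_rate,
                 threshold = config$min_conversion_rate),
            class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat(sprintf(paste0("<conversion_report> %d/%d C-to-T converted ",
                     "(rate %.4f, gate > %.3f): %s\n"),
              x$converted, x$total_spikein_c_observations, x$rate,
              x$threshold, if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Call credible m5C sites
#'
#' Applies the three credibility gates (coverage depth >= `min_coverage`,
#' level >= `min_level`, methylated depth >= `min_methylated_depth`) to a
#' pileup, where level = i/(i+j) ignoring other-base observations, and
#' projects each site to genome coordinates. The spike-in is never reported as
#' a site. Refuses to run when the conversion QC failed unless `force = TRUE`.
#'
#' @param pileup a `site_pileup`.
#' @param models a [transcript_set()] (for projection and annotation).
#' @param config a [caller_config()].
#' @param qc optional [conversion_qc()] report; if failed, `force` is
#'   required.
#' @param force emit sites despite failed conversion QC.
#' @return a `site_table` data.frame with columns chrom, pos (1-based),
#'   strand, gene_id, transcript_id, tpos, coverage, methylated_depth, level,
#'   context, region.
#' @export
call_sites <- function(pileup, models, config = caller_config(), qc = NULL,
                       force = FALSE) {
  if (!is.null(qc) && !qc$passed && !force)
    stop("conversion QC failed (rate ", signif(qc$rate, 4),
         " <= ", qc$threshold, "); use force = TRUE to override")
  cov <- pileup$i + pileup$j
  lev <- ifelse(cov > 0L, pileup$i / cov, 0)
  spike <- vapply(models, `[[`, TRUE, "spikein")[pileup$transcript_id]
  keep <- cov >= config$min_coverage & lev >= config$min_level &
    pileup$i >= config$min_methylated_depth & !spike
  p <- pileup[keep, , drop = FALSE]
  n <- nrow(p)
  out <- data.frame(chrom = character(n), pos = integer(n),
                    strand = character(n), gene_id = character(n),
                    transcript_id = p$transcript_id, tpos = p$tpos,
                    coverage = p$i + p$j, methylated_depth = p$i,
                    level = p$i / (p$i + p$j),
                    context = character(n), region = character(n),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    m <- models[[p$transcript_id[k]]]
    out$chrom[k] <- m$chrom
    out$strand[k] <- m$strand
    out$gene_id[k] <- m$gene_id
    out$pos[k] <- project_to_genome(m, p$tpos[k])
    out$context[k] <- classify_context(m, p$tpos[k])
    out$region[k] <- classify_region(m, tpos = p$tpos[k])
  }
  rownames(out) <- NULL
  as_site_table(out)
}

as_site_table <- function(df) {
  class(df) <- c("site_table", "data.frame")
  df
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("<site_table> %d m5C sites on %d transcripts", nrow(x),
              length(unique(x$transcript_id))))
  if (nrow(x))
    cat(sprintf("; median level %.3f", stats::median(x$level)))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Intersect replicate site tables
#'
#' Keeps sites called in both replicates, matched on (chrom, pos, strand).
#' The reported level is the arithmetic mean of the replicate levels (or
#' pooled counts with `merge_level = "pooled"`); both replicate levels are
#' retained.
#'
#' @param a,b `site_table` replicates from the same reference/annotation.
#' @param config a [caller_config()] (for `merge_level`).
#' @return merged `site_table` with extra columns level_rep1, level_rep2.
#' @export
intersect_replicates <- function(a, b, config = caller_config()) {
  ra <- attr(a, "reference_id"); rb <- attr(b, "reference_id")
  if (!is.null(ra) && !is.null(rb) && !identical(ra, rb))
    stop("replicates come from different references: ", ra, " vs ", rb)
  key <- c("chrom", "pos", "strand")
  m <- merge(as.data.frame(a),
             as.data.frame(b)[, c(key, "coverage", "methylated_depth",
                                  "level")],
             by = key, suffixes = c("", "_rep2"))
  m$level_rep1 <- m$level
  m$level_rep2 <- m$level_rep2
  m$level <- if (config$merge_level == "mean") {
    (m$level_rep1 + m$level_rep2) / 2
  } else {
    (m$methylated_depth + m$methylated_depth_rep2) /
      (m$coverage + m$coverage_rep2)
  }
  m <- m[order(m$chrom, m$pos, m$strand), ]
  rownames(m) <- NULL
  drop <- c("coverage_rep2", "methylated_depth_rep2")
  as_site_table(m[, setdiff(names(m), drop)])
}

#' Write / read a site table TSV
#' @param sites a `site_table`.
#' @param path TSV path.
#' @return `path` / a `site_table`.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  as_site_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Export a site table as BED6 (score = level x 1000)
#' @param sites a `site_table`.
#' @param path BED path.
#' @export
write_site_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$chrom, start = sites$pos - 1L,
                    end = sites$pos,
                    name = paste0(sites$chrom, ":", sites$pos),
                    score = as.integer(round(sites$level * 1000)),
                    strand = sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
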