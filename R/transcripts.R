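#' Transcript models
#'
#' A `transcript_model` describes one mature transcript: its exon chain on the
#' genome, strand, CDS boundaries in transcript space, and its sense-strand
#' sequence (RNA written in DNA alphabet, i.e. T not U). Exons are stored as a
#' two-column integer matrix of 0-based half-open genomic intervals, ordered
#' 5'-to-3' in transcript orientation (descending genomic coordinates on the
#' minus strand). All emitted genomic positions are 1-based.
#'
#' @param transcript_id,gene_id,chrom identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of 0-based half-open genomic intervals,
#'   5'-to-3' in transcript orientation.
#' @param sequence sense-strand sequence (A/C/G/T string), same total length
#'   as the exon chain.
#' @param cds_start,cds_end transcript-space CDS boundaries (0-based
#'   half-open), or `NA` for non-coding transcripts.
#' @param spikein logical; marks the unmethylatable conversion-control
#'   transcript.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             sequence, cds_start = NA_integer_,
                             cds_end = NA_integer_, spikein = FALSE) {
  exons <- matrix(as.integer(exons), ncol = 2)
  stopifnot(strand %in% c("+", "-"), all(exons[, 2] > exons[, 1]))
  widths <- exons[, 2] - exons[, 1]
  if (sum(widths) != nchar(sequence))
    stop("exon lengths (", sum(widths), ") do not match sequence length (",
         nchar(sequence), ") for ", transcript_id)
  if (nrow(exons) > 1) {
    # non-overlapping, ordered 5'->3' in transcript orientation
    ord <- if (strand == "+") order(exons[, 1]) else order(-exons[, 1])
    if (!identical(ord, seq_len(nrow(exons))))
      stop("exons of ", transcript_id, " are not ordered 5'->3'")
    lo <- exons[order(exons[, 1]), , drop = FALSE]
    if (any(lo[-1, 1] < lo[-nrow(lo), 2]))
      stop("exons of ", transcript_id, " overlap")
  }
  if (!is.na(cds_start)) {
    if (!(cds_start >= 0 && cds_start < cds_end && cds_end <= sum(widths)))
      stop("invalid CDS boundaries for ", transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 sequence = toupper(sequence), spikein = isTRUE(spikein)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "ncRNA" else
    sprintf("CDS [%d,%d)", x$cds_start, x$cds_end)
  cat(sprintf("<transcript_model> %s (%s) %s:%s, %d exon(s), %d nt, %s%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), nchar(x$sequence), cds,
              if (x$spikein) ", spike-in" else ""))
  invisible(x)
}

#' @export
length.transcript_model <- function(x) nchar(x$sequence)

#' Collect transcript models into a set
#'
#' @param models list of [transcript_model()] objects.
#' @return A named list of class `transcript_set` (names are transcript ids).
#' @export
transcript_set <- function(models) {
  ids <- vapply(models, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript ids")
  structure(stats::setNames(models, ids), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("<transcript_set> %d transcripts (%d coding, %d spike-in)\n",
              length(x),
              sum(!vapply(x, function(m) is.na(m$cds_start), TRUE)),
              sum(vapply(x, `[[`, TRUE, "spikein"))))
  invisible(x)
}

#' @export
`[.transcript_set` <- function(x, i) {
  structure(NextMethod(), class = "transcript_set")
}

exon_widths <- function(model) model$exons[, 2] - model$exons[, 1]

#' Project a transcript-space position to the genome
#'
#' Walks the exon chain. On the minus strand transcript coordinates run
#' against the genomic axis, so positions are counted back from the high end
#' of each exon block.
#'
#' @param model a [transcript_model()].
#' @param tpos 0-based transcript offset(s).
#' @return integer vector of 1-based genomic positions.
#' @seealso [unproject_from_genome()] for the inverse.
#' @export
project_to_genome <- function(model, tpos) {
  tpos <- as.integer(tpos)
  L <- nchar(model$sequence)
  if (any(tpos < 0L | tpos >= L))
    stop("tpos out of range [0,", L, ") for ", model$transcript_id)
  cw <- cumsum(exon_widths(model))
  k <- findInterval(tpos, c(0L, cw), rightmost.closed = FALSE)
  off <- tpos - c(0L, cw)[k]
  if (model$strand == "+") model$exons[k, 1] + off + 1L
  else                     model$exons[k, 2] - off
}

#' Map a genomic position back to transcript space
#'
#' @param model a [transcript_model()].
#' @param gpos 1-based genomic position(s) that fall inside the exon chain.
#' @return 0-based transcript offset(s).
#' @export
unproject_from_genome <- function(model, gpos) {
  gpos <- as.integer(gpos)
  cw <- c(0L, cumsum(exon_widths(model)))
  out <- rep(NA_integer_, length(gpos))
  for (k in seq_len(nrow(model$exons))) {
    s <- model$exons[k, 1]; e <- model$exons[k, 2]
    hit <- gpos >= s + 1L & gpos <= e
    if (!any(hit)) next
    out[hit] <- if (model$strand == "+") cw[k] + (gpos[hit] - s - 1L)
                else                     cw[k] + (e - gpos[hit])
  }
  if (anyNA(out)) stop("genomic position outside exons of ",
                       model$transcript_id)
  out
}

#' Genomic span of a gene model
#' @noRd
gene_span <- function(model) {
  c(min(model$exons[, 1]), max(model$exons[, 2]))
}

#' Extract the spliced transcript sequence from a genome
#'
#' Used as an internal consistency check: the spliced exon sequence of a model
#' must reproduce its stored sense-strand sequence.
#'
#' @param model a [transcript_model()].
#' @param genome named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @return sense-strand sequence string.
#' @export
spliced_sequence <- function(model, genome) {
  chrom <- as.character(genome[[model$chrom]])
  ex <- model$exons[order(model$exons[, 1]), , drop = FALSE]
  pieces <- substring(chrom, ex[, 1] + 1L, ex[, 2])
  s <- paste0(pieces, collapse = "")
  if (model$strand == "-") s <- revcomp(s)
  s
}

# vectorized reverse complement on plain character vectors
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  rev_chars <- vapply(strsplit(x, "", fixed = TRUE),
                      function(ch) paste(rev(ch), collapse = ""), "")
  chartr("ACGTN", "TGCAN", rev_chars)
}

#' Write / read transcript annotation as BED12-like TSV
#'
#' Columns follow the BED12 convention: chrom, start, end (0-based half-open
#' over the whole gene span), name, score, strand, thickStart/thickEnd (CDS in
#' genomic coordinates; equal to start when non-coding), blockCount,
#' blockSizes, blockStarts (comma-separated, relative to start, in genomic
#' order). Two extra columns carry gene_id and the spike-in flag.
#'
#' @param models a [transcript_set()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- m$exons[order(m$exons[, 1]), , drop = FALSE]
    span <- gene_span(m)
    if (is.na(m$cds_start)) {
      thick <- c(span[1], span[1])
    } else {
      g1 <- project_to_genome(m, m$cds_start)
      g2 <- project_to_genome(m, m$cds_end - 1L)
      thick <- c(min(g1, g2) - 1L, max(g1, g2))
    }
    data.frame(chrom = m$chrom, start = span[1], end = span[2],
               name = m$transcript_id, score = 0L, strand = m$strand,
               thickStart = thick[1], thickEnd = thick[2],
               blockCount = nrow(ex),
               blockSizes = paste(ex[, 2] - ex[, 1], collapse = ","),
               blockStarts = paste(ex[, 1] - span[1], collapse = ","),
               gene_id = m$gene_id, spikein = m$spikein)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @param path TSV written by [write_annotation()].
#' @param reference named character vector of transcript sequences (sense
#'   strand), used to fill the `sequence` field.
#' @export
read_annotation <- function(path, reference) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    sizes <- as.integer(strsplit(r$blockSizes, ",")[[1]])
    starts <- as.integer(strsplit(r$blockStarts, ",")[[1]])
    ex <- cbind(r$start + starts, r$start + starts + sizes)
    if (r$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    seq <- reference[[r$name]]
    cds <- c(NA_integer_, NA_integer_)
    if (r$thickEnd > r$thickStart) {
      m0 <- transcript_model(r$name, r$gene_id, r$chrom, r$strand, ex, seq)
      t1 <- unproject_from_genome(m0, r$thickStart + 1L)
      t2 <- unproject_from_genome(m0, r$thickEnd)
      cds <- c(min(t1, t2), max(t1, t2) + 1L)
    }
    transcript_model(r$name, r$gene_id, r$chrom, r$strand, ex, seq,
                     cds_start = cds[1], cds_end = cds[2],
                     spikein = isTRUE(r$spikein))
  })
  transcript_set(models)
}
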