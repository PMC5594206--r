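#' Gene exon-union models as GRanges
#' @noRd
gene_exon_ranges <- function(models, chroms = NULL) {
  if (is.null(chroms))
    chroms <- unique(vapply(models, `[[`, "", "chrom"))
  parts <- lapply(models, function(m) {
    GenomicRanges::GRanges(factor(m$chrom, levels = chroms),
                           IRanges::IRanges(m$exons[, 1] + 1L, m$exons[, 2]),
                           gene_id = m$gene_id)
  })
  gr <- do.call(c, unname(parts))
  grl <- S4Vectors::split(gr, gr$gene_id)
  GenomicRanges::reduce(grl)        # union of exons per gene
}

#' Count reads per gene (union overlap mode)
#'
#' A read is counted for a gene iff its genomic projection overlaps that
#' gene's exon-union model and no other gene's; reads overlapping two genes
#' are counted for neither (union-mode ambiguity). Alignments are already
#' unique, so no mapping-quality filter is needed.
#'
#' @param aln a `bisseq_alignments` object.
#' @param models a [transcript_set()].
#' @return named integer vector of counts per gene (all genes, zeros
#'   included).
#' @export
count_reads_per_gene <- function(aln, models) {
  chroms <- unique(vapply(models, `[[`, "", "chrom"))
  genes <- gene_exon_ranges(models, chroms)
  gene_ids <- names(genes)
  counts <- stats::setNames(integer(length(gene_ids)), gene_ids)
  a <- aln$alignments
  if (!nrow(a)) return(counts)
  # project each read interval through its transcript's exon chain
  blocks <- lapply(seq_len(nrow(a)), function(i) {
    m <- models[[a$transcript_id[i]]]
    gp <- project_to_genome(m, a$tpos[i]:(a$tpos[i] + a$length[i] - 1L))
    r <- IRanges::reduce(IRanges::IRanges(gp, width = 1L))
    GenomicRanges::GRanges(factor(m$chrom, levels = chroms), r, read = i)
  })
  gr <- do.call(c, unname(blocks))
  flat <- unlist(genes)
  flat$gene_id <- rep(gene_ids, lengths(genes))
  hits <- GenomicRanges::findOverlaps(gr, flat)
  if (length(hits)) {
    df <- unique(data.frame(read = gr$read[S4Vectors::queryHits(hits)],
                            gene = flat$gene_id[S4Vectors::subjectHits(hits)]))
    ngenes <- table(df$read)
    unambig <- df[df$read %in% names(ngenes)[ngenes == 1L], ]
    t <- table(unambig$gene)
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  counts
}

#' Compute RPKM and the expressed-gene gate
#'
#' RPKM = count x 1e9 / (exon_model_length x total_mapped), with
#' exon_model_length the union of exon lengths per gene; genes with
#' RPKM >= 1 are flagged expressed.
#'
#' @param counts named vector from [count_reads_per_gene()].
#' @param models a [transcript_set()].
#' @param total_mapped total mapped reads in the library (defaults to
#'   `sum(counts)`).
#' @return data.frame of class `expression_table` with columns gene_id, count,
#'   exon_model_length, rpkm, expressed.
#' @export
compute_rpkm <- function(counts, models, total_mapped = sum(counts)) {
  if (total_mapped <= 0) stop("total_mapped must be > 0")
  genes <- gene_exon_ranges(models)
  len <- vapply(genes, function(g) sum(IRanges::width(g)), 0)
  if (any(len == 0)) stop("gene with zero exon model length")
  ids <- names(genes)
  cnt <- stats::setNames(numeric(length(ids)), ids)
  cnt[names(counts)] <- counts
  rpkm <- cnt * 1e9 / (len[ids] * total_mapped)
  out <- data.frame(gene_id = ids, count = as.integer(cnt),
                    exon_model_length = as.integer(len[ids]),
                    rpkm = rpkm, expressed = rpkm >= 1,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("expression_table", "data.frame")
  out
}
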