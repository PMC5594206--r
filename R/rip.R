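#' Read a BED peak file
#'
#' Peaks use the BED convention (0-based half-open); site positions are
#' 1-based, so a site at 1-based position g lies in a peak \[start, end) iff
#' start <= g-1 < end. Unsorted input is sorted internally with a warning.
#'
#' @param path BED file (>= 3 columns).
#' @return a [GenomicRanges::GRanges] peak set (1-based closed internally, as
#'   is the Bioconductor convention).
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.unsorted(order(as.character(GenomicRanges::seqnames(gr)),
                        GenomicRanges::start(gr)))) {
    warning("peak file not sorted; sorting internally")
  }
  GenomicRanges::sort(gr)
}

#' Peak set from a data.frame (0-based half-open intervals)
#'
#' @param df data.frame with columns chrom, start (0-based), end (half-open),
#'   and optionally name, score, strand.
#' @return a [GenomicRanges::GRanges].
#' @export
peaks_from_df <- function(df) {
  stopifnot(all(df$end > df$start))
  GenomicRanges::sort(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1L, df$end)))
}

#' Intersect m5C sites with RIP peaks
#'
#' Keeps sites falling inside any peak interval (half-open BED semantics
#' exact at the boundaries). Strand is ignored unless `stranded = TRUE` and
#' the peaks carry strand.
#'
#' @param sites a `site_table`.
#' @param peaks a [GenomicRanges::GRanges] from [read_peaks()] or
#'   [peaks_from_df()].
#' @param stranded require matching strand.
#' @return the subset `site_table` of reader-bound sites.
#' @export
intersect_sites_with_peaks <- function(sites, peaks, stranded = FALSE) {
  if (!nrow(sites)) return(sites)
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, width = 1L),
                               strand = if (stranded) sites$strand else "*")
  if (!stranded) GenomicRanges::strand(peaks) <- "*"
  hits <- IRanges::overlapsAny(gr, peaks, ignore.strand = !stranded)
  as_site_table(sites[hits, , drop = FALSE])
}

#' Compare level distributions of bound vs input sites
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test on the methylation-level
#' vectors of reader-bound and input fractions.
#'
#' @param bound,input `site_table`s (each with >= 3 sites).
#' @return list with `median_bound`, `median_input`, `statistic` (U) and
#'   `p_value`.
#' @export
compare_level_distributions <- function(bound, input) {
  if (nrow(bound) < 3L || nrow(input) < 3L)
    stop("need >= 3 sites in each group")
  wt <- stats::wilcox.test(bound$level, input$level, alternative = "two.sided",
                           exact = FALSE)
  list(median_bound = stats::median(bound$level),
       median_input = stats::median(input$level),
       statistic = unname(wt$statistic),
       p_value = wt$p.value)
}
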