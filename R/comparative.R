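site_keys <- function(sites) paste(sites$chrom, sites$pos, sites$strand,
                                   sep = ":")

#' Sample-specific m5C sites
#'
#' A site is specific to a sample iff it is present in exactly one of the
#' tables.
#'
#' @param tables named list of `site_table`s (>= 2 samples).
#' @return named list mapping each sample to its specific site keys
#'   (`"chrom:pos:strand"`).
#' @export
find_specific_sites <- function(tables) {
  if (length(tables) < 2L) stop("need >= 2 samples")
  keys <- lapply(tables, site_keys)
  all_keys <- unlist(keys, use.names = FALSE)
  once <- names(which(table(all_keys) == 1L))
  lapply(keys, function(k) sort(intersect(k, once)))
}

#' Stringent sample-specific sites
#'
#' Restricts the site universe to genes expressed (RPKM >= 1) in every sample
#' before applying [find_specific_sites()], so that sample-specificity cannot
#' be an artifact of expression dropout.
#'
#' @param tables named list of `site_table`s.
#' @param expression named list of `expression_table`s, same names.
#' @return named list of specific site keys per sample.
#' @export
find_stringent_specific <- function(tables, expression) {
  if (!all(names(tables) %in% names(expression)))
    stop("missing expression table for: ",
         paste(setdiff(names(tables), names(expression)), collapse = ", "))
  expressed_all <- Reduce(intersect, lapply(names(tables), function(s) {
    e <- expression[[s]]
    e$gene_id[e$expressed]
  }))
  restricted <- lapply(tables, function(t)
    t[t$gene_id %in% expressed_all, , drop = FALSE])
  find_specific_sites(restricted)
}

#' Classify methylation-level changes between two conditions
#'
#' Over sites common to both tables, a site is `increased` iff
#' level_b - level_a > delta, `decreased` iff the difference is below -delta,
#' and `stable` otherwise (strict inequalities: a change of exactly `delta` is
#' stable).
#'
#' @param a,b `site_table`s for the two conditions.
#' @param delta level-change threshold (default 0.05, i.e. 5%).
#' @return data.frame with columns key, level_a, level_b, delta, class.
#' @export
classify_dynamic <- function(a, b, delta = 0.05) {
  ka <- site_keys(a); kb <- site_keys(b)
  common <- intersect(ka, kb)
  la <- a$level[match(common, ka)]
  lb <- b$level[match(common, kb)]
  d <- lb - la
  cls <- ifelse(d > delta, "increased", ifelse(d < -delta, "decreased",
                                               "stable"))
  data.frame(key = common, level_a = la, level_b = lb, delta = d,
             class = cls, stringsAsFactors = FALSE)
}

#' Writer-knockdown regulated sites
#'
#' Sites of the control sample whose methylation level drops by more than
#' `delta` in the knockdown are regulated (e.g. NSUN2-dependent). A site
#' absent from the knockdown table is treated as level 0 when the knockdown
#' pileup shows adequate coverage there; with coverage below the caller's
#' minimum the site is not assessable and excluded.
#'
#' @param control `site_table` of the control sample.
#' @param kd_levels `site_table` of the knockdown, or a data.frame with
#'   chrom/pos/strand/level.
#' @param delta level-reduction threshold (strict `>`, default 0.05).
#' @param kd_pileup optional knockdown `site_pileup` plus `models` used to
#'   check coverage at control sites absent from `kd_levels`; when omitted,
#'   absent sites are assumed covered (level 0).
#' @param models a [transcript_set()] (needed with `kd_pileup`).
#' @param config a [caller_config()] (coverage gate for assessability).
#' @return character vector of regulated site keys.
#' @export
knockdown_regulated <- function(control, kd_levels, delta = 0.05,
                                kd_pileup = NULL, models = NULL,
                                config = caller_config()) {
  kc <- site_keys(control)
  kk <- site_keys(kd_levels)
  lev_kd <- kd_levels$level[match(kc, kk)]
  assessable <- rep(TRUE, length(kc))
  missing <- is.na(lev_kd)
  if (any(missing) && !is.null(kd_pileup)) {
    stopifnot(!is.null(models))
    cov <- kd_coverage_at(control[missing, , drop = FALSE], kd_pileup)
    assessable[missing] <- cov >= config$min_coverage
  }
  lev_kd[missing] <- 0
  regulated <- assessable & (control$level - lev_kd > delta)
  sort(kc[regulated])
}

kd_coverage_at <- function(sites, pileup) {
  key_p <- paste(pileup$transcript_id, pileup$tpos)
  key_s <- paste(sites$transcript_id, sites$tpos)
  cov <- (pileup$i + pileup$j)[match(key_s, key_p)]
  ifelse(is.na(cov), 0L, cov)
}

#' Build a sites-by-samples level matrix
#'
#' @param tables named list of `site_table`s.
#' @return numeric matrix, rows keyed `"chrom:pos:strand"`, one column per
#'   sample, NA where a site was not called.
#' @export
build_level_matrix <- function(tables) {
  keys <- sort(unique(unlist(lapply(tables, site_keys))))
  m <- sapply(tables, function(t) t$level[match(keys, site_keys(t))])
  rownames(m) <- keys
  m
}

#' Correlation clustering of methylation levels
#'
#' Pairwise Pearson correlation of m5C levels over pairwise-complete sites,
#' followed by agglomerative hierarchical clustering with distance 1 - r and
#' average linkage.
#'
#' @param matrix level matrix from [build_level_matrix()].
#' @param min_complete minimum pairwise-complete sites per sample pair.
#' @return list of class `m5c_clustering` with `correlation` (matrix),
#'   `hclust`, `order` (sample names in dendrogram order) and `newick`
#'   (dendrogram string).
#' @export
correlation_clustering <- function(matrix, min_complete = 3L) {
  if (ncol(matrix) < 2L) stop("need >= 2 samples")
  sds <- apply(matrix, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0))
    stop("constant or empty level column: ",
         paste(colnames(matrix)[is.na(sds) | sds == 0], collapse = ", "))
  n <- ncol(matrix)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (sum(stats::complete.cases(matrix[, c(i, j)])) < min_complete)
      stop("fewer than ", min_complete, " pairwise-complete sites for ",
           colnames(matrix)[i], " vs ", colnames(matrix)[j])
  }
  r <- stats::cor(matrix, use = "pairwise.complete.obs", method = "pearson")
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  phy <- ape::as.phylo(hc)
  structure(list(correlation = r, hclust = hc,
                 order = colnames(matrix)[hc$order],
                 newick = ape::write.tree(phy)),
            class = "m5c_clustering")
}

#' @export
print.m5c_clustering <- function(x, ...) {
  cat("<m5c_clustering> order:", paste(x$order, collapse = " - "), "\n")
  print(round(x$correlation, 3))
  invisible(x)
}

#' @export
plot.m5c_clustering <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", main = "1 - Pearson r, average linkage",
       ...)
  invisible(x)
}
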