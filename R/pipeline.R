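#' Call m5C sites from simulated or provided reads
#'
#' One-sample driver: align, filter incompletely converted reads, pile up,
#' run spike-in conversion QC and call credible sites.
#'
#' @param index a [build_converted_index()] object.
#' @param read1,read2 read vectors or FASTQ paths.
#' @param models a [transcript_set()].
#' @param config a [caller_config()].
#' @param force emit sites despite failed conversion QC.
#' @return list with `alignments`, `n_removed`, `pileup`, `qc`, `sites`.
#' @export
call_sample <- function(index, read1, read2, models,
                        config = caller_config(), force = FALSE) {
  aln <- align_reads(index, read1, read2)
  filt <- filter_reads(aln, config)
  pileup <- build_pileup(filt$alignments,
                         vapply(models, `[[`, "", "sequence"))
  qc <- conversion_qc(pileup, config)
  sites <- call_sites(pileup, models, config, qc = qc, force = force)
  list(alignments = filt$alignments, n_removed = filt$n_removed,
       pileup = pileup, qc = qc, sites = sites)
}

#' Run the full pipeline end-to-end
#'
#' Simulates a transcriptome and bisulfite reads, aligns, calls sites, and
#' writes every artifact (reference, genome, annotation, truth, FASTQ,
#' alignments, pileup, conversion report, site table, metagene profile,
#' context summary, flank PFM, expression table) under `outdir`. Re-running
#' with the same configuration reproduces byte-identical outputs.
#'
#' @param sim_cfg a [sim_config()].
#' @param caller_cfg a [caller_config()].
#' @param outdir output directory.
#' @param force emit sites despite failed conversion QC.
#' @return (invisibly) list with the in-memory results.
#' @export
run_pipeline <- function(sim_cfg = sim_config(),
                         caller_cfg = caller_config(),
                         outdir, force = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- run_simulation(sim_cfg)
  write_simulation(sim, outdir)
  index <- build_converted_index(sim$reference)
  res <- call_sample(index, sim$reads$read1, sim$reads$read2, sim$models,
                     caller_cfg, force = force)
  write_alignments(res$alignments, file.path(outdir, "alignments.tsv"))
  utils::write.table(res$pileup, file.path(outdir, "pileup.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("total\t%d\nconverted\t%d\nrate\t%.6f\npassed\t%s",
                     res$qc$total_spikein_c_observations, res$qc$converted,
                     res$qc$rate, res$qc$passed),
             file.path(outdir, "conversion_report.tsv"))
  write_site_table(res$sites, file.path(outdir, "sites.tsv"))
  prof <- metagene_profile(res$sites, sim$models)
  utils::write.table(as.data.frame(prof), file.path(outdir, "metagene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(res$sites)) {
    ctx <- context_summary(res$sites, sim$models)
    utils::write.table(
      data.frame(context = c("CG", "CHG", "CHH"),
                 count = as.numeric(ctx$raw_counts),
                 background = as.numeric(ctx$transcriptome_proportions),
                 normalized = as.numeric(ctx$normalized_fractions)),
      file.path(outdir, "context.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    pfm <- extract_flanks(res$sites, sim$models)
    utils::write.table(cbind(position = rownames(pfm), as.data.frame(pfm)),
                       file.path(outdir, "flank_pfm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  counts <- count_reads_per_gene(res$alignments, sim$models)
  expr <- compute_rpkm(counts, sim$models)
  utils::write.table(as.data.frame(expr), file.path(outdir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(sim = sim, index = index, result = res, expression = expr))
}
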