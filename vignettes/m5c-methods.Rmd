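---
title: "Models and methods behind m5cpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind m5cpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m5cpipe)
```

# The measurement model

RNA bisulfite sequencing estimates, for every transcript cytosine, the
fraction of molecules carrying 5-methylcytosine. The package models the
chemistry per fragment molecule:

- a cytosine planted as an m⁵C site with stoichiometry $s$ is methylated on
  any given molecule with probability $s$;
- an unmethylated cytosine is deaminated and read as T with probability
  $p_\mathrm{conv}$ (default 0.999, near-complete conversion);
- a methylated cytosine is (mis)converted with probability
  $p_\mathrm{conv,m}$ (default 0);
- each sequenced base is then substituted uniformly at random with
  probability $e$ (default 0.001).

At a site of stoichiometry $s$, the probability that an aligned read shows C
is therefore approximately

$$ P(\mathrm{C}) \;=\; s + (1 - s)\,(1 - p_\mathrm{conv}), $$

up to a sequencing-error term of order $e$. The methylation level reported
for a site, $i/(i+j)$ with $i$ reads showing C and $j$ showing T, is the
binomial estimate of this quantity; bases other than C or T at a reference
cytosine (sequencing errors) are counted separately and excluded from both
$i$ and $j$, since the chemistry model gives them no interpretation.

# The simulator: what it emulates, and what it does not

`sim_config()` fixes the study conditions. Defaults: strand-specific paired
125-bp reads from ~200-nt fragments (SD 20 nt), as produced by a stranded
poly(A) library on a 125-bp paired-end sequencer; mean read-1 fold-coverage
50×; conversion 99.9%; sequencing-error rate 0.1%; a toy transcriptome of 20
genes with 5′UTR/CDS/3′UTR length ranges 80–150/240–450/120–250 nt, 10%
non-coding, 1–3 exons per gene placed with random introns on a synthetic
chromosome; and one extra unmethylatable 600-nt spike-in transcript
(`Dhfr_spikein`) on its own contig, standing in for the in-vitro transcribed
Dhfr conversion control (the spike-in sequence is synthetic, not the real
gene). RNA is represented with T rather than U throughout, because the
sequenced molecules are cDNA.

Planted stoichiometries default to Beta(1.5, 5), whose median is near 0.2 —
the typical bulk of mRNA m⁵C levels, where most sites sit below 40% with a
median around 20%. The true distribution in any real sample is unknown; the
Beta default is a modeling choice, and uniform or fixed distributions are
available for calibration experiments.

Deliberate simplifications:

- fragment starts are uniform; the ACT-hexamer priming bias of real
  libraries (hexamers devoid of G, which under-copy poorly deaminated
  templates) is not modeled, because it suppresses an artifact — incomplete
  conversion of structured RNA — that the simulator does not create;
- only the sense strand is sequenced (read 1 sense, read 2 its reverse
  complement), as in a stranded poly(A) protocol;
- quality strings are constant; trimming is out of scope;
- no intron-retaining pre-mRNA reads, no hm⁵C, no RT-priming bias.

Passing tests on simulated data therefore validate the *inference machinery*
(alignment, filtering, counting, gating, projection) against a known truth;
they do not validate robustness to structure-driven conversion failure,
coverage biases, or annotation errors found in real libraries.

# Alignment in three-letter space

Bisulfite conversion collapses C onto T, so alignment operates on
C→T-converted reads against a C→T-converted reference
(`build_converted_index()`). Design choices:

- **transcriptome-space alignment.** Reads are simulated from mature
  transcripts, so the genome-first cascade with an exon–exon junction
  library used for real genome-wide data is unnecessary; the aligner works
  directly in transcript coordinates and sites are projected to the genome
  afterwards through the exon chain. This is a deliberate deviation from the
  genome-first strategy, valid exactly because no reads span unannotated
  junctions here.
- **seeding and verification.** A 25-nt exact seed in converted space (the
  analogue of a zero-mismatch seed policy) proposes loci; the full read is
  verified in converted space allowing ≤ 2 mismatches. Mismatches in
  converted space cannot be methylation differences — those are invisible by
  construction — so they correspond to sequencing errors.
- **uniqueness or rejection.** If two distinct loci tie at the best
  mismatch count the read is discarded as ambiguous; multi-mappers are never
  emitted. Reads whose seed contains a sequencing error go unmapped
  (~2.5% at $e = 0.001$) rather than being rescued by additional seeds; this
  costs coverage, never correctness.
- **mate gate.** The mate must map concordantly on the same transcript with
  a fragment span ≤ 500 nt.
- **read 1 only in pileups.** Overlapping mates would count one molecule
  twice; using read 1 alone gives one observation per fragment.

Methylation evidence is read off the *original* read against the *original*
reference at the verified locus, so a C↔T toggle at any reference-C position
never changes where a read aligns — an invariant the test suite checks
explicitly.

# Calling and QC

The caller applies, in order: the read-level filter (a read with more than
30% of its reference cytosines unconverted is discarded — strictly greater,
so exactly 30% survives; reads covering zero cytosines are kept, treating
0/0 as 0); pileup construction; spike-in conversion QC (total T over total
C+T at spike-in cytosines must *exceed* 99.6%, otherwise site emission is
refused unless forced); and the three site gates (coverage ≥ 30, level
≥ 0.1, methylated depth ≥ 5). The read filter runs before any site is known,
so genuinely methylated cytosines count as "unconverted" there — faithful to
the pre-calling order of the procedure it implements.

Replicate tables are intersected on (chromosome, 1-based position, strand);
the merged level is the arithmetic mean of the replicate levels by default
(pooled counts are available via `caller_config(merge_level = "pooled")`);
matching on coordinate alone (not annotation) is our resolution of an
underdetermined convention. All emitted positions are 1-based and
strand-explicit, matching the usual `chr:pos` site naming; internally,
coordinates are 0-based half-open.

# Annotation, metagene, context

- **Regions.** Exonic positions classify by the transcript-space CDS
  interval (half-open: the base at `cds_start` is CDS); genomic positions
  inside the gene span but outside exons are intronic; transcripts without a
  CDS are ncRNA.
- **Context.** CG/CHG/CHH is read from the two bases immediately 3′ of the
  site on the *spliced* sense strand, falling back to genomic downstream
  bases at transcript ends, else `NA` (excluded from summaries). Whether
  real analyses use spliced or genomic context is ambiguous; splice-aware
  context is the chosen default because the molecule that was sequenced is
  the spliced one.
- **Context normalization.** Observed counts $n_k$ are divided by the
  transcriptome proportions $p_k$ of each context and renormalized:
  $\tilde f_k = (n_k/p_k) / \sum_m (n_m/p_m)$. Planting sites uniformly over
  cytosines (i.e., proportionally to abundance) recovers (⅓, ⅓, ⅓) within
  multinomial error — a calibration the acceptance tests verify.
- **Metagene.** A site's offset within its region is divided by the region
  length and multiplied by 100; the percentile bin is `floor`, clamped to
  bin 99 so the final base lands in the last bin (the edge rule is not
  dictated by the procedure's usual description, so floor-plus-clamp is
  fixed here and tested). Bins are reported as percentages of all profiled
  sites and smoothed with a centred 3-bin moving average whose edges are
  replicated — a kernel that preserves total mass exactly, so the smoothed
  profile still sums to 100.
- **Flanks.** 21-nt windows centred on each site, N-padded at transcript
  ends (N excluded from tallies), yield a position frequency matrix whose
  centre column is all C.

# Expression gate and comparisons

Gene counts use union-mode resolution on the union-of-exons gene model: a
read counts for a gene only if its genomic projection overlaps that gene's
exons and no other gene's. A mapping-quality filter is unnecessary because
the aligner emits unique alignments only. RPKM is
$\mathrm{count} \times 10^9 / (\mathrm{exon\ length} \times
\mathrm{total\ mapped})$, and RPKM ≥ 1 defines "expressed".

Cross-sample classifiers are pure set/threshold functions: a site is
sample-specific iff present in exactly one table; stringent specificity
first restricts the universe to genes expressed in *all* samples; dynamic
classification over common sites uses strict thresholds (|Δ| = 0.05 exactly
is stable, matching "greater than 5%"); knockdown-regulated sites satisfy
control − knockdown > 0.05, where a site absent from the knockdown counts
as level 0 if the knockdown pileup shows adequate coverage there and is
excluded as not assessable otherwise (coverage dropout must not masquerade
as demethylation). Correlation clustering uses Pearson correlation on
pairwise-complete sites, distance 1 − r, average linkage; both the distance
and the linkage are conventional choices, configurable in principle, fixed
here for determinism. Constant level columns make the correlation undefined
and raise an error naming the sample.

# Numerical and testing choices

- Every stochastic stage derives its RNG stream from `sim_config(seed =)`;
  the entire pipeline is byte-reproducible for a fixed configuration.
- In the stoichiometry-recovery test, each called level is checked against
  the binomial confidence interval of $s + (1-s)(1-p_\mathrm{conv})$ at its
  coverage. With 200 sites, 200 individual 99% intervals would fail ~2 sites
  by construction, so the interval is applied family-wise at 99%
  (per-site level $\alpha = 0.01/n$) — the property being tested is recovery
  of planted stoichiometries, not per-site coverage calibration.
- Test and acceptance problem sizes — 1–20 transcripts of a few hundred nt,
  depths 5–60×, 200 planted sites, 50 small caller-oracle instances — were
  chosen so that binomial error bars are tight enough for each assertion
  while the whole suite remains a desk-scale computation.
- On the minus strand, transcript position 0 projects to the *highest*
  genomic coordinate of the exon chain (1-based); project/unproject
  round-trips are identity by construction and by test.

# Known limitations

- The aligner has no indel support and no quality-aware scoring; it targets
  simulated reads and small references, not production genome-scale data.
- Single-seed lookup loses ~2–3% of reads to seed sequencing errors.
- Context classification at transcript ends depends on genome availability;
  otherwise sites are dropped from context summaries.
- Sites on overlapping isoforms are attributed to the transcript they were
  called on; real annotation-ambiguity handling (longest CDS-bearing
  isoform per gene) matters only when multiple isoforms are supplied.
- The statistics stop at the hard gates; there is no site-level significance
  model beyond them, mirroring standard practice for this assay.
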