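---
title: "Models and methods behind gscrna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gscrna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical models, the biological assumptions
and the numerical choices behind each stage of the pipeline, in the spirit
of the methods sections of DESeq2 or limma vignettes. It states no
empirical result that the test suite does not itself compute.

## The problem

Male (SSC) and female (FGSC) mouse germline stem cells are profiled by
strand-specific bulk RNA-seq, three libraries per condition. From the
aligned and assembled data one wants: the circular RNAs (circRNAs),
identified by backsplice junctions; the novel long noncoding RNAs
(lncRNAs), separated from coding, housekeeping and known transcripts; the
transcripts with sex-biased expression; the autosome-vs-X distribution of
those sex-biased sets; and two interaction networks — coding–noncoding
co-expression (CNC) and competing endogenous RNA (ceRNA).

Coordinates are 0-based half-open everywhere inside the package;
conversion to GTF's 1-based inclusive convention happens only at file
boundaries. This removes off-by-one ambiguity from the splice-motif
window arithmetic.

## circRNA calling

A backsplice read aligns as two exact-match segments in *reversed*
genomic order: the 5' part of the read downstream, the 3' part upstream.
After PCR-duplicate removal (identical `(sample, chrom, strand, seg1,
seg2)` keys collapse; read ids are sequencer artifacts and are ignored), a
candidate junction requires both segments on one chromosome and strand,
`seg2_end <= seg1_start`, and an outer span of at most 100 kb — the span
equals the circle length bound, measured `seg1_end - seg2_start` because
the anchor points are otherwise unstated.

Raw breakpoints are refined against the genome: the canonical splice
dinucleotides must flank the circle (GT after the donor, AG before the
acceptor, read on the junction strand; on the reference the minus-strand
pattern is AC left of the leftmost boundary and CT right of the rightmost).
Both arms are searched within ±10 nt, with one *shared* shift: alignment
ambiguity at a backsplice displaces both breakpoints by the same offset,
and coupling the arms prevents chimeric donor/acceptor pairings. Ties are
broken by smallest |shift|, preferring 0, then the negative shift —
purely for determinism. The original study describes this dual-segment
procedure in its methods while its results mention the CIRI program; the
methods procedure is what is implemented here.

Annotation assigns the hosting gene whose span contains the junction
(largest reciprocal overlap, then lexicographic id on ties), calls a
junction exonic when both boundaries coincide exactly with exon boundaries
of one transcript, intronic when it lies wholly inside one intron, and
flags usage of the transcription-order first/last exon — the statistic of
interest being that almost all circRNAs *avoid* terminal exons.

## The lncRNA cascade

Six filters, applied in a fixed order with the first failure recorded:

1. monoexonic **or** shorter than 200 bp spliced. The source describes
   "a single exon and less than 200-bp" but also defines lncRNAs as
   transcripts longer than 200 nt, and multi-exon filtering is standard,
   so the two conditions reject independently (an OR). This is the one
   deliberate reading choice in the cascade and is configurable.
2. read coverage < 3, then maximum FPKM over libraries < 0.01 (the
   aggregation over libraries is unstated in the source; the maximum is
   the most permissive reading).
3. known lncRNA by *intron-chain congruence*: the ordered list of internal
   splice sites must be identical on the same chromosome and strand;
   terminal exon lengths are free. Monoexonic references have no chain and
   can never match (they are rejected at step 1 anyway).
4. ≥ 1 bp same-strand exon overlap with rRNA/tRNA/snRNA/snoRNA/pre-miRNA/
   pseudogene annotations rejects.
5. an intron chain identical to a known mRNA rejects.
6. coding potential. The original pipeline intersects two external
   classifiers (CNCI and CPC); those are out of scope, and the *structure*
   of the rule is preserved with two independent ORF statistics: rule A
   calls coding when the longest ATG→stop ORF (three forward frames, stop
   included, codons containing N inert) reaches 300 bp; rule B calls
   coding when the ORF covers at least half the transcript. A transcript
   is noncoding only when **both** rules call it noncoding. The 300 bp /
   0.5 thresholds are the conventional ORF-length boundary for noncoding
   RNA and are configurable.

Survivors are classified positionally with precedence
sense > antisense > bidirectional > intergenic: exon-level overlap with a
coding gene (same strand → sense, opposite → antisense), else a 5' end
within 1000 bp of a coding 5' end on the opposite strand → bidirectional
(the window is a common promoter-divergence convention; the source states
none), else intergenic.

## Expression and the NB test

`FPKM = count / ((L/10^3)(N/10^6))` with `L` the spliced transcript
length (no fragment-length correction — the simplest defensible effective
length, stated here deliberately) and `N` the library's mapped-fragment
total. Gene-level FPKM is the sum over the gene's transcripts.

The differential test replaces Cuffdiff, of which the source names only
the distributional family (negative binomial, variance `mu + d mu^2`):

* size factors by median-of-ratios (geometric-mean reference over rows
  with no zeros);
* one **common dispersion** pooled across all transcripts and both
  conditions by method of moments: within each condition the excess of
  the variance of normalized counts over the mean estimates `d mu^2`;
  numerators and denominators are summed over transcripts. Per-transcript
  moment estimates above the Tukey upper fence (Q3 + 3 IQR) are excluded
  from the pool so a handful of rows with extra, non-NB variation (for
  example transcripts driven by a shared latent factor) cannot inflate
  the estimate. Pooling across conditions (rather than per-condition
  dispersions) is declared, not derived;
* per transcript, a two-sided exact conditional test on the two condition
  sums: conditional on the total, the probability of each split is
  proportional to the product of two NB masses (the sum of iid NB counts
  is NB with summed size), and the p-value sums the splits no more
  probable than the observed one. Above a total of 2000 the conditional
  enumeration is replaced by a normal approximation on the difference of
  size-factor-normalized rates with NB variances. The switch point only
  bounds enumeration cost; the test suite checks the two paths agree near
  it;
* Benjamini–Hochberg adjustment, fold change from normalized condition
  means with pseudocount 1 (`log2((SSC+1)/(FGSC+1))`), and calls at
  P-adjust < 0.05 and |log2FC| > 1. The source's results section mentions
  a raw p < 0.05 screen while its methods state the adjusted thresholds;
  the methods thresholds are the operative default and both are exposed.

## Autosome/X odds ratios

For a biased set within its expression universe (all expressed
transcripts of the same molecule class — the universe choice follows the
"non-biased lncRNAs and mRNAs" wording), the 2×2 table
(biased/non-biased × autosomal/X-linked) gives `OR = (a/b)/(c/d)`; OR > 1
means autosomal enrichment of the biased set. The two-sided Fisher p sums
all hypergeometric tables with probability not exceeding the observed one
(relative tie tolerance 1e-7, the convention of `stats::fisher.test`).
When `b` or `d` is zero the OR is flagged undefined rather than silently
corrected; Haldane-style corrections are deliberately off by default.

## Networks

**CNC.** Coding gene expression is the per-library *median* over the
gene's transcripts; both sides are restricted to the sex-biased lists;
all noncoding × coding pairs are tested; edges require |PCC| ≥ 0.99,
p < 0.01 (t distribution, n−2 df) and BH FDR < 0.01 over all tested
pairs. Correlations are computed on `log2(FPKM+1)` by default: expression
correlation is conventionally assessed on the log scale, and only there is
a negated shared factor (an anti-correlated pair) exactly affine —
on the raw scale `cor(G, 1/G)` of a lognormal factor is bounded away from
−1 and a planted anti-correlated pair could never reach the 0.99 gate.
`log_transform = FALSE` restores the raw scale.

**ceRNA.** The seed is miRNA nucleotides 2–8; a site is a target match to
its reverse complement, classed 8mer (with an A opposite position 1),
7mer-m8, or 7mer-A1 (A anchor, position 8 unpaired), all overlapping
occurrences reported. A circRNA's scanning sequence is its exonic
sequence plus the first 6 nt appended, so sites crossing the backsplice
junction are found exactly once (sites are reported modulo the circle
length). A sponge–miRNA–mRNA link requires at least one site on both the
sponge and the mRNA for the *same* miRNA, plus an expression gate of
|PCC| ≥ 0.9 — looser than the CNC 0.99 because the source asks only for
"a meaningful correlation" here; the threshold is configurable.

## The synthetic world

The generator's defaults describe a mouse-like desk-scale world: 19
autosomes plus X (~5% of genes X-linked), 150 kb chromosomes, 60 coding
genes of six 200-bp exons separated by 500-bp introns, every intron
GT..AG on its template strand, each mRNA carrying a planted 330-bp ORF.
lncRNAs are planted in all four positional classes (nested in a host
intron with a 10-bp exon overlap for sense/antisense; divergent at 200 bp
for bidirectional; >1.5 kb from anything for intergenic) and are
ORF-scrubbed — in-frame stops are inserted in a region that cannot touch
coding exons or splice dinucleotides until both coding-potential rules
call them noncoding. Backsplice junctions are planted on internal exons
(terminal-exon circles only on request, with the missing flanking
dinucleotide written in), supported by reads split at ≥ 20 bp per segment
— 20 bp guarantees unambiguous placement under the exact-match
assumption — plus three decoy classes (genomic-order, >100 kb reversed,
motif-scrubbed reversed) and byte-identical PCR duplicates.

Counts are NB with dispersion 0.1 around lognormal baseline means (scale
100, floored at 20 so no planted transcript is silent); biased
transcripts get a 4-fold change in their condition, and 40% of
female-biased picks are drawn from the X. Planted co-expressed and ceRNA
pairs share a per-library lognormal factor (sdlog 0.3, comparable to the
NB noise so the pooled dispersion is not distorted) at high expression
(5000) and low dispersion (5e-4); together with the shared (or, for
negative pairs, opposed) condition effect this puts |PCC| of log-FPKM
above 0.99. Libraries are emitted with a fixed mapped-fragment total of
10^6 — equal sequencing depth is the realistic assumption, and with only
tens of simulated transcripts a column-sum "depth" would be dominated by
the planted high-expression pairs themselves. Seed sites are written into
sponge and target sequences at recorded positions and *all* transcript
(and circle, junction-aware) sequences are then scrubbed of spurious seed
matches for every simulated miRNA, preserving coding/noncoding status.

What the generator does **not** emulate — and hence what a green test does
not establish: sequencing error and quality, fragment-length effects,
alternative isoforms per gene, expression-dependent assembly artifacts,
GC or mappability bias, and single-cell structure. Recovery results on
this world certify the *logic* of the stages, not their robustness to
alignment noise.

## Numerical and scale choices

* All randomness flows from one integer seed; each simulator stage derives
  a fixed offset seed so stages are reproducible both standalone and
  composed. Outputs are byte-identical across reruns, and the pipeline
  manifest records md5 hashes to prove it.
* The determinism acceptance check runs on a scaled-down configuration
  (5 chromosomes × 150 kb, 25 genes) to stay well inside its time budget;
  the full default configuration is exercised once elsewhere in the suite.
* Degenerate inputs: empty alignment sets, zero-candidate refinements,
  all-zero count rows (p = 1, ns), constant expression vectors (flagged,
  excluded from networks), and empty circRNA summaries (explicit `empty`
  flag) are all defined rather than erroring.
* The split-alignment dialect carries a single chromosome column, so
  inter-chromosomal artifacts are unrepresentable by construction; the
  caller's same-chromosome requirement is enforced by the format.
* Config files for the command-line wrapper are JSON (no YAML parser is
  assumed on the target system); structure and field names are unchanged.

## Known limitations

Rolling-circle (multi-segment) backsplice reads, circRNA abundance
normalization, isoform-level quantification, batch correction, GO/KEGG
enrichment and thermodynamic miRNA-site scoring are out of scope. The
coding-potential stand-in is an ORF heuristic, not a trained classifier:
on real data it will disagree with CNCI/CPC near the 300 bp boundary.
The reference genome is treated as opaque (any FASTA + GTF pair works);
nothing is mm9- or mm10-specific.
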