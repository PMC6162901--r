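---
title: "Calling variants behind a pseudogene: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling variants behind a pseudogene: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogr)
```

## The problem

The 3' exons of PMS2 (a mismatch-repair gene on hereditary-cancer panels)
are nearly identical to the pseudogene PMS2CL: sequence identity in each of
the last five exons exceeds 97%, and after accounting for population-level
sequence exchange between the two loci, exons 12--15 retain *zero* bases
that reliably distinguish them. A short sequencing read from this region
cannot be attributed to the gene or the pseudogene. `paralogr` implements
the computational core of a reflex workflow for this situation, together
with a synthetic-locus simulator for validating every stage:

1. permissive realignment that stacks gene- and pseudogene-originating reads
   on one locus,
2. diploid variant calling in exon 11 (where seven distinguishing bases
   allow read partitioning) and tetraploid calling in exons 12--15 (two gene
   copies + two pseudogene copies at one position),
3. read-depth HMM copy-number calling at a baseline of two or four,
4. simulation drivers that measure CNV and indel sensitivity,
5. dosage-aware concordance statistics with exact binomial intervals, and
6. a decision engine that sends only ambiguous non-benign findings to
   long-range-PCR disambiguation ("reflex testing").

## The synthetic locus

`generate_locus()` builds one contig holding a gene block and a pseudogene
block that are byte-identical except at injected *distinguishing bases*.
Five exons are modelled; gene exons are labelled 11--15 and the homologous
pseudogene exons 2--6. Choices worth knowing:

* **Equal-length exon pairs, one constant-offset homology bijection.** Real
  gene/pseudogene pairs have small structural differences; modelling them
  would make the position map partial without changing what the pipeline is
  tested on. The bijection makes "the homologous coordinate" exact.
* **Exon shape.** The default exon lengths are 880 nt for exon 11 and 150 nt
  for exons 12--15: a 26-base difference set at >97% identity needs a
  ~900 nt window, mirroring the one large + four small exon layout of the
  real locus. Identity per exon is computed over the exon plus 20 nt of
  intron, the same padded window used for placing distinguishing bases.
* **Flank and spacer sizes.** The blocks are separated by 650 nt of
  unrelated sequence and flanked by 650 nt, which exceeds half the longest
  simulated fragment; a fragment drawn from one paralog can therefore never
  physically extend into the other, as befits loci that are megabases apart
  in reality.
* **hg19-like vs degraded configurations.** The default places 26, 0, 1, 1,
  0 distinguishing bases in exons 11--15 (the reference-genome picture).
  Population-level erosion is not baked into the sequence; it is simulated
  by `generate_cohort(gene_conversion_rate = ...)`, which lets every
  haplotype carry the partner paralog's allele at each distinguishing base
  independently with the given per-site probability. Site reliability is
  then *measured* from the cohort by `build_catalog()`, exactly as an
  amplicon survey would.

## Read simulation

`simulate_reads()` draws sequencing fragments per haplotype with uniform
midpoints and uniform fragment lengths in [250, 600] nt (a narrower range
than typical sonication so the 1000 bp pairing rule stays exercised but
testable). In hybrid-capture mode, fragment midpoints are sampled from the
block extended by half a mean fragment on each side, which keeps realized
coverage uniform (and equal to `mean_depth`) across the whole block rather
than tapering at its edges; amplicon mode instead contains fragments within
the amplified block, as PCR does. Sequencing error is independent per-base
substitution, uniform over the three alternatives, with no indel errors --
the simplest noise that stresses the callers. Allelic dropout in amplicon
mode is per-fragment Bernoulli thinning of the second haplotype: only the
*signature* of dropout (allele balance far below 50%) is specified by the
assay, not its generative mechanism, so the simplest mechanism with the
right signature is used; retention `f` gives an expected het allele balance
of `f/(1+f)` (about 6.5% at `f = 0.07`).

Truth is carried per read: origin haplotype, generative fragment interval
and strand, written to a SAM `XO` tag. The truth CIGAR is recorded as
full-length match; small indels on the source haplotype are not spelled out
there (the tag is for evaluating read *attribution*, not alignment detail).

## Alignment

`seed_and_extend()` is a deliberately permissive single-end aligner: every
exact 11-mer is a seed (no minimizer sampling -- the locus is tiny), and
each seed-diagonal cluster is extended by banded affine-gap Smith-Waterman
with match +1, mismatch -1, gap open 2, gap extend 1, emitting *all*
alignments scoring at least 20. The mismatch/gap-open penalties and the
threshold are the workflow's stated operating point; the match reward and
extension penalty complete the scheme so a 115 nt read scores 115 when
perfect and 113 with one mismatch. The DP band covers the seed diagonals
plus/minus the window padding (16 nt), so any alignment whose gaps fit the
padding is found; tests check score equality against an exhaustive
Smith-Waterman oracle.

`pair_alignments()` rebuilds pairs with four rules: same read name, both
mates inside the exon 12--15 region (both paralog copies qualify), mate
starts within 1000 bp, and the highest pair score wins. A tie across the
two locus copies keeps one pair per copy -- that is precisely what stacks
four haplotypes at one position after `aggregate_exons12_15()` translates
pseudogene placements through the homology map. Unpairable reads are
dropped and counted.

`partition_exon11_reads()` keeps only reads overlapping a reliable
distinguishing site and assigns each read (jointly with its mate) to the
paralog whose allele it carries at *every* overlapped reliable site. Mixed
alleles, alleles matching neither paralog, or no overlapped site all lead
to discard; conflicts are not adjudicated because a conflicted read is
exactly what gene conversion or sequencing error produces.

## Genotyping

Variant calling is a pileup-based maximum-likelihood dosage model rather
than local haplotype assembly: the workflow's acceptance surface (dosage
concordance against amplicon truth) is model-agnostic, and a binomial
dosage likelihood is transparent and exactly testable. For alternate-allele
dosage $d$ at ploidy $P \in \{2, 4\}$ with per-base error rate
$\varepsilon$ (default 0.01, spread over three alternatives):

$$p_d = \frac{d}{P}(1-\varepsilon) + \Big(1 - \frac{d}{P}\Big)\frac{\varepsilon}{3},
\qquad \log L(d) = \log \mathrm{Binom}(k \mid n, p_d)$$

with $k$ alternate reads out of $n$. The call is $\arg\max_d \log L(d)$
under a uniform prior (no dosage priors are stated for this assay); ties go
to the lower dosage (parsimony). Indels are left-aligned VCF-style and
keyed at their anchor: a read carrying the indel contributes the indel
allele *instead of* the anchor base, so column depth equals informative
reads. Multi-allelic columns are genotyped for the best non-reference
allele against the pooled remainder. Sites below 20 reads are flagged
`LOW_DEPTH`, the panel's coverage minimum. Exon 11 is called at ploidy 2 on
gene-partitioned reads; exons 12--15 at ploidy 4 on aggregated reads.

## Copy number

`bin_depths()` counts reads per 50 bp bin (any-overlap convention; a
one-bin-per-target start-position convention is available for capture
panels). `normalize_depths()` is the two-stage median scheme: each sample
by its median bin depth, then each bin by its cross-sample median; bins
with zero cross-sample median are masked. After normalization the per-bin
median is 1 by construction, which the tests assert.

When the depth matrix covers only a small target (the four swept exons, or
the handful of exon-11 distinguishing sites), an event spanning *every* bin
would be absorbed by the stage-one median; `normalize_depths()` and the
sweep therefore accept an externally anchored per-sample divisor -- in
production the sample median over the whole panel, in the sweep the
pre-injection median. This is a property of median normalization, not of
the caller.

`call_cnv()` Viterbi-decodes a three-state HMM over copy numbers
{baseline-1, baseline, baseline+1} with Gaussian emissions centred at
copy/baseline. The wild-type state leaves with probability `p_cnv = 0.01`
(split over the two CNV states) -- the workflow's stated sensitivity
setting -- and CNV states return with probability 0.1. The reference
depth-HMM caller is not fully specified publicly, so this minimal HMM is a
declared stand-in consistent with every stated fact (baselines, `p_cnv`,
binning, normalization); its decoding is verified against exhaustive path
enumeration. Per-bin emission noise defaults to the cohort median absolute
deviation, floored at 0.01. Event quality is the log-odds of the decoded
path against the same path with the event flattened to baseline; events
under `q_min = 3` log-odds become `NO_CALL` (the workflow reports that
no-calls exist but no criterion, so the threshold is a package choice).
Copy states beyond one step from baseline are out of scope -- a documented
limitation, reasonable where homozygous deletions are rare.

Exon-11 CNVs are called at baseline 2 on gene-partitioned depths measured
only at the distinguishing sites (the only positions where "gene depth" is
well defined); fewer than two usable sites is an explicit `NO_CALL`.

## Sensitivity simulations

`inject_cnv()` subsamples span reads/counts to 75% (one copy lost of four)
or resamples 25% extra (one gained) -- duplication scaling is implemented
as sampling-with-replacement of span reads with fresh ids, since the
read-vs-count level of the original scaling is not specified.
`cnv_sensitivity_sweep()` enumerates every contiguous exon combination of
the last four exons (10 spans), both kinds, distributing the replicate
budget uniformly (the study scale is 2186 replicates; how they were
distributed is unstated). Detection requires a confident call overlapping
the injected span with the correct sign. `merge_diploid_to_tetraploid()`
builds synthetic tetraploid indel samples by merging two diploid alignment
sets, binomially downsampling the deeper one in the 100 bp window around
the indel; the expected merged dosage is the sum of the diploid dosages.
`weighted_aggregate_sensitivity()` weights per-size sensitivities by an
observed CNV length distribution and reports one decimal.

Synthetic sensitivities at 500x with cohort noise around 3--5% are near 1
and are asserted only as bounds (multi-exon >= 99%, single-exon >= 85%,
sample-level false positives <= 1/300): the published per-size values
depend on patient depth profiles that no simulation should claim to
reproduce.

## Metrics and the reflex engine

`concordance()` compares tetraploid hybrid-capture dosages (0--4) against
the *sum* of gene and pseudogene amplicon dosages (each 0--2). Equal
non-zero dosages are true positives; unequal non-zero dosages are
*permissible dosage errors* -- presence was detected, the sample reflexes,
and the dosage is corrected downstream -- counted toward sensitivity by
default and always reported as their own class. True negatives are counted
only at sites polymorphic in the cohort; concordant-reference pairs at
non-polymorphic sites are not evaluated. `clopper_pearson()` is the exact
central interval via beta quantiles, cross-checked in tests against
numeric tail inversion. `qc_allelic_dropout()` flags an amplicon when no
heterozygous site exists or all het balances fall below 0.2 (a configurable
quantification of "significantly less than 50%").

`decide()` encodes the reporting rules: benign and likely-benign variants
are neither reported nor reflexed; non-benign CNVs anywhere in exons 11--15
reflex; non-benign SNVs/indels reflex only in exons 12--15 (in exon 11 the
partitioned reads already prove gene origin, so they are reported
directly); CNV no-calls reflex by default, with a flag for the
retest-first practice that usually resolves them.
`estimate_reflex_rate()` places an independent Beta(k+1, n-k+1) posterior
on each observed component rate (binomial likelihood, uniform prior) and
Monte-Carlo sums the components; with the observed counts 41/707, 2/707
and 1/144 the posterior mean is 7.7% -- equal to the analytic sum of
posterior means (k+1)/(n+2), which supports the independence + uniform
prior choice. Rates are scale-free in this model, so the target cohort
size is framing only.

## What the simulations do and do not show

The generator emulates: near-identical paralog pairs, a small degradable
distinguishing-base set, diploid gene + diploid pseudogene samples, SNVs,
short indels and exon-scale CNVs, 115 nt paired reads at 200--1000x with
substitution errors, amplicon restriction to one paralog, and allelic
dropout. It does not emulate GC or capture bias, indel sequencing errors,
optical duplicates, structural divergence between the paralogs, or the
depth heterogeneity of patient batches. Green tests therefore demonstrate
the *algorithms* are implemented correctly at realistic operating points;
they do not certify clinical performance on real data.

Problem sizes used by the test-suite: a compact locus (240 nt exon 11,
7 distinguishing bases), end-to-end runs at 150--250x, 200 pileup-level
genotyper samples at 500x, 300-sample false-positive cohorts, and sweeps
of a few hundred replicates; the full 2186-replicate sweep and 10^5-draw
posterior run in seconds through the same code paths.

## Numerical conventions

0-based half-open intervals internally; 1-based on VCF/SAM/BED output
where those formats require it. Reported percentages round half away from
zero to one decimal. Genotype likelihood ties break to the lower dosage;
Viterbi ties break deterministically by state order. Degenerate inputs are
explicit errors or explicit `NO_CALL`s, never silent zeros: empty cohorts,
zero reliable exon-11 sites, rows shorter than two bins, and k > n all
stop.
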