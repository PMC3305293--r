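---
title: "Methods: group-exclusive SNPs and expression divergence between two population groups"
author: "snpexpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-exclusive SNPs and expression divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis

`snpexpress` implements a joint sequence-and-expression contrast between two
population groups of the same species sequenced with legacy long-read
(454-style) transcriptome libraries — the motivating system is a marine
("AO") versus a recently landlocked freshwater ("LM") population of a small
clupeid fish, sampled as 4 and 3 individuals respectively. Because the
libraries are not normalized, the same reads carry two signals at once:

1. **Sequence divergence.** Reads realigned to the reference transcript set
   yield per-site allele counts (pileups). Polymorphic sites are filtered to
   an intermediate variant-allele-fraction window and classified by whether
   an allele is restricted to one group (group-exclusive), either as a fixed
   difference or as a polymorphism confined to one group.
2. **Regulatory divergence.** Per-contig read counts, RPKM-normalized, are
   tested for differential expression between the groups with an
   empirical-Bayes moderated t-test and Benjamini–Hochberg FDR control,
   after fold-change tiering.

The package also provides the connecting statistics: a Fisher exact test
contrasting how many group-exclusive sites remain polymorphic within each
group, and the overlap between SNP-bearing loci and the most misexpressed
genes. A synthetic-data module generates studies with known truth so every
stage is testable by recovery.

## The synthetic study generator

`generate_reference()` emulates a de novo transcriptome assembly: a few
hundred contigs with truncated-normal lengths (default mean 350 bp), a
settable GC content, and a fraction carrying a CDS (ATG start, no in-frame
internal stop, terminal stop, length divisible by 3).

`plant_variants()` places three variant classes, mirroring the site types a
two-group comparison distinguishes:

* `shared_polymorphism` — both groups segregate ref and alt;
* `group_exclusive_fixed` — the carrier group is fixed for the alternate
  allele (within-group frequency 1), the other group carries the reference;
* `group_exclusive_polymorphic` — the carrier group segregates ref and alt;
  one allele is therefore always shared with the other group.

A configurable number of variants are single-base deletions (`alt = "-"`),
the one indel class the caller annotates. Variants sit at least 5 bp from
transcript ends so typical read alignments span them.

`sample_plans()` encodes the non-normalized library design: per-transcript
sampling weights are proportional to transcript length times a shared
log-normal abundance, with true LM/AO fold changes (default magnitudes
log-uniform on 2–200×) multiplied into the LM samples. `simulate_reads()`
draws multinomial read counts per transcript, builds per-read haplotypes
(alt alleles included with their planted within-group frequency), applies
truncated-normal read lengths (mean 187, sd 60, min 40 bp), uniform start
positions and strands, independent per-base substitutions (default 0.5%)
and single-base indel errors (default 0.2%), and writes FASTQ with a
constant Q30 placeholder quality (the downstream analysis does not use
qualities beyond trimming, which is assumed done). Homopolymer-aware error
structure and flowgram space are deliberately not modelled; recovery results
on these reads therefore do not speak to homopolymer-driven artifacts in
real 454 data.

Per-sample random streams are derived from the master seed by hashing the
stream label (`derive_seed(master, "reads:AO_2")`), so adding a sample never
changes the reads of the others, and identical configurations are
byte-identical.

## Alignment

`build_index()` indexes every k-mer of the reference (default k = 15, the
specific-match seed size). `align_reads()` seeds both read orientations,
groups hits into candidate (transcript, strand, diagonal-range) triples by
vote count, and extends each candidate with a local affine-gap
Smith–Waterman (match +10, mismatch −20; a gap of length L costs
20 + 5L, so a 1-bp gap is worse than a mismatch but long gaps are not
catastrophically penalized, capped at 15 bp per gap). The DP runs on a
reference window padded 30 bp beyond the seeded diagonals — exhaustive over
that window, which contains the optimum for reads whose gaps are small
relative to the pad; the test suite verifies score equality with a full
independent DP on reads with up to two edits. Percent identity is computed
over aligned columns, excluding soft-clipped ends, and the threshold
(default 0.90) is inclusive. A consequence worth knowing: a read with a
badly mismatching tail may align as a clipped, identity-passing segment
rather than being rejected outright. An assembler-style "expected coverage"
parameter has no analog in alignment to a known reference and is
intentionally unused.

Exact score ties break to the lowest transcript id, then the lowest start,
then the forward strand, and a read is counted once (best hit only) so
per-sample mapped totals are conserved for RPKM. Internally all coordinates
are 0-based half-open; every emitted text report is 1-based.

`build_pileup()` tallies per-sample counts over the alleles
{A, C, G, T, gap}: deletions contribute gap counts at the deleted reference
positions; insertions do not occupy a reference column and are returned
separately. Note that the placement of a gap inside a homopolymer run is
alignment-ambiguous; recovery tests therefore match planted deletions
within ±2 bp.

## SNP calling and classification

`call_putative_snps()` pools raw-read counts over samples and emits sites
with at least two alleles each supported by ≥ 2 reads and pooled depth ≥ 10.
The majority allele across all samples stands in for the assembly consensus
as the site's reference allele.

`filter_frequency()` keeps sites whose polymorphism involves an intermediate
fraction of raw reads, window [0.25, 0.75], boundaries inclusive. Two
readings of "intermediate" are implemented: the default requires *every*
non-majority allele to lie inside the window; the alternative
(`mode = "total_nonref"`) tests the summed non-consensus fraction. The
default is the stricter reading: a site acquires a third allele from two
stray error reads and is dropped, because that allele's fraction is far
below 0.25.

`classify_group_specific()` applies a deliberately asymmetric evidence rule:
an allele is *present* in a group with ≥ 2 supporting reads, *absent* only
with 0 reads, and a single read is neither — it cannot establish an allele
in its own group, and it blocks declaring that allele exclusive to the
other. This keeps isolated sequencing errors from either creating or
destroying exclusivity. Subtypes: `fixed_divergent` (each group presents a
single, different allele), `polymorphic_in_AO` / `polymorphic_in_LM` (the
named group presents ≥ 2 alleles, at least one absent from the other
group), plus two values beyond the basic trio that real profiles can
produce: `polymorphic_in_both` (both groups polymorphic, each with an
exclusive allele) and `uncallable` (a group with zero depth, or with no
allele reaching the presence threshold).

**Depth matters.** Both the strict window and the presence/absence rule
interact with depth × error rate: the expected number of stray reads of a
specific allele at a site grows linearly with depth, so at very deep sites
(several hundred ×) stray alleles routinely reach 2 reads (killing the
per-allele window) or 1 read in the "wrong" group (blocking exclusivity).
The calling rules are calibrated for the pooled-depth regime of roughly
40–100× at the default error rates; the default toy pipeline configuration
deliberately runs much deeper (~900×) to exercise the funnel and typically
reports very few or zero surviving group-exclusive sites, which is the
expected behaviour of these rules, not a defect. The recovery tests run at
~60× pooled depth with a 0.2% substitution rate and planted within-group
frequencies of 0.85–1, where a simple error budget puts expected misses
well under 5%; those conditions were fixed from that budget before the
tests were first executed.

`annotate_coding_effect()` translates substitutions in the annotated CDS
frame with the standard genetic code (majority allele as the consensus
base), labels gap alleles in a CDS as `indel`, and everything outside a CDS
as `noncoding`.

## Expression

RPKM is `count / (length/1e3) / (total/1e6)` per contig and sample; testing
is on `log2(RPKM + 1)` (the pseudocount avoids log 0; the transform is a
package choice, as the upstream tooling this emulates does not state one).
Fold change is reported on untransformed group-mean RPKM with a pseudocount
of 0.1 in numerator and denominator.

The moderated t-test shrinks each contig's pooled two-group variance
\(s_g^2\) (df \(d_g = n_1 + n_2 - 2\)) towards a prior \(s_0^2\) with
\(d_0\) prior df:

\[ \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
   \tilde t_g = \frac{\bar x_{g,\mathrm{AO}} - \bar x_{g,\mathrm{LM}}}
   {\tilde s_g \sqrt{1/n_1 + 1/n_2}}, \]

with two-sided p-values from a t distribution on \(d_0 + d_g\) df (capped
at \(10^6\) when \(d_0 = \infty\)). The prior is fitted by matching the
first two moments of \(\log s_g^2\) against the scaled inverse chi-square
prior via digamma/trigamma identities; when the observed spread of log
variances does not exceed the chi-square sampling component, \(d_0\) is
infinite and \(s_0^2\) is the common variance. At \(d_0 = 0\) the statistic
is exactly the ordinary pooled t — both limits are asserted numerically in
the tests, and the whole fit is cross-checked against limma's
empirical-Bayes machinery on shared data. Contigs with zero counts in every
retained sample are dropped before testing. Negative \(\tilde t\) means
overexpressed in LM (group labels sort AO before LM).

Fold-change tiers (2× and 8×) keep contigs with
\(\max(FC, 1/FC) \ge\) threshold. The pipeline applies the 8× tier first
and then BH-adjusts within the tier (the narrowed candidate list is what is
multiplicity-corrected); `de_test()` also returns q-values over all tested
contigs for generic use.

Clustering of the tier-filtered log2 expression uses Euclidean distance
with centroid linkage (merge criterion: distance between cluster centroids,
recomputed after each merge). Internally this runs `hclust` on squared
distances, whose centroid heights are squared centroid distances; heights
are re-expressed on the Euclidean scale. Centroid linkage can produce
height inversions; leaf orders are emitted as-is and dendrograms exported
as Newick.

Sample QC mirrors the design where one low-yield, short-read sample is
excluded from the expression analysis only: `qc_samples()` defaults to
min 60,000 reads and mean length ≥ 150 bp (study scale); the toy
configuration scales these down. Failed samples keep contributing reads to
the SNP stage.

## Divergence statistics

`fisher_exact_two_sided()` uses the probability-ordering convention (sum of
hypergeometric probabilities of tables no more probable than the observed
one); the suite confirms it against direct enumeration on every table with
total ≤ 20. The pipeline builds its 2×2 table as
rows = groups, columns = (polymorphic within the group, not) over the
group-exclusive sites. `snp_de_overlap()` treats its inputs as sets;
percentages print at integer precision, the group-specific fraction of
filtered sites at one decimal, with full-precision values kept in the JSON
report alongside.

## Problem sizes, determinism, and limitations

The shipped tests run the full pipeline at 20 transcripts × 7 samples ×
5,000 reads (the default toy configuration), the recovery study at ~2,250
reads (~60× pooled depth), and the prior-recovery simulation at 5,000
contigs — sizes chosen so the whole suite completes in a few minutes while
keeping the binomial error budgets of the recovery assertions tight.
Everything stochastic flows from one master seed through labelled stream
derivation; reruns of a pipeline configuration are bit-identical, and each
run directory is stamped with the configuration hash.

Known limitations: no homopolymer-aware 454 error model; only single-base
indels are simulated, called and annotated; no functional annotation
(the per-locus report carries transcript ids, not gene names); the
frequency window and exclusivity rules are depth-calibrated as described
above; and absolute funnel counts from any real study depend on its data
and are not reproduced by synthetic runs.
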