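---
title: "Detecting and classifying miRNA mutation/editing sites with mirledit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying miRNA mutation/editing sites with mirledit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirledit)
```

## The problem

MicroRNAs are post-transcriptionally modified in several ways that leave a
sequence trace in small RNA-seq reads: A-to-I editing by ADAR enzymes
(inosine is read as G by sequencers), C-to-U editing by APOBEC-family
deaminases, untemplated 3' additions of adenosines or uridines, 5'-end
variation, and plain genomic variation (SNPs). In brain tissue, A-to-I
editing of miRNAs is widespread and its level changes with age; editing
inside a mature miRNA's seed region (positions 2-8) can retarget the
miRNA entirely. Distinguishing genuine modification from sequencing error,
from cross-mapping artifacts, and from genomic polymorphism requires a
statistical pipeline rather than simple mismatch counting.

`mirledit` implements such a pipeline: from raw FASTQ reads to per-sample
mutation/editing (M/E) site calls, cohort-level retention, nine-way
classification, and cohort statistics (age correlation of editing levels,
case-control differential editing). A site is named
`{precursor}_{position}_{REF}_{alt}` with the template base upper-case and
the variant base lower-case in RNA letters — `hsa-mir-376a-1_9_A_g` is an
A-to-I site at hairpin position 9.

## The detection model

Reads are adapter-trimmed, quality-filtered and collapsed to unique tags
with counts. Each unique tag is placed on the pre-miRNA hairpins by a
deterministic exact-seed (12-mer), ungapped aligner allowing up to 2 body
substitutions and an untemplated 3' tail of up to 3 nt; the
mismatch-vs-tail split minimises `mismatches + tail length`, ties going to
the shorter tail. Tail positions past the hairpin 3' end are compared
against genomic flanking sequence, which is what distinguishes an
untemplated addition from templated read-through.

Multi-mapped tags are re-weighted by iterative cross-mapping correction:
a read's weight at each candidate locus is proportional to the locus's
current mass of perfectly matching reads plus a pseudocount of 0.5,
iterated to a fixed point (tolerance 1e-6, at most 100 iterations).
Uniquely placed reads keep weight 1, so total read mass is conserved
exactly — a property the test suite checks to 1e-9.

Weighted counts feed a per-position pileup. Every position/alternative
with non-zero weighted count is a candidate site, tested against a
binomial sequencing-error null: with the Phred-30 threshold the per-base
error probability is $p_0 = 10^{-30/10} = 0.001$, and the p-value is
$P(X \ge k)$ for $X \sim \mathrm{Binomial}(n, p_0)$ with $n$ the rounded
coverage and $k$ the rounded weighted alternative count. Candidates are
Benjamini-Hochberg corrected within each sample, and a site is
*significant* when all of the following hold:

* editing level (alternative fraction) $\ge$ 5%,
* support $\ge$ 10 reads per ten million sequencing tags (RPTM),
* BH-corrected p-value $< 0.05$.

Samples are then combined: a site is *retained* for cohort analysis when
it is significant in at least 10% of the samples. The threshold is
round-half-up of `0.10 * n_samples`, floored at one sample, which gives
13 samples for a 131-sample cohort — the arithmetic used throughout.
A strict ceiling would give 14 at that cohort size; the round-to-nearest
rule is this package's choice and is pinned by a test.

## Classification

Each retained site gets exactly one of nine categories, decided in order:

1. **SNP** — the site coincides with a known variant (same genomic
   position, same alleles, strand-aware) *and* reaches a 100% editing
   level in at least one sample, i.e. behaves like a homozygous genomic
   variant rather than a partial modification.
2. **Pseudo** — more than half of the supporting-read mass is attributed
   to another locus by cross-mapping correction. The pipeline
   operationalises "pseudo site" as this majority-elsewhere criterion;
   it is a definition made here, chosen because suppressing such sites is
   precisely what cross-mapping correction exists for.
3. **3'-A / 3'-U / 3'-Other** — positions past the mature 3' end (up to
   5 nt; farther is a classification error), split by the added
   nucleotide.
4. **5'** — positions at or before the mature 5' start.
5. **A-to-I** (central A>g), **C-to-U** (central C>u), **Other** (any
   other central change, e.g. U>g).

Central A-to-I and C-to-U sites can additionally be flagged as conserved
when another species shows the same editing type at the same
mature-relative position, as in-seed when the mature-relative position
lies in 2-8, and their immediate hairpin neighbours are tabulated by
`context_preference()` — A-to-I sites are expected to favour a 5' U and
3' G, C-to-U sites a C on both sides (the CCC motif).

## Cohort statistics

`run_cohort_analysis()` takes the site-by-sample level matrix and a design
table (sample, case/control group, age). Per site it computes:

* **Age correlation** — midrank Spearman rho within each group, exact
  permutation p for n $\le$ 8 and the t approximation otherwise, BH
  corrected across sites separately per group (call at q < 0.05).
  All-zero (or otherwise constant) level vectors return an undefined-rho
  sentinel rather than being dropped.
* **Differential editing** — Mann-Whitney U from pooled midranks, exact p
  from the full null distribution of the rank sum (dynamic programming
  over the midrank multiset) when `n_case * n_control <= 400`, otherwise
  the normal approximation with tie and continuity correction. The
  significance column follows the uncorrected p < 0.05 rule; a
  BH-corrected column is emitted alongside, because the two screens in
  the underlying study design differ in whether they correct, and users
  should see both. Direction (`hyper`/`hypo`) compares group medians.
* The under-10 subgroup analysis is the same machinery after filtering
  samples to age strictly below the cutoff.

## The synthetic-data generator

The generator exists so that every stage can be tested against a known
truth. `generate_reference()` draws random hairpins (50 nt or longer)
with one or two mature arms of 20-24 nt, genomic flanks, and optional
decoy loci — genomic segments sharing a long exact substring with a
hairpin but differing by one substitution, the configuration that
produces cross-mapping artifacts. `simulate_sample()` anchors reads on
the mature arms with geometric 5'/3' end jitter (p = 0.7, capped at
3 nt — a read-start model chosen to reproduce isomiR-like pileups without
modelling Drosha/Dicer kinetics), plants each specified edit
independently per covering read with probability equal to its target
level (SNPs at level 1), applies per-base errors at
`10^(-phred_q/10)` uniformly over the three other bases, and appends a
fixed 3' adapter (default `TGGAATTCTCGGGTGCCAAGG`, a common small-RNA
kit adapter) plus a uniform Phred string. A truth table records each
planted event's realised coverage and carrier count.

What the simulator deliberately does **not** model: realistic expression
differences across miRNA families, ligation bias, per-cycle quality
decay, UMIs, indels. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated error model, not robustness
to every artifact of real libraries. Two further conventions: the
adapter is sequenced error-free (trimming behaviour is tested
separately), and the error model accepts `per_base_error = 0` so that
noiseless reads with finite quality strings can probe the no-noise limit.

## Numerical and design choices

* "Low-quality read" is operationalised as *any base below Q30* — the
  same score that defines the error null; both are configurable but move
  together by default.
* The RPTM library total is the number of reads surviving trimming and
  the length filter — usable sequencing tags, not raw FASTQ records.
* Adapter matching: leftmost position where the read/adapter overlap is
  at least 8 nt and exact, or where the full adapter occurs with at most
  one mismatch.
* The error null uses $p_0 = 0.001$ toward the specific alternative
  (conservative); `error_split_three = TRUE` divides by 3.
* Weighted (fractional) counts are rounded half-up for the binomial test.
* BH families: all candidates within one sample at the calling stage;
  all sites within one analysis at the cohort stage.
* Ties use midranks everywhere; the Mann-Whitney exact p is the
  two-sided `2 * min(lower tail, upper tail)` capped at 1.
* Minus-strand hairpins complement alleles for SNP comparison.
* The under-10 filter is strict (`age < 10`).

## Problem sizes used by the test suite

The packaged checks run, among others: a 20-replicate null study
(50 hairpins, 500 reads per arm, Q30 errors, no planted edits) verifying
that the retained-site fraction stays within twice the nominal 5% FDR
level; a 300-run level-recovery study (levels 0.1/0.3/0.7 at coverage
1000, 3-binomial-SD tolerance, $\ge$ 99% pass rate); and a 100-seed
end-to-end cohort study (20 cases at level 0.35 vs 25 controls at 0.12,
coverage 800) requiring the planted site to be retained, classified
A-to-I and called significantly hyperedited in at least 95% of seeds.
These sizes were chosen to give each check enough replicates for a
stable verdict while keeping a full run in the minutes range on one CPU.

## A small worked example

```{r example}
ref <- generate_reference(2, c(70, 90), seed = 1)
hp1 <- names(ref$hairpins)[1]
m <- ref$matures[ref$matures$pre_mirna_id == hp1, ][1, ]
pos <- which(strsplit(ref$hairpins[[1]], "")[[1]] == "A")
pos <- pos[pos > m$start + 1 & pos < m$end - 1][1]

ed <- edit_spec(hp1, pos, "A", "g", 0.30, "central")
s <- simulate_sample(ref, ed, depth_per_arm = 1000, seed = 7)
res <- process_sample(s, NULL, ref)
subset(res$calls, significant,
       select = c(key, coverage, level, support_rptm, q_value))
```

The called level matches the planted 30% within binomial noise, and the
site key encodes hairpin, position and the A>g change.

## Known limitations

Gapped alignment and indel editing are out of scope; decoy loci stand in
for a genome-wide mapping step, so cross-mapping correction only sees the
competing loci it is given; the binomial null assumes one uniform error
rate per sample rather than a per-cycle profile; and the nine-way
classifier assigns positions between two mature arms to the nearest arm,
which is a convention, not a biological claim.
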