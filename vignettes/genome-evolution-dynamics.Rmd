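---
title: "Genome evolution dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome evolution dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gevodyn)
```

`gevodyn` implements the computational core of a genome-evolution study of
a large, repeat-rich, partially selfing plant genome: genome sizing from
k-mer spectra, dating of LTR retrotransposon insertions, detection and
dating of whole-genome duplications (WGD) from synonymous-substitution
(Ks) distributions, and population-genetic summaries of inbreeding and
diversity. Every stage has a seeded synthetic-data generator with a truth
table, so each estimator is exercised as a parameter-recovery problem.
This vignette records the models, their assumptions, the tunable
parameters, and the places where the design was genuinely open.

## 1. Genome size from a k-mer spectrum

For a histogram of distinct k-mer counts by depth, the estimator is the
classic

$$\hat G = \frac{\text{total k-mer instances above the error valley}}
               {\text{peak coverage}}.$$

`find_main_peak()` takes the *valley* as the first local minimum of count
against depth (the boundary between the sequencing-error tail and the
coverage peak) and the *peak* as the count argmax beyond it. A monotone
histogram has no valley and is reported as an error advising a manual
cutoff; a one-bin (delta) histogram has peak at that bin and cutoff 0.
An optional 3-bin moving average (`smooth = TRUE`, off by default) is
available for ragged histograms.

One numerical subtlety justified a refinement. If per-k-mer depth is
Poisson with rate $\lambda$, the histogram mode sits near
$\lambda - \tfrac12$; at *integer* $\lambda$ the two flanking depths carry
equal probability, so the sample argmax is decided by sampling noise and
the resulting size estimate jumps by $1/\lambda$ (5% at 20×). The default
`peak_method = "poisson_fit"` therefore refines the integer mode into a
real-valued *peak coverage*: a mean-shift pass centres a window of
half-width $\max(2, \text{mode}/4)$ on the peak, and the Poisson rate is
then fit by matching the truncated mean over that window. On simulated
spectra this recovers the generating coverage to ~0.1% where the raw
argmax errs by 0–5% depending on the seed. `peak_method = "argmax"`
preserves the plain total/mode reading.

Whether a real survey's "total number of k-mers" excluded the error tail
is rarely stated; here the cutoff is explicit (`low_depth_cutoff`,
default the detected valley) and reported alongside the estimate.
Heterozygosity estimation from the spectrum is intentionally out of
scope: it requires a two-peak mixture model this package does not fit.

## 2. Dating LTR-RT insertions

A full-length LTR retrotransposon carries two terminal repeats that were
identical at insertion. Each repeat then accumulates substitutions
independently, so for a pairwise divergence $K$ and neutral rate $r$
(substitutions/site/year) the insertion time is

$$T = \frac{K}{2r}, \qquad
  K = -\tfrac34 \ln\!\left(1 - \tfrac43 p\right),$$

with $p$ the per-site mismatch fraction over gap- and N-free aligned
columns (excluded from numerator *and* denominator) and the Jukes–Cantor
correction undefined at $p \ge 3/4$ (the element is reported saturated
and undatable). The default $r = 1.33\times10^{-9}$ is the conventional
neutral rate for Solanaceae. Rate literature sometimes quotes such rates
per *generation*; with a multi-year generation time the two readings
differ severalfold. The formula here treats $r$ as per year — the unit
the $T = K/2r$ conversion itself requires — and `r` is an explicit
argument, so a per-generation rate can be supplied directly if that
convention is wanted.

Alignment is an in-package affine-gap Needleman–Wunsch (Rcpp): match +1,
mismatch −1, gap open −2, gap extend −0.5, with deterministic
tie-breaking (diagonal, then the gap consuming the first sequence). A
dedicated aligner, rather than an external multiple-alignment tool, keeps
the distance computation exactly reproducible and lets short-string tests
compare against an exhaustive alignment-enumeration oracle.

Solo-LTRs — single repeats left behind when unequal recombination excises
the element body — are screened by the interval rule alone: a candidate
segment is solo iff it overlaps no full-length element by ≥ 1 bp
(half-open intervals, so abutting segments do not overlap). Upstream
homology search for candidates is out of scope; candidates are inputs.
`solo_paired_ratio()` and `superfamily_masses()` reproduce the study-style
summaries (ratios and percentages reported to 2 decimals).

`transposition_rate_curve()` bins dated insertions into half-open 0.1-My
bins over a 10-My horizon (both configurable) and accumulates them from
the present backwards. A single genome snapshot shows only *surviving*
elements, so "insertion rate" here means insertions-per-bin of survivors;
deaths are unobservable and no survival correction is attempted.

The landscape generator plants non-overlapping elements into a random
genome, mutating the two repeat copies independently under substitution-only
JC69 for age $t$ (per-branch expected substitutions $r\,t$, pairwise
$2rt$). Substitution-only mutation makes the closed-form expectation
exactly testable; real LTR pairs also accumulate indels and nested
insertions, which are exercised only by hand-built fixtures, so recovery
tests say nothing about indel-heavy or nested elements. Recovery under
the study conditions (500 elements, 5-kb repeats, ages uniform on 0–5 My)
dates the cohort mean to well within 5%; *per-element* times at young
ages are binomial-noise limited (a 0.1-My-old 5-kb pair expects ~1.3
mismatches), which is why accuracy is asserted for the cohort mean, not
per element.

## 3. Ks distributions and WGD dating

Ks is estimated with the Nei–Gojobori (1986) method: per-codon fractional
synonymous sites averaged over the two sequences; codons differing at
several positions resolved over all orderings of the single-base steps,
orderings through stop codons discarded (all retained if every ordering
is blocked); mutations *to* stops counted as nonsynonymous in site
counting; proportions JC-corrected with the same 3/4 saturation bound.
The study tradition uses maximum-likelihood yn00 for this step; NG86 was
chosen because it is fully specifiable and testable — the per-codon-pair
site and pathway counts are compared against an exhaustive enumeration
oracle for all 61 × 61 sense-codon pairs. NG86 ignores
transition/transversion and codon-usage bias, so its Ks is slightly
compressed relative to yn00 at high divergence; all downstream numbers
(peak locations, proportional dates) are internally consistent on the
NG86 scale, and the paralog-pair generator *targets a measured Ks* —
substitutions are applied until the NG86 estimate first reaches the
sampled target, and the realized value is the truth — so recovery tests
are free of estimator-scale mismatch by construction.

Collinear blocks are maximal chains of gene-order anchors, strictly
increasing in one genome's rank and strictly monotone in the other's
(same or inverted orientation), with consecutive anchors within
`max_rank_gap = 25` on both axes. Chains are extracted greedily by
repeated longest-chain dynamic programming; each anchor joins at most one
block, and blocks need `min_anchors = 5` (the `-s 5` convention of
standard synteny callers). The first extracted chain is provably maximal —
tests compare it with a memoized brute-force oracle on random instances.
Tandem pairs (same chromosome, rank distance ≤ 5) are removed before Ks
analysis; the rank-gap definition of "tandem" is a documented stand-in
for the varied definitions in the literature. Block Ks is the median over
non-saturated anchors (even counts: mean of the middle two; all
saturated: undatable).

Peaks are read from a Gaussian KDE on $(0, k_{max}]$ (default
`ks_max = 2`), Silverman bandwidth unless overridden, 512-point grid;
peaks are strict local maxima with height ≥ 5% of the global maximum (the
floor suppresses KDE ripple). This mirrors how Ks peaks are read off
published distributions; no mixture model is fit, so a reported peak
location is a grid mode, not a fitted component mean. Dating is
proportional: with the core-eudicot γ triplication as calibration
($K_s = 1.51$ at 117 Mya),

$$t_{event} = t_{cal}\,\frac{K_s^{event}}{K_s^{cal}},$$

so a recent peak at 0.125 dates to 9.69 Mya. The conversion assumes a
shared, constant synonymous clock across events. Syntenic depth ratios
summarize block coverage: each gene's depth is the number of blocks
spanning it, and the ratio of modal nonzero depths (e.g. 2:1) flags a
lineage-specific WGD.

## 4. Inbreeding, selfing and diversity

The SNP filter cascade applies, in order: (1) biallelic sites with
QUAL ≥ 20; (2) per-genotype masking when depth falls outside the open
band (site-mean/3, 3 × site-mean) or GQ < 10 (depth and GQ are retained
for masked calls, which makes the cascade idempotent); (3) sites within
5 bp of an indel dropped; (4) missing fraction > 0.3 dropped (the
`max-missing 0.7` convention — a conflicting "<20% missing" phrasing in
the source pipeline is taken as a typo for this setting); (5) MAF < 0.05
dropped; (6) exact Hardy–Weinberg test p < 0.001 dropped; (7)
repeat-masked sites dropped. Each rule's removals are counted. The HWE
test is the Wigginton-style conditional exact test, computed in log-space;
the choice of *exact* test is this package's, as the source pipeline
names only a threshold.

Per-individual inbreeding uses the moment estimator
$F_i = 1 - O_i/E_i$, observed heterozygous calls over the Hardy–Weinberg
expectation $\sum 2\hat p(1-\hat p)$ across the individual's non-missing
sites — a deliberate, documented substitute for GCTA's SNP-based
estimators, which agree with it to well within the ±0.03 recovery
tolerance at 30 × 50k sites. The selfing rate is the equilibrium
conversion $s = 2F/(1+F)$, strictly increasing on $(-1,\infty)$ and
mapping $[0,1]$ onto $[0,1]$; $F = 0.84 \mapsto s = 0.91$ and
$F = 0.0005 \mapsto s = 0.001$ bracket the reported range. One caveat the
analysis scripts demonstrate: in a strong selfer the HWE rule removes
precisely the heterozygote-deficit sites, biasing $\hat F$ downward
(0.61 vs a truth of 0.84 in the bundled run), so inbreeding is best
summarized from a cascade with that rule disabled
(`filter_config(hwe_alpha = NA)`).

Windowed nucleotide diversity follows the vcftools convention: per-site
$\pi = ab/\binom{a+b}{2}$ over the non-missing alleles (alt count $a$,
ref count $b$), summed over a 50-kb window and divided by the window
*length* (monomorphic and unobserved positions contribute zero), stepping
25 kb; only full windows are reported, in BED-like half-open coordinates.
Equality with an $O(n^2)$ haplotype-pair oracle is asserted on small
cohorts, including missing data.

The genotype generator draws independent sites at inbreeding-equilibrium
frequencies — $P(\text{het}) = 2p(1-p)(1-F)$ and so on — which captures
the heterozygosity deficit but none of the linkage, population structure
or allele-frequency-spectrum shape of real cohorts; passing recovery
tests therefore validates the estimators' arithmetic, not their behaviour
under structure or LD.

## 5. Coordinates, formats and other conventions

On-disk interval formats are 1-based inclusive (VCF/GFF style) except
BED; all in-memory intervals are 0-based half-open, converted exactly
once at the I/O boundary. The LTR element table is this package's own
nine-column TSV (documented in the README) rather than any detector's
pass-list dialect; a converter is a deliberate non-goal. FASTA I/O goes
through Biostrings (with uppercasing and U→T), VCF reading through vcfR;
the VCF writer is a minimal GT:DP:GQ emitter for simulated cohorts.
N bases are accepted in sequences but excluded from every
distance denominator.

Problem sizes in the test suite are chosen to keep the full run at
desk scale while leaving estimators in their asymptotic regime: 500
elements × 5-kb repeats for insertion dating, 1,000 pairs × 300 codons
for Ks peaks, 30 individuals × 50k sites for F recovery, 100 random
instances ≤ 200 anchors for chaining optimality, $10^6$ k-mers for genome
sizing. Determinism is end-to-end: every generator takes a single seed,
and identical seeds give byte-identical outputs.

## Known limitations

* NG86 Ks, not yn00/ML: no transition/transversion or codon-usage
  correction; cross-method Ks comparisons should recalibrate.
* Insertion-rate curves count surviving elements only.
* The KDE peak reader reports grid modes; closely spaced events closer
  than about one bandwidth merge.
* The exact-HWE filter is inappropriate for strongly selfing cohorts
  (see §4) — kept for fidelity to standard pipelines, with the disable
  switch documented.
* Generators omit indels, TE nesting, read-level error, linkage and
  demographic structure; recovery results bound arithmetic correctness,
  not robustness to those features.
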