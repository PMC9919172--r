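---
title: "Methods: diagnostic oak markers and Bayesian assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic oak markers and Bayesian assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oakdiff)
```

## The problem

*Quercus robur* (pedunculate oak) and *Q. petraea* (sessile oak) are the
two dominant white oaks of Central Europe. They hybridize, introgress
and overlap morphologically, so species determination from single
markers is unreliable. `oakdiff` implements a three-stage analysis that
turns pooled whole-genome sequencing of the two species into a small,
cheap diagnostic marker panel and a statistical assignment rule:

1. **Discovery** (`pooldiff`): reduce per-pool variant tables to fixed
   interspecific differences with a deterministic filter cascade.
2. **Genotyping** (`markers`): type individuals at a six-variant panel
   spread over four small amplicons, using CAPS restriction digestion,
   InDel amplicon sizing or Sanger reading — all also available as
   in-silico operators on sequence templates.
3. **Assignment** (`assign`): score each multilocus genotype against
   *Q. robur*, *Q. petraea* and hybrid reference panels with a Bayesian
   predictive likelihood, and guard against false positives with a
   Monte-Carlo exclusion probability.

A fourth module (`fixtures`) generates seeded synthetic data with the
statistical structure the analysis assumes, so that every stage is
testable without access to the original sequencing runs.

## Discovery: the fixed-difference cascade

The input is one variant table per pool (SNVs, MNVs of at most two
bases, and short InDels, against the *Q. robur* reference), plus a
per-position coverage track for the *Q. robur* pool. After merging on
the variant key (reference, position, reference allele, alternative
allele), four ordered stages are applied:

1. keep variants with a **100% alternative allele frequency** in the
   *Q. petraea* pool;
2. keep variants with *Q. petraea* coverage **≥ 13** reads;
3. remove variants with **no mapping coverage** in the *Q. robur* pool;
4. keep variants with a **100% reference allele frequency** and
   coverage **≥ 5** in the *Q. robur* pool.

The thresholds (13, 5, 100%, 100%) are the package defaults in
`filter_thresholds()`. Frequencies are compared exactly after rounding
to one decimal — fixation is a definition here, not a tolerance band; a
pool with one discordant read fails the stage. Stage counts are reported
after every step (`cascade_report`), because with real data the shape of
the count chain is the first sanity check. Whether the two robur-side
conditions of stage 4 are applied jointly or sequentially is not
observable from the published narrative; the cascade applies them
jointly and reports both the no-coverage removals and the final count.

Mapping parameters of the original pools (length fraction 0.94,
similarity fraction 0.98, nominal 29X / 19X depths) are carried as
provenance only and never enter any computation.

## The marker panel

Four primer pairs give amplicons under 200 bp; they carry six
diagnostic variants:

| Region | Method | robur | petraea |
|---|---|---|---|
| QP_miSeq14a (2 SNPs) | MboI CAPS | uncut 187 | 80 + 107 |
| QP_miSeq32 (InDel)   | amplicon sizing | 188 | 193 (insertion GCTTC) |
| QP_miSeq36 (SNP)     | MseI CAPS | 86 + 83 | uncut 169 |
| QP_miSeq38 (2 SNPs)  | Sanger | G, A | A, C |

The published contract for each region is its primer sequences, variant
alleles and fragment sizes — not the internal amplicon layout. The
template generator therefore *chooses* a layout that satisfies the
printed sizes and records it in a sidecar manifest: the MboI site GATC
occupies amplicon offsets 81–84 of QP_miSeq14a (cut before the G gives
80 + 107), the MseI site TTAA occupies offsets 86–89 of QP_miSeq36 (cut
T^TAA gives 86 + 83), the QP_miSeq32 insertion sits at offset 100, and
the QP_miSeq38 SNPs at offsets 90 and 120. Filler sequence is
seeded-random and rejected until each primer occurs exactly once in PCR
orientation and no spurious recognition site falls inside an amplicon.
QP_miSeq36's primers bind the reverse complement of the reference, so
its template is stored on the minus strand and its marker-orientation
alleles (T/C) are the complement of the reference-orientation alleles
(A/G); `extract_amplicon()` re-orients products so the forward primer is
always at the 5' end.

Primer matching is exact on both strands. No mismatch tolerance is
modelled: the published panel was validated by real PCR, and the
in-silico operators exist to type *known* templates deterministically,
not to predict hybridization.

Genotype calling maps physical observations onto allele pairs. CAPS
heterozygotes show the union of both alleles' fragment patterns;
ambiguous patterns give a *missing* genotype with a warning rather than
a forced call. The paired SNPs of QP_miSeq14a and QP_miSeq38 are typed
as two separate columns, as in the published genotype table, but the
generator co-assigns their classes (an individual heterozygous at one is
heterozygous at the other), which is how the validation data behave.
Sanger mode accepts IUPAC two-base codes as heterozygotes and is
additionally allowed for the CAPS regions, since any SNP amplicon can be
sequenced.

The two QP_miSeq14a SNPs fall in the coding sequence of a putative
detoxification 56-like gene on the minus strand. `coding_effect()`
applies variants, translates both alleles and reports the first
differing residue; on the synthetic CDS fixture (random sense codons
with only the variant codon constrained) the petraea alleles convert
alanine to threonine at protein position 125. The fixture is synthetic:
it reproduces the annotated *effect*, not the real gene sequence.

## Reference panels from published class frequencies

The validated reference sets comprise 39 *Q. robur* and 45 *Q. petraea*
individuals (77 per species at the InDel region, where extra individuals
were typed at that marker only) plus 20 hybrids. Only genotype-class
*percentages* are published, so the generator reconstructs integer
counts by largest-remainder apportionment and rejects any class whose
realized percentage deviates more than one point. Largest-remainder
rounding is also used when summarizing panels, because it reproduces the
published rows exactly where plain rounding does not (e.g. 33/5/1 of 39
prints as 85/13/2). One published row — 81/15/4 of 45 — is not
realizable by any integer counts (45 × 0.81 = 36.45; 36 and 37
individuals give 80% and 82%); the generator uses the closest
realization (36/7/2 → 80/16/4), within one point per class. The
Caucasus-origin *Q. petraea* allele (the 188-bp InDel variant on a
petraea background) needs no special handling: the published petraea
188/188 and 188/193 classes already encode it.

The multilocus composition of individuals is not published, only
per-marker margins; classes are therefore shuffled independently across
individuals within each region (seeded). This assumes linkage
equilibrium between regions — they lie on different chromosomes — while
preserving the exact per-marker margins.

The true genotypes of the 20 reference hybrids are likewise unpublished.
The default hybrid panel is 20 seeded F1 simulants: at each locus one
allele is drawn from each species panel's posterior-mean allele
frequencies \((n_a + 1/k)/(n + 1)\). F1 is the conservative choice
consistent with "first or next generation" hybrids; backcrosses are
available (`simulate_hybrid(..., "backcross")`) and users can substitute
their own hybrid genotype CSV. Real reference hybrids include later
generations and are less uniformly heterozygous than F1s; conclusions
about hybrid *power* from the synthetic panel are therefore optimistic
and the package makes no claim beyond internal consistency.

Pool coverage noise is Poisson around the nominal 29X / 19X depths
(conditioned to the stated minima for planted survivors) — the only
depth information available; real short-read coverage is overdispersed,
which does not matter here because the cascade thresholds coverage
deterministically.

## The assignment model

For a reference group with allele counts \(n_a\) (total \(n\)) at a
locus with allele universe size \(k\), the predictive probability of a
genotype integrates the unknown population allele frequencies over
their Dirichlet posterior. With per-allele prior \(\tau\) and
\(S = k\tau\):

\[
P(a/b) = \frac{2 (n_a+\tau)(n_b+\tau)}{(n+S)(n+S+1)}, \qquad
P(a/a) = \frac{(n_a+\tau)(n_a+\tau+1)}{(n+S)(n+S+1)} .
\]

These sum to one over the \(k(k+1)/2\) unordered genotypes for any
counts. The default prior is \(\tau = 1/k\) (the Rannala–Mountain
choice; the originally used software names that method as its source);
a flat Dirichlet(1) alternative is exposed as
`assignment_config(prior_style = "uniform")` because "equal probability
density of the allele frequencies" can also be read that way. The
allele universe \(k\) is the set of distinct alleles seen across *all*
reference groups plus the query, which keeps unseen query alleles at
positive (prior-only) probability — standard assignment-software
behaviour.

Loci are treated as independent; the multilocus log-likelihood is the
sum over the sample's non-missing loci, skipped symmetrically in every
group. Samples typed at fewer than four loci are rejected
(`min_typed = 4`). Scores are likelihoods normalized across the three
groups, computed in log space with max-subtraction; the assigned group
is the argmax, and exact ties are reported rather than broken silently.
The hybrid group is an ordinary third reference population with its own
allele counts — no explicit admixture model is fitted.

### Exclusion probability

To guard against assigning a sample to the best of three wrong groups,
the package simulates `n_sim` (default 10,000) genotypes from the tested
panel — two alleles per typed locus, drawn independently from the
posterior-mean frequencies — and reports the fraction whose
log-likelihood *strictly* exceeds the query's. Values near 1 mean the
query is atypical of the panel; below 0.95 a false positive is deemed
improbable. The originally used implementation is unpublished; drawing
from posterior means with a strict tail count is our documented
approximation, so published per-sample exclusion values are not exact
targets. Two consequences of this design are worth noting: a query
identical to the modal genotype of a monomorphic panel has exclusion
exactly 0 (nothing can be strictly more likely), and for panel-typical
queries the exclusion probability is approximately Uniform(0,1) by the
probability-integral-transform argument — approximately, because the
genotype space is discrete and likelihood ties accumulate at strongly
differentiated loci. The uniformity property is exercised in the tests
on balanced multi-allelic loci where ties are rare.

Simulation uses per-locus genotype-probability lookup tables, so
exclusion for a full self-assignment run costs seconds. All Monte-Carlo
steps accept a seed; identical seeds give identical results.

### Self-assignment and reporting

`self_assignment()` scores every sufficiently typed panel member,
optionally removing it from its own panel first (leave-one-out, the
default, which avoids circularity; whether the original analysis did so
is not stated, so both modes exist). Members typed only at the InDel
region contribute to allele counts but are not scored. Reports carry
divergent-marker notes relative to the sample's species group —
"36 hetero", "36 homo QR", "14 missing" — with scores rounded to three
decimals in TSV output and kept at full precision in JSON.

## Numerical and size choices

Frequencies compare exactly after one-decimal rounding; likelihood ties
use a 1e-9 log tolerance; the exclusion tail count uses a strict
inequality with the same tolerance. Test problem sizes are chosen to
keep the default suite under a minute of computation while leaving
Monte-Carlo margins comfortable: 200-row cascade fixtures, 500
uniformity replicates at 1,000 draws in the module tests (300 × 800 in
the acceptance suite), 200-member simulated panels for the
misassignment bound, and 1,500 draws for the F1 closed-form check.
Exclusion simulations in self-assignment demonstrations use reduced
draw counts where only argmax scores matter, since exclusion does not
influence assignment.

## Known limitations

* Discovery starts from variant tables; variant *calling* from
  alignments, read simulation and mapping are out of scope, so the
  published raw-data count chain (4678 candidate variants and its
  subsequent reductions) is not reproducible at desk scale — the
  cascade is instead validated by exact planted-truth recovery.
* Primer thermodynamics, BLAST specificity screening and the editorial
  curation steps of the original marker selection (75 → 38 → 26 → 10 →
  4 primer pairs) are not modelled; a retained panel is simply declared.
* The exclusion algorithm is a documented approximation of unpublished
  software; per-sample published exclusion values are indicative only.
* Synthetic templates reproduce published lengths and sites, not the
  real genomic sequence; synthetic hybrid panels are F1-biased.
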