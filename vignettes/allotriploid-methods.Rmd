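---
title: "Subgenome-resolved analysis of an allotriploid complex: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgenome-resolved analysis of an allotriploid complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allotriploid)
```

This vignette is the package's own account of the statistical models it
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the places where the design was genuinely
open and a choice had to be made.

## The system and its coordinate conventions

The object of study is a four-genotype complex: two diploid inbred parents
(2nRR, red crucian carp; 2nCC, common carp) and their two reciprocal
allotriploids, 3nR₂C (subgenome copy numbers R:C = 2:1) and 3nRC₂ (1:2).
Absent a triploid assembly, all quantities are computed against the
combined parental genomes, and the parental orthologs serve as the
homoeolog coordinate system inside the triploids.

All internal coordinates are 1-based inclusive; BED input is converted at
the boundary, once. Gene exons are stored 5′→3′ in transcript orientation,
so minus-strand genes have `tss > tts` genomically. Cytosine-report context
tokens are normalised (`CG` → `CpG`); an unknown token is a hard error, not
a skip, because silently dropped records hide strand/context bugs upstream.

## Homoeolog catalogue

Reciprocal best hits are computed from 12-column tabular similarity-search
hits plus a query-length table. A pair survives iff each gene is the
other's highest-*bitscore* hit and both directions pass e-value < 1e−5,
query coverage ≥ 0.80 and aligned length ≥ 300 bp. Bitscore (not e-value)
defines "best" because it is comparable across query lengths; e-value ties
fall back to percent identity, then lexicographic subject order for
determinism.

Orthologous chromosome pairing is a deliberate simplification of
collinearity analysis: candidate pairs vote for their
(chrom_R, chrom_C) combination and a greedy one-to-one matching repeatedly
takes the largest count, breaking ties lexicographically. On genomes with
clear one-to-one chromosome ancestry (the case here) the greedy matching
coincides with the maximum-weight matching; a dynamic-programming synteny
block model would change no downstream statistic, which is why it was left
out. RBH pairs whose chromosomes disagree with the vote are discarded —
this is also how many-to-many RBH conflicts across chromosomes are
resolved, which is one reading of "consistent with orthologous
chromosomes"; the alternative (keeping them) would only add pairs that the
read-ratio module cannot anchor to a chromosome pair anyway.

## Methylation model

**Error rate.** The bisulfite non-conversion error is estimated from the
unmethylated lambda spike-in as pooled Σmeth/Σcoverage over all contexts.
An estimate ≥ 0.05 triggers a warning (a failed conversion makes every
downstream call suspect).

**Site calling.** Per site, p = P(X ≥ n_meth | n = coverage, p₀ = error)
— a one-sided exact binomial tail — with Benjamini–Hochberg correction
across the tested sites of a sample. "Tested" means coverage ≥ 5: the
source protocol demands coverage strictly greater than 4×, and the strict
inequality is kept as printed. Sites below the threshold are never called
and carry `NA` q-values.

**Region levels.** The default is coverage weighting
(Σmeth/Σcoverage over the covered CpGs of the interval), matching the
pooled-count DMR test; site weighting (mean of per-site levels) is
available because the source describes only an "average". The two differ
exactly when coverage is uneven — a (9/10, 0/90) pair of sites reads 0.09
coverage-weighted but 0.45 site-weighted — and the choice is therefore
exposed, not hidden.

**Binned profiles.** Each gene element (2 kb upstream, first/inner/last
exon, first/inner intron, gene body, 2 kb downstream; transposon body and
± 2 kb flanks) is split into 20 equal-length bins along transcript
orientation, concatenating multi-interval elements (e.g. inner exons) into
one axis. Genes lacking an element contribute nothing to it. Profiles pool
genes coverage-weighted: counts, not per-gene levels, are accumulated per
bin. Whether the original figures weighted genes equally is not stated;
coverage weighting was chosen for consistency with every other pooled
statistic in the package.

**DMRs.** Dedicated shrinkage-based DMR callers model biological variance
between replicates; this package instead uses an exactly testable
pooled-count design: non-overlapping 100 bp windows, replicate counts
pooled per group, a two-sided Fisher exact test on the pooled 2×2 table,
BH across windows with ≥ 4 covered CpGs, and a |Δ| ≥ 0.1 effect floor,
merging adjacent significant windows. The source's DMR threshold is
described in terms of an e-value, which has no analogue in a Fisher
framework; FDR < 0.05 is used instead and the discrepancy is simply
documented rather than guessed at. Pooling sacrifices replicate-variance
modelling for exactness; with three replicates per genotype and
beta-binomial overdispersion in the generator, this makes the window test
mildly anticonservative for biological inference — acceptable for a
deterministic, fully specified pipeline stage, and the reason DMR counts
should not be over-interpreted.

## Promoter divergence, DMGs and recombinant genes

Per homoeolog pair, `d_parent` is the promoter (2 kb upstream,
replicate-pooled, coverage-weighted) methylation level of the R gene in
2nRR minus the C gene in 2nCC; `d_triploid` is the R-minus-C homoeolog
difference within each triploid. Divergences are kept signed; thresholds
apply to absolute values.

Per triploid: **hyper-DMG** iff |d_parent| > 0.6 and |d_triploid| < 0.3;
**hypo-DMG** iff 0 < |d_parent| < 0.6 and |d_triploid| < 0.2. The hypo
lower bound is 0 by default — the procedural definition — with a
`hypo_parent_lower = 0.4` switch reproducing the narrower variant that
appears in some summaries of the same analysis; the procedural reading was
preferred because it is the one stated as a method.

A pair is a candidate **HRG** when its class is identical and non-none in
*both* triploids: a promoter exchange in the shared tetraploid ancestor
collapses homoeolog divergence in both derived triploids at once. The
weaker reading — any non-none class in both, not necessarily the same —
would only add pairs whose evidence disagrees between triploids; the
strict reading was chosen. Note the hypo class at its default lower bound
of 0 also captures pairs that were never divergent; the class is a
candidate set, and the read-ratio module provides the orthogonal,
copy-number-based evidence.

## Read-ratio recombination statistic

For a pair with reads per kb d_R and d_C, the statistic is
log₁₀(d_R/d_C), compared with the analytic line log₁₀(copy_R/copy_C)
(0.30103 in 3nR₂C, −0.30103 in 3nRC₂). The significance band is the line
± log₁₀(2) — the value implied by the four printed boundary lines
(0 and 0.60206; −0.60206 and 0), i.e. a two-fold departure, exactly one
exchanged copy. The half-width is exposed as a parameter because the rule
is inferred from those four values, not stated.

Pairs with total reads < 20 are undefined and never flagged. A pair with
one zero side is *not* given a pseudocount: a 3:0 exchange is real but its
ratio is unbounded, so it is reported in a separate one-sided channel.
At 30 reads/copy/kb a true (2:1) pair has a log-ratio standard deviation
of roughly 0.08 for a 1.5 kb gene, putting the band at ≈ 3.8σ — which is
what makes ≥ 0.9 recall at ≤ 0.05 false positives attainable for
one-copy exchanges.

The positional trend is a first-degree local regression with tricube
weights over the nearest ⌊span·n⌋ points (span 0.3), evaluated at every
input position — deterministic, with no sampling involved.

## Expression and the dosage scaling test

**TMM** is implemented as the published trimmed-mean-of-M-values
procedure: reference = sample whose library-scaled upper quartile is
closest to the mean; per sample, M/A values on doubly-positive features;
30 % of M and 5 % of A trimmed symmetrically; inverse-delta-method
(binomial) variance weights; factors scaled to geometric mean 1. The
reference implementation in the wider ecosystem is used as an independent
oracle in the test suite, never as the implementation.

**DE** uses a common negative-binomial dispersion estimated by the method
of moments on library-equalised counts (median across features, floored
at 1e−4) and an exact NB test conditional on the pooled two-group sum,
summing the probabilities of all outcomes at most as likely as the
observed one. A call requires |log₂FC| > 1 (fold change from mean CPM
with pseudocount 0.5) *and* FDR below threshold (0.05 for mRNA, 0.01 for
miRNA). Common — rather than tagwise/trended — dispersion is a documented
simplification; under the generator's constant-dispersion model it is also
correct.

**Dosage scaling.** For k ∈ {1, 2, 4}, log₂(k·x + 1) of a triploid
subgenome is compared with log₂(y + 1) of its parent; verdict *equal* when
p > 0.05, otherwise the sign of the mean difference. Two design points
matter and both were genuinely open:

1. *Normalisation.* The inputs must be whole-library CPM. Normalising
   within the tested subgenome — or TMM-normalising the triploid against
   the parent — removes precisely the global shift the test measures,
   because a uniformly compensated subgenome looks like a library-size
   effect. TMM is kept for DE, where that behaviour is the point.
2. *Paired vs unpaired.* The test defaults to Welch's two-sample
   comparison of the per-gene value distributions. A paired test across
   thousands of genes is so powerful that it flags percent-level
   library-composition offsets (the triploid's total library is the mean
   of the two parental totals, not the parent's own) that have nothing to
   do with dosage; the figure being reproduced is a boxplot-with-t-test,
   i.e. a distribution-level comparison. Paired mode remains available.

Under the generator's *compensated* model every present subgenome is
expressed at half its parental per-two-copy mean — so ×1 reads lower, ×2
equal, ×4 higher, and the subgenome-summed triploid total equals the mean
of the parental totals. The alternative parameterisation (splitting a
parental total R:C by copy number) was rejected because it cannot
reproduce the ×2-equals-parent observation that defines compensation in
this system: doubling a 2/3 share gives 4/3 of the parent, not 1. The
*uncompensated* model scales each subgenome by copy_number/2, and
*partial* interpolates linearly by α.

## miRNA module

Dedup is exact identity after uppercasing and U→T normalisation,
first-seen id kept. Patterns are a pure function of the per-subgenome
locus counts: (2,2)→P1, (1,2)→P2, (2,1)→P3, (1,1)→P4, (2,0)/(0,2)→P5R/P5C,
(1,0)/(0,1)→P6R/P6C; anything outside {0,1,2}² is reported as `other`
rather than forced into a diagram — never silently misclassify. Locus
counts are summed per miRNA across both subgenomes before DE because the
copies are sequence-identical and reads cannot be attributed to one locus.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, not
the sequences:

- **Methylation**: per-CpG coverage ~ Poisson(20 by default); methylated
  counts beta-binomial around the planted mean with precision 50 — a
  binomial generator would make replicate-based tests unrealistically
  easy, so overdispersion is explicit and tunable. Parental promoter
  divergence per gene follows a three-stratum mixture (55 % in [0, 0.4),
  25 % in [0.4, 0.6), 20 % in [0.62, 0.95)) so that hyper-, hypo- and
  non-DMG strata are all populated; gene bodies, downstream flanks and
  transposons get constant levels (0.7 / 0.7 / 0.9). A lambda contig with
  planted non-conversion error 0.005 (0.5 %, a realistic spike-in error)
  gives the error-rate estimator a real target.
- **Recombination**: a planted event copies the donor homoeolog's promoter
  methylation onto the acceptor in *both* triploids (the event is
  ancestral) and moves one resequencing copy to the donor subgenome, with
  copy numbers floored at zero — so some events surface as one-sided 3:0
  patterns rather than band excursions, exactly as in the statistic's
  one-sided channel.
- **Expression**: NB counts (dispersion 0.05) around the dosage-model
  means; parents express only their own subgenome. Resequencing reads are
  Poisson(copies × 30 × kb).
- **Orthology**: hit tables are emitted directly with controlled
  scores/coverage (plus ~10 % lower-scoring decoys); sequence content is
  never simulated because the catalogue consumes hit tables.
- **miRNA**: locus counts per pattern default to the observed carp-complex
  pattern sizes (114/65/34/51/26/6/133/69).

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: sequence-level mappability and
alignment bias, CHG/CHH methylation biology beyond the spike-in contexts,
tagwise dispersion variation, batch effects, chromosome-scale synteny
breaks, and the coupling between methylation and expression (the
generator's DE and DM are independent, so DE–DM quadrant counts on
simulated data measure the join logic, not biology).

## Problem sizes and determinism

Everything is a deterministic function of the scenario, which carries a
single seed; component generators derive fixed sub-seeds so that the
methylation, expression, resequencing and miRNA layers can be regenerated
independently. The test suite runs the default analyses at desk scale —
a few hundred gene pairs for end-to-end checks, 2 000 pairs for the
dosage-recovery study, 5 000 pairs with 200 planted exchanges for the
read-ratio recovery study, 1 000 features for the DE null calibration —
sizes chosen so each property is measured with comfortable statistical
margin.

## Known limitations

- The Fisher window DMR test ignores replicate variance (see above).
- The OCP vote assumes an essentially one-to-one chromosome
  correspondence; fission/fusion histories would need true synteny blocks.
- The dosage test's verdict at ×2 is an acceptance of the null; with few
  genes it has limited power to distinguish partial from full
  compensation.
- HRG candidacy via the hypo class is permissive at the default lower
  bound (0); pairs with little parental divergence are indistinguishable
  from collapsed ones by methylation alone. The read-ratio module is the
  discriminating evidence.
- Copy-number patterns above two loci per subgenome are reported as
  `other`, not classified.
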