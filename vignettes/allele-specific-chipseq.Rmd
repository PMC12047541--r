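---
title: "Quantifying cis-effects of genetic variation on TF binding with aschip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cis-effects of genetic variation on TF binding with aschip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aschip)
```

## The measurement and its two failure modes

In an F1 hybrid of two inbred lines, every variant differing between the
parents is heterozygous with fully resolved phase. ChIP-seq reads covering a
phased heterozygous site can therefore be assigned to the maternal or the
paternal haplotype, and a departure of that assignment from 50:50 measures a
cis-acting effect of genetic variation on transcription-factor occupancy,
with the trans environment internally controlled.

Two artefacts can masquerade as such an effect. *Reference mapping bias*:
reads carrying non-reference alleles align worse to the reference, and the
loss grows with allele length — an unhandled 10 bp deletion can eliminate
most alternative-haplotype reads at a locus. *Duplicate filtering bias*:
keeping the "best" read among duplicates systematically favours
reference-matching copies. The bias filter addresses the first by allele-swap
remapping; seeded random duplicate selection addresses the second.

## The bias filter

For every read pair whose aligned span intersects a variant, all `2^h`
allele assignments over the `h` overlapped biallelic variants are
enumerated (capped at 64 versions; pairs above the cap are dropped). Each
mate's sequence is rebuilt from the corresponding haplotype, anchored at the
mate's strand-aware 5' reference coordinate and kept at the original read
length, so an indel shifts the read's far end into flanking haplotype
sequence rather than truncating it. A pair survives only if *every* version
of *both* mates remaps uniquely, with mapping quality strictly above 10, to
the original chromosome, strand and 5' anchor. Drop reasons are recorded as
`unmapped`, `multimapped`, `low_mapq` or `moved`.

Three design points deserve note:

* **"Same position" is compared per mate at the 5' anchor.** A version
  carrying a deletion spans more reference than the original read, so its
  leftmost coordinate legitimately differs on the minus strand; the 5' anchor
  (leftmost base for plus-strand mates, rightmost for minus-strand mates) is
  invariant under the rebuild and is what we require to match.
* **The cap counts all versions including the original assignment**, which
  must itself pass the remap test — this guards against unstable loci.
* **Aligners are pluggable.** `bwa_aligner()` drives `bwa mem` and is the
  production choice; `mismatch_aligner()` (ungapped, substitution-tolerant)
  and `exact_aligner()` are pure-R implementations of the same interface
  used for desk-scale experiments. The ungapped aligner intentionally
  reproduces the failure mode of gap-unaware mapping — indel-carrying reads
  go unmapped — which is how the test suite demonstrates that the filter
  removes the resulting bias (post-filter allelic ratios at SNPs flanking a
  4 bp deletion return to 0.5 within binomial error).

## Counting

Consensus peaks are merged intervals (1 bp overlap, transitive) supported by
at least three lines, with the summit recomputed as the pooled-coverage
argmax (leftmost on ties). Target regions are summits ± 2.5 kb, and every
panel variant inside a region is a candidate test variant, subject to four
inclusive filters taken as defaults from the upstream tooling conventions:
total reads across samples ≥ 400, summed allele-specific reads ≥ 50, het
samples ≥ 1, minor-allele copies ≥ 1.

Allele-specific counting is fragment-level: a fragment contributes at most
one observation per region, taken at its highest-base-quality informative
het site (leftmost on ties), with overlapping mates counted once. Base calls
below quality 10 are ignored — the threshold mirrors the spirit of the
mapq > 10 remap rule; it is configurable. SNP alleles are read through the
CIGAR; indel alleles are called by exact presence of the local haplotype
context (5 bp flank + allele + 5 bp flank) in the read sequence. The context
form is deliberate: gapped aligners left-shift or soft-clip indels, so a
CIGAR-walk call silently misses alternative-allele reads and reintroduces
reference bias downstream of a clean mapping step (we observed ratios of
0.64–0.72 at indels with CIGAR calls, against 0.50 with context calls).
Reads matching neither context, or both (possible in short tandem repeats),
are excluded as "other".

Expected counts `E_i` allocate each region's pooled total to samples by
library-size share (optionally reweighted by per-sample fraction of reads in
peaks), corrected by a per-sample median observed/expected ratio within GC
quartile bins, and renormalised so `sum_i E_i = sum_i T_i` holds exactly per
region. The GC model is intentionally simple — any monotone correction that
preserves the per-region total satisfies the calibration tests; quartile
median-ratio scaling recovers planted bin factors within 10%.

## The combined haplotype test

For one (region, test variant) pair with per-sample totals `T_i`, expected
totals `E_i`, genotypes `g_i ∈ {0,1,2}` ALT copies and phased
allele-specific counts, both components share the effect parameter
`p = beta/(alpha+beta)`, the ALT-haplotype read probability:

* Allele-specific: for het samples,
  `k_i ~ BetaBin(n_i, p, rho_as)` with mean-overdispersion shapes
  `a = p(1-rho)/rho`, `b = (1-p)(1-rho)/rho`; `rho = 0` is evaluated as the
  exact binomial.
* Depth: for all samples, `T_i ~ NB(mu_i, phi_bnb)` with
  `mu_i = E_i ((2-g_i)(1-p) + g_i p)`; het samples are depth-uninformative
  (`mu_i = E_i`), as they should be. `phi = Inf` is evaluated as the exact
  Poisson, and an optional beta layer on the NB success probability gives
  the beta-negative-binomial.

The alternative model maximises the joint log-likelihood over `p` by bounded
one-dimensional optimisation (`p` clamped to `[1e-6, 1-1e-6]`, tolerance
1e-8) — with `alpha + beta` fixed by the allele-specific count scale, `p` is
the single free effect parameter, which makes the 1-df likelihood-ratio
test against the `p = 0.5` null well-defined. Non-convergence is flagged and
reported conservatively as `p-value = 1`; tests with no het sample and no
genotype contrast are skipped rather than given `p = 1`. Dispersions
(`rho_as`, `phi_bnb`) are genome-wide maximum-likelihood estimates under the
null across all regions (deterministic; falls back to documented defaults
below 50 regions, with a warning).

The exact parameterisation of the depth overdispersion is a package choice:
we validate it by calibration (permuted-genotype p-values uniform; FDR<0.01
& AI>0.1 calls ≤ 1% on null data) and by parameter recovery (true `p = 0.7`
recovered within ±0.05 at depth 2000) rather than by numerical identity to
any external implementation.

`permute = TRUE` shuffles genotype labels across samples independently per
test variant and randomises the haplotype orientation of the
allele-specific counts while leaving all counts fixed — the empirical null.
Replicates are treated as independent samples. FDR is Benjamini–Hochberg
within each component (full, AS-only, depth-only) across all tested
variants. Significance uses `FDR < 0.01` and `AI > 0.1`; peak-level calls
take the minimum-p variant, ties broken by larger AI then leftmost
coordinate, for reproducibility.

## Motifs

Variant-centered windows of 30 bp are scored on both alleles and both
strands; the alternative window is rebuilt through the haplotype machinery
and re-centered on the variant, so indels shift flanks rather than the
centre, and indel disruption is captured by full-window re-scan rather than
per-position alignment. A motif is "called" above the log-odds score whose
match p-value under the background model is 1e-4 by default (computed by
exact convolution of discretised per-position score distributions, step
0.001 bits). The default suits motifs of typical length; for very short
motifs the achievable p-values are coarser (a 6-mer has only 4096 background
words) and a looser threshold must be chosen explicitly.

For significant SNPs inside called motifs, the preferred allele is the one
on the fitted higher-occupancy haplotype, complemented and position-flipped
for minus-strand hits. Tallying preferred bases per motif position gives the
allelic-imbalance count matrix; with 0.25 pseudocounts per base,
`IC = 2 + sum_b f_b log2 f_b` bits and letter heights `f_b * IC` give the
information-content logo. Positions without variants stay as zero columns.

## pAI and saturation mutagenesis

Any sequence-to-coverage model exposing `predict(sequence) -> summed
coverage` over a fixed window can drive prioritization;
`pAI = pred(ref)/(pred(ref)+pred(alt))` on variant-centered windows, ranked
per peak by `|pAI - 0.5|` (ties: distance to summit, then coordinate). The
shipped reference predictor is a PWM-energy model,
`occupancy = sum over offsets and strands of exp(lambda * log-odds score)` —
deterministic, strictly positive, and exactly computable, which is what the
pAI and saturation-mutagenesis guarantees are tested against (reference-base
deltas identically zero; importance concentrated in the motif footprint;
rank-1 causal recovery beating a 10,000-draw permutation baseline at
empirical p < 0.001). The prediction window is a predictor property (toy
default 256 bp), not a constant of the method; the "sum" statistic is taken
over the full predictor window. Saturation mutagenesis substitutes all four
bases at each of the 151 positions in a ±75 bp window, normalises scores by
the mean absolute value, and reports per-position importance as the sum of
absolute deltas versus the reference base.

## The synthetic-data generator

The generator emulates the genetic structure such a study rests on: a
uniform-random genome with evenly spaced binding regions; a non-overlapping
biallelic panel at one variant per 230 bp with an 18% indel fraction
(geometric lengths, cap 20 bp — roughly 69% of indels ≤ 5 bp); homozygous
parents, eight F1 crosses sharing one maternal line (maternal ALT rate 0.3,
paternal 0.5, so about half the panel is het per line); 75 bp paired-end
reads from 300 bp fragments placed around summits. Imbalance modes: `null`
(p = 0.5), `fixed` (a chosen ALT-haplotype probability, anchored at the
variant nearest each summit), and `motif` (a planted consensus whose
disruption by a causal SNP sets p from the toy predictor's energies, giving
motif-level ground truth). Per-read haplotype of origin is recorded, and all
randomness flows from one seed through named child streams
(panel/reads/dedup/permute) so each stage is independently reproducible.

What the generator does *not* emulate — chromatin accessibility and
fragment-bias structure, repeat-driven mappability (beyond optional planted
duplications), sequencing error profiles, linkage beyond a single shared
maternal line, and trans effects — bounds what green tests show: the
pipeline is unbiased and calibrated under its stated model, not that any
particular biological dataset will meet that model.

## Problem sizes and numerical choices

The calibration suites run the full pipeline at 20 regions × 8 lines × 1000
fragments per region (about 20,000 read pairs), the scale at which the mean
null allelic ratio is estimated to within ±0.007 (binomial), comfortably
inside the ±0.02 acceptance band; model-level suites use counts-level
simulations of 100–300 regions. Optimiser tolerances are 1e-8 (effect
parameter) and 1e-7 (dispersions); beta-binomial and Poisson limits are
evaluated by exact branches rather than numerically. Degenerate inputs are
handled explicitly: single-GC-bin data fix the GC factor at 1 with a
warning, unphased het genotypes are an error unless parental phase is
asserted, overlapping variants are rejected with their ids (the stringent
panel such analyses use is non-overlapping by construction), and reads that
merely graze an indel's reference span receive context-dependent treatment
documented in the counting section.

## Known limitations

* The depth component's overdispersion parameterisation is validated by
  calibration, not uniqueness; other NB mixtures would pass the same tests.
* Context-based indel calls require locally unique flanks; in short tandem
  repeats both contexts can match and the read is discarded as ambiguous.
* The permutation scheme randomises genotype labels and haplotype
  orientation but keeps each sample's count magnitudes, so it conditions on
  the observed depth structure.
* Multiallelic sites, phase-unknown variants and soft-clip rescue are out of
  scope; the panel loader drops or rejects them explicitly.
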