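---
title: "Genotyping inversions from Strand-seq composites: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping inversions from Strand-seq composites: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandinv)
```

This vignette explains the model behind `strandinv`, the assumptions it
makes, the tunable parameters that matter, what the bundled simulator does
and does not emulate, and the numerical and design choices taken where the
problem left room.

## Why composites, and why two of them

Strand-seq sequences only the inherited template strand of each homolog in
each cell, so every (cell, chromosome) pair is in one of four strand
states: WW, WC, CW, or CC, where the letters give the strand (Watson = minus,
Crick = plus, in that order for haplotypes 1 and 2) on which each homolog's
reads appear. Individual cells are too sparse to genotype small inversions,
so reads are pooled:

* The **WW-type composite** collects WW regions as-is and CC regions with
  strands flipped. Reference-orientation sequence then reads almost
  entirely Watson; a homozygous inversion reads almost entirely Crick; a
  heterozygous inversion reads ~50/50.
* The **WC-type composite** collects Watson-Crick regions after phasing
  each library so haplotype 1 sits on Watson. Reference sequence reads
  ~50/50; a heterozygous inversion reads directionally, with the direction
  giving the phase; a homozygous inversion stays ~50/50.

The WC composite exists because two very different things look identical in
the WW composite: a genuine heterozygous inversion and a collapsed repeat
in the reference assembly (every cell shows WC there, regardless of
inheritance). Only the former switches strand in the WC composite, so
jointly modelling both composites lets the caller return an ambiguous call
rather than a false heterozygote at collapses.

## The genotype model

For a putative inversion, let `(n_W, n_C)` be the read counts of one
composite inside the interval (a read belongs to the interval iff its
start lies inside; deterministic at boundaries). Under strand state `s`
the Crick count is binomial with success probability `b` (state WW),
`1 − b` (CC), or `0.5` (WC/CW), where `b` is the composite background —
the fraction of mis-oriented reads. This gives per-composite strand-state
likelihoods `L(comp, s)`; with zero reads every state has likelihood 1.

Each genotype is a mixture over three error states — no error
(prior `P_none = 0.5`), always-WC (`P_AWC = 0.25`, the collapse state),
and missing/deletion (`P_del = 0.25`):

```
S_REF    = P_REF    [ ½ P_none L(ww,WW) L(wc,WC) + P_AWC L(ww,WC) L(wc,WC)
                      + ½ P_del L(ww,WW) (L(wc,WW) + L(wc,CC)) ]
S_HET01  = P_HET/2  [ P_none L(ww,WC) L(wc,WW)   + P_AWC L(ww,WC) L(wc,WC)
                      + ½ P_del (L(ww,WW) + L(ww,CC)) L(wc,WW) ]
S_HET10  =          ... as S_HET01 with L(wc,WW) -> L(wc,CC)
S_HOM    = P_HOM    [ ½ P_none L(ww,CC) L(wc,WC) + P_AWC L(ww,WC) L(wc,WC)
                      + ½ P_del L(ww,CC) (L(wc,WW) + L(wc,CC)) ]
```

The ½ weights on the no-error and deletion terms of the phase-symmetric
genotypes (REF, HOM) are kept as a fixed convention of the model; the two
heterozygote phases share the heterozygote prior equally (`P_HET/2` each),
so `P_REF + P_HET + P_HOM = 1` holds for every prior set. Posteriors are
the softmax of the four log scores, and a call is *confident* when the
maximum posterior reaches the threshold (default 0.95); otherwise the call
is AMBIGUOUS. Note what the always-WC component does: it is identical
across all four genotypes, so when both composites read ~50/50 the
posteriors collapse to the renormalized priors and the call is ambiguous —
the desired behaviour at assembly collapses.

All mixtures are evaluated in log space with log-sum-exp; sums inside
log-sum-exp are performed on sorted addends so that model symmetries (the
heterozygote phase swap under a Watson/Crick exchange in the WC composite)
hold exactly in floating point, not just to rounding error.

## Parameters and defaults

| Parameter | Default | Meaning / rationale |
|---|---|---|
| posterior threshold | 0.95 | confidence gate for calls |
| `P_none`, `P_AWC`, `P_del` | 0.5 / 0.25 / 0.25 | conservative error-state priors |
| genotype priors | REF 0.9, HET 0.05, HOM 0.05 | neutral default; use frequency or catalogue priors when available |
| catalogue prior `n` | 100 (catalogue), 80 (de novo) | expected true inversions among the candidate intervals; de novo scans miss small events, hence the smaller n |
| background bin size | 1 Mb | enough reads per bin for a stable minority fraction |
| MAPQ floor | 10 | drops multi-mapping reads |
| min reads per background bin | 50 | below this the minority fraction is too noisy |
| WW/CC classification bins | 1 Mb, thresholds 0.8 / 0.2 | permissive at moderate background (a WW bin at b = 0.05 has Watson fraction ~0.95) |
| WC-region discovery bins | 20 Mb | coarse state calls for phasing |
| min reads per classification bin | 20 | below this a bin is `unknown` and excluded |
| detector windows | 40/120/360 reads, minReads 15/50/50 | three scales targeting small/medium/large events |
| adjustment radius | half the interval length, capped at 1 Mb | see below |

Catalogue priors use `P_HET = P_HOM = n·i/(2l²)` with `i` the ordered
self-intersection count at 80% reciprocal overlap (self-hits included, as
an intersection of the catalogue against itself counts them); `l²/i`
estimates the number of unique intervals once overlapping duplicates are
clustered.

## Background estimation

`b` is the argmax (mode) of a Gaussian KDE — Scott's plug-in bandwidth,
512-point grid on [0, 0.5] — over per-bin minority-read fractions of the
WW composite. The mode, unlike the mean, is insensitive to the minority of
bins inflated by true inversions or poor mapping. Degenerate inputs
(single bin, zero spread) fall back to the median; an estimate at or above
0.5 is an error because such a composite is not directional. For the WC
composite the same routine runs on folded fractions `|W-fraction − 0.5|`
and is reported for diagnostics only; the genotype model uses a single
`b`, by default the WW-composite estimate, because a per-composite
background is not identifiable from the WC composite (background flips
leave a 50/50 region 50/50).

## Phasing the WC composite

Every read in a WC region that covers a heterozygous SNV votes on which
allele sits on the Watson strand (a Crick read votes for the complementary
allele, the SNV being heterozygous). With a *phased* SNV table the
orientation of each library × chromosome is anchored to VCF haplotype 1
directly, giving globally consistent phase. With an unphased table a
consensus is built greedily per chromosome — the library with most
informative reads seeds it, others join in decreasing order of evidence,
and assignments iterate to convergence — so labels are then defined only
up to one global swap per chromosome. Libraries with no informative reads
are excluded rather than guessed.

## Interval refinement

The de novo detector classifies non-overlapping windows of a fixed number
of reads by Watson fraction and emits maximal runs that differ from the
chromosome's modal state. Boundaries are refined to peaks of the deltaW
profile — the absolute difference in Watson counts between the `w` reads
on either side of a position, summed over window sizes {40, 120, 360} and
smoothed over 3 points. Support is counted as reads *inconsistent with the
base state* inside the refined interval (Crick reads on a WW chromosome,
and so on), because deltaW cannot localize events narrower than the window
and a raw interval read count would overstate the evidence; events below
`minReads` support are dropped.

Breakpoint adjustment moves each endpoint of a call to a deltaW peak
within a search radius of **half** the interval length (capped at 1 Mb),
choosing the two endpoints jointly (start strictly left of end, ties
toward the original endpoints). Half-length radii keep the two search
windows disjoint: with full-length windows both endpoints can see the
stronger switch's broad deltaW plateau and collapse onto it. Adjusted
coordinates are kept only if re-genotyping returns a confident call that
matches the original genotype and phase; a previously ambiguous call keeps
any confident adjustment. The procedure is idempotent on its own output.
Merging replaces overlapping confident calls of identical genotype and
phase by their union span, re-genotypes it, and keeps the merge only if
the genotype is confirmed.

## The simulator, and what passing tests mean

The simulator draws template-strand inheritance per library × chromosome
(WC and CW each with probability `wc_fraction/2`, WW and CC each with
`(1 − wc_fraction)/2`), places reads uniformly along chromosomes, orients
each read by its haplotype's template strand, flips it inside inversions
carried by that haplotype, and flips again independently with probability
`background`. Collapse regions emit Bernoulli(0.5) orientations in every
cell; deletion regions silence one haplotype; phased het SNVs are placed
at a configurable density (default 8 × 10⁻⁴/bp, of the order of human
heterozygosity) and each read records the allele it would show at the
first SNV it covers. Identical configurations and seeds give identical
output.

Deliberately not emulated: sequencing error, GC and mappability bias,
variable coverage, sister-chromatid exchanges (strand states are constant
along a simulated chromosome), clustered BrdU-incorporation errors (the
error taxonomy is exactly i.i.d. background plus collapse and deletion
regions), and real breakpoint microhomology. Passing recovery tests
therefore demonstrates correctness of the *model and its implementation*
under the model's own assumptions — not calling performance on real
libraries, where state changes within chromosomes and non-uniform
background would reduce usable regions and sharpen the need for the
blacklist.

Problem sizes used by the test-suite and the acceptance script were
chosen to mirror the study conditions at desk scale: the recovery
experiment simulates 300 inversions of 100 Kb (100 REF, 100 HET split
between phases, 100 HOM) across three 204 Mb chromosomes with 20
libraries at 1 read per 5 Kb per library, giving ≥50 reads per composite
per inversion; the collapse experiment uses 50 always-WC regions; the
exhaustive model check covers all counts up to 30 per composite against a
direct-space oracle.

## Numerical and degenerate-input choices

* Zero-read intervals are genotyped (all strand-state likelihoods 1), so
  the posterior reduces to the renormalized priors — AMBIGUOUS under any
  sensible prior set.
* `b = 0` is allowed (error-free data); binomial likelihoods with
  impossible outcomes simply contribute `-Inf` in log space and drop out
  of the mixtures.
* Intervals larger than composites render reliably (8 Mb for the HET
  signature, 4 Mb for HOM — and proportionally smaller than the
  classification bin, roughly a third of it for HET and a fifth for HOM,
  when smaller bins are used) are flagged but still genotyped.
* Confident HET calls on user-declared haploid chromosomes are downgraded
  to AMBIGUOUS with a note, since a heterozygote is impossible there.
* Read-to-interval assignment uses start positions and half-open
  intervals, making boundary behaviour deterministic.

## Known limitations

Copy number is not modelled, so inverted duplications tend to come back
ambiguous; the simplified detector is not a substitute for a full
segmentation tool (no per-library genotyping, no confidence intervals);
the unphased-consensus mode leaves a per-chromosome phase ambiguity that
only a phased SNV set resolves; and trio concordance uses unphased
genotype classes by default (the optional phase-aware check assumes the
child's first-listed haplotype is paternal, a convention rather than an
observable).
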