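---
title: "Quantifying double-strand-break mobility: models and design choices"
author: "breakfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying double-strand-break mobility: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakfish)
```

## The scientific problem

Topoisomerase-II poisons such as etoposide induce double-strand breaks
(DSBs) in genes like *AML1* (*RUNX1*) whose translocations drive
therapy-related leukaemia. Two questions decide how such translocations
arise: do the broken ends separate and wander, and are the recurrent
translocation partners already spatially close? breakfish implements the
two measurement pipelines that address them:

* a **break-apart FISH** pipeline that detects nuclei, dual-colour probe
  spots and whole-chromosome-paint territories in 3D confocal z-stacks,
  pairs the spots into alleles, and calls an allele *broken* when its two
  probe signals separate beyond the upper quantile of the control
  distance distribution; and
* a **4C-seq** pipeline that counts restriction-fragment contacts of a
  chosen bait locus genome-wide, profiles them in 500-kb windows, and
  tests whether translocation-partner genes are contacted more often
  than other genes.

Both pipelines are exercised end to end on synthetic data with known
ground truth; no external dataset is required.

## Image model and detection

A field is a multi-channel voxel grid indexed `(z, y, x)` with
anisotropic spacing in nm (`voxel_stack`). All physical distances use
the per-axis spacing.

**Despeckling.** Pre-processing applies a 1 × 1 × 3 median filter along
z (`despeckle`). Isolated hot voxels live in a single focal plane and
are annihilated by the median of three consecutive planes, while genuine
signal spanning two or more planes survives. Edge planes replicate their
neighbour. A consequence worth stating explicitly: any real object must
extend over at least two focal planes to survive this filter, which is
why the synthetic geometry uses a 400-nm z-step (see below).

**Nucleus detection.** Nuclei flattened on a coverslip are modelled as
cylinders with the axis along z. After a 3D Gaussian blur (sigma = 1
voxel), the global brightest voxel seeds a cylinder fit; the fitted
cylinder is removed from the working image and the process repeats until
the next seed falls below `stop_frac` (default 0.3) of the initial
maximum. Raw total in-cylinder brightness grows without bound with
volume, so `fit_cylinder` maximises mean brightness × volume^β with
β = 0.5 by default — large enough to favour covering the whole nucleus,
small enough that background voxels (whose brightness is below half the
in-cylinder mean) shrink the fit rather than inflate it. The ascent is
deterministic coordinate-wise finite-difference search with step halving
(tolerance 1e-3 voxel, at most 200 sweeps); no randomness enters
detection anywhere.

Two robustness rules matter in practice. First, the removed footprint is
dilated (radius + 4 voxels, one extra plane each side) so the Gaussian
blur halo of a removed nucleus cannot re-seed a duplicate. Second, fits
whose objective is locally flat are flagged `unstable` and discarded: on
a pure-background region the density objective grows monotonically with
volume, so a noise-seeded fit balloons and flags itself — a uniform
image is the degenerate case of the same behaviour.

**Loci and territories.** Within each nucleus cylinder, the `top_k`
brightest voxels of the probe channel are selected (300 by default; ties
broken lexicographically for reproducibility) and their connected
components (26-connectivity by default) become candidate loci. Territory
detection is identical after a further sigma = 1 Gaussian blur of the
paint channel, with `top_k` = 3000. Candidates then pass a voxel-count
filter. The top-k surplus necessarily lands on background noise, and
under 26-connectivity chance clusters of 3–7 voxels appear in virtually
every nucleus; a diffraction-limited spot occupies roughly 60 voxels at
the default 200-nm xy sampling, so the locus filter accepts 10–500
voxels — a six-fold margin below the dimmest genuine spot while removing
chance clusters. Territories accept 100–50 000 voxels and nuclei
1000–10^6.

**Pairing and QC.** A locus is reduced to its brightness-weighted
centroid in nm. The two channels are paired by greedy mutual-nearest
extraction: repeatedly take the globally closest cross-channel pair and
remove both members. Every extracted pair is mutually nearest among the
remaining points, and on planted instances the greedy result coincides
with the exhaustive minimum-total-distance matching whenever intra-pair
distances are smaller than inter-allele spacing (a property test). A
cell is retained only with exactly two objects per probe channel, one or
two territories (two homologues that may merge), and both pairs within
the 2000-nm cutoff; the first failing rule is recorded. The cutoff is
strict (`> 2000 nm` removed) and configurable.

**Signed territory distance.** The distance from a locus to its nearest
territory is measured to the plane through the three nearest territory
surface points, positive outside and negative inside. Two numerical
choices deserve justification:

* *Surface sampling.* The surface is sampled at boundary-face midpoints
  — halfway between an object voxel and an outside face-neighbour —
  rather than at boundary-voxel centres. Voxel centres sit
  systematically inside the true surface, by up to a full z-step in
  anisotropic stacks; against an analytic sphere this bias pushed errors
  to ~1.4 voxel diagonals, while face midpoints centre the
  discretisation error and keep the worst error under 0.7 diagonals.
* *Plane trust region.* Three nearest samples subtend a tiny angle when
  the point is far from the surface, so the plane can tilt arbitrarily.
  The plane is used only when the triple is a compact patch (pairwise
  within two voxel diagonals), non-collinear, and within half a diagonal
  of the nearest-sample distance; otherwise the nearest surface point —
  whose error is bounded by about one diagonal — is used. Inside/outside
  is decided by voxel membership of the nearest grid voxel, which stays
  correct for concave territories where plane orientation would not.

When two territories are present the distance is taken to the nearer
one; which territory belongs to which allele is not observable from the
image alone, and the output flags this convention.

## Break calling and statistics

The break threshold is the 99th quantile (type-7, linear interpolation)
of the control pair-distance distribution; an allele is broken when its
distance strictly exceeds it, so by construction about 1% of control
alleles are called broken and the treated excess above that floor
estimates the true broken fraction. The empirical tail test asks whether
the treated tail is non-empty: with observed tail proportion `P*` of `n`
alleles, `x = 3·sigma/sqrt(n)` with `sigma = sqrt(P(1−P))` and `P ≈ P*`;
a positive margin `P* − x` establishes a non-empty tail with reliability
above 0.997 (three-sigma rule; the multiplier is a parameter). The
margin is strictly increasing in `n`, so significance is monotone in
sample size — a property test.

Association between break status and territory localisation uses the
Pearson chi-square on a 2 × 2 table (closed form, df = 1, no continuity
correction by default since the cohorts are large; Yates correction via
a flag), with the fold ratio of outside proportions reported. Group
comparisons of 4C signal use the Mann–Whitney test with exact
small-sample p-values (smaller group ≤ 8, no ties) and the tie-corrected
normal approximation otherwise.

## 4C-seq model

The genome is digested in silico at the primary-enzyme motif (HindIII
`A^AGCTT`, cut offset 1; the secondary enzyme DpnII `^GATC` appears only
in the synthetic library construction, matching a counting path that
works entirely in HindIII fragments). Fragments tile each chromosome
`[0, L)` exactly — asserted on every digestion.

A read is informative only if it contains the ligation site preceded by
a bait primer: the prefix classifies the anchor, the suffix is the
captured contact. All rejections are categorised (`no_site`,
`unknown_anchor`, `ambiguous`) and read conservation
(classified + rejected = total) is asserted. Captures are mapped by the
unique exact occurrence of their first 20 bases on either strand — the
synthetic-genome stand-in for unique short-read alignment; externally
produced alignments can be supplied wherever mapped positions are
consumed. The reported position is the capture's 5′ base on the plus
strand, so a plus-strand hit near a fragment start or a minus-strand hit
near a fragment end (± 4 bp tolerance for end trimming) increments that
fragment's raw signal; everything else is a counted end-miss. The bait
fragment and its two neighbours are masked by default (self-ligation and
undigested template dominate there), with a flag for strict counting.

Window profiles count, per non-overlapping 500-kb window from position
0, the fragments with at least one contact, assigning each fragment by
midpoint. Replicates are normalised to a common library size
(`raw · scale / Σraw`, signal-per-million by default), merged by
averaging, and compared by the Pearson correlation of their window
profiles. The trans fraction is the proportion of signal-bearing
fragments off the bait chromosome, consistent with the fragment-level
window definition. Partner-gene enrichment sums window values over the
windows overlapping each gene (window level is the default; a
fragment-level option counts signal-bearing fragments instead, and is
the better-powered choice on the small synthetic genomes where only a
handful of 500-kb windows exist per chromosome) and applies the
Mann–Whitney test of partner genes against all other genes on non-bait
chromosomes.

## What the synthetic data emulates — and what it does not

`simulate_fish_stack` renders, per field: nucleus cylinders (radius
4 µm, 13 focal planes) in the counterstain; two territories per nucleus
(1.5-µm balls, blurred) kept at least 2.2 territory radii apart — two
homologue territories occupy distinct sub-volumes, and without that
margin spots of different alleles can blend even in the noise-free
limit; and one spot per probe per allele with an isotropic Gaussian
point spread of sigma = 200 nm. Intact intra-allele separations are
normal (mean 400 nm, sd 150 nm, resampled to stay below the 1500-nm
break distance); broken alleles add a 2000-nm shift and always exceed
it. Noise is Gaussian background (mean 100, sd 30) plus Bernoulli
single-voxel speckles (rate 1e-4, brightness 3000) to exercise the
despeckle filter.

The default grid is 256 × 256 × 20 voxels at 200/200/400 nm — a
scaled-down field that keeps a full detection run around six seconds;
the full 1024 × 1024 geometry is available through `dims`. The 400-nm
z-step is the fine end of the standard confocal interval and is a
requirement of the model, not a convenience: with a 200-nm isotropic
point spread, a coarser step renders spots as single-plane objects that
the despeckle filter itself is designed to remove.

`simulate_fourc_dataset` builds random chromosomes (HindIII sites arise
naturally about every 4 kb), plants each bait primer immediately
upstream of a site, and samples target fragments from a distance-decay
model: cis probability ∝ `(1 + |i − bait|)^(−α)` in fragment-index
units with α = 1, plus a uniform trans floor (0.002 per fragment,
≈ 91% of reads in cis, echoing the observation that most captured
contacts are cis). Only fragments long enough to donate a capture and
with genome-wide-unique end seeds are eligible, so noise-free recovery
of the planted counts is exact by construction. Junk reads (no site, or
an unknown primer) are added at a configurable fraction and verified
never to masquerade as valid reads, making read accounting exact.

None of this emulates real optics (anisotropic PSF, photobleaching,
chromatic shift), chromatin texture inside nuclei or territories,
sequencing errors, PCR duplicates, or mappability structure of a real
genome. Passing the recovery tests therefore shows the algorithms are
implemented correctly and calibrated under their stated model — not
that the thresholds are optimal for any particular microscope or
library.

## Problem sizes and determinism

The test suite runs detection on twenty 256 × 256 × 20 fields of ten
nuclei for the recovery check, 500 planted points for the
signed-distance check, cohorts of 2000 alleles for break-calling
calibration, a 3 × 1-Mb genome with 10^4 reads for 4C exactness, and 500
null simulations for the enrichment test's type-I error — sizes chosen
so the whole suite completes in minutes while keeping Monte-Carlo error
well inside the asserted tolerances. Every stochastic step takes an
explicit seed, and regenerating with the same seed is asserted to be
bit-identical (FASTQ bytes, truth tables, arrays). Detection itself is
seed-free and deterministic, including tie-breaks.

## Known limitations

* The cylinder model assumes nuclei are well separated in xy; touching
  nuclei would be merged or mis-fitted.
* Break calling attributes the control tail entirely to measurement
  noise; a contaminated control inflates the threshold and deflates the
  treated excess.
* Territory distances use the nearest territory, which can pick the
  wrong homologue for an allele wandering past the midpoint between two
  territories.
* The exact-match mapper requires a unique 20-mer; it is a stand-in for
  read alignment on synthetic genomes and is not suitable for repetitive
  real genomes.
* With two territories that genuinely merge, the territory count QC
  accepts the merged object, but the signed distance then measures the
  union surface.
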