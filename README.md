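# breakfish

Quantification of double-strand-break formation and broken-end mobility
from **break-apart FISH** confocal z-stacks, together with **4C-seq**
contact profiling of a bait locus — the two measurements used to ask
whether recurrent leukaemia translocations (e.g. those involving
*AML1*/*RUNX1* after etoposide exposure) arise from spatial proximity of
the partners or from the mobility of broken DNA ends.

## What it computes

**FISH half.** A field is a multi-channel 3D stack: DNA counterstain,
two probe channels flanking the gene of interest, and a
whole-chromosome-paint channel. The pipeline

1. despeckles each channel with a 1×1×3 z-median filter;
2. detects nuclei iteratively: Gaussian blur (σ = 1 voxel), brightest
   voxel as seed, cylinder (axis ∥ z) fitted by deterministic coordinate
   ascent on mean brightness × volume^β, fitted nucleus removed, repeat;
3. detects loci and territories as connected components of the top-k
   brightest in-nucleus voxels (territories after an extra σ = 1 blur),
   with voxel-count filters;
4. pairs the two probe channels by mutual nearest neighbours, applies
   the cell QC (exactly two objects per channel, 1–2 territories,
   2000-nm cutoff);
5. measures inter-probe distances and signed locus-to-territory
   distances (positive outside, negative inside), and calls an allele
   **broken** when its pair distance exceeds the 99th quantile of the
   control distribution.

Statistics: the empirical three-sigma tail test
(`margin = P* − 3·√(P*(1−P*))/√n`), the 2×2 chi-square association of
break status with outside-territory localisation (with fold ratio), and
the Mann–Whitney rank test.

**4C half.** In-silico HindIII digestion (`A^AGCTT`), bait-anchored read
demultiplexing (primer + ligation site + captured contact), unique
exact-match mapping on synthetic genomes, fragment-end counting
(left/right end ± 4 bp), 500-kb window profiles of contact-bearing
fragments, library-size normalisation with replicate Pearson
correlation, trans-contact fractions, and partner-gene enrichment.

**Synthetic truth.** `simulate_fish_stack`, `simulate_distance_cohort`
and `simulate_fourc_dataset` generate imaging fields, distance cohorts
and read sets with known ground truth, so every stage is testable
without any external data.

## Worked example

```r
library(breakfish)

# a control field and an etoposide-like field with 3% planted breaks
ctl <- simulate_fish_stack(n_nuclei = 10, noise = "moderate", seed = 1)
out <- run_fish_pipeline(list(ctl$channels))
out$stats$threshold_nm
#> [1] 795.0639
out$stats$broken_fraction
#> [1] 0.05

# cohort-scale break calling (n = 2000 alleles per arm)
control <- simulate_distance_cohort(2000, broken_fraction = 0,    seed = 11)
treated <- simulate_distance_cohort(2000, broken_fraction = 0.03,
                                    broken_shift_nm = 2000,       seed = 12)
thr <- broken_threshold(control$distance_nm)          # 99th quantile, nm
classify_broken(treated$distance_nm, thr)$broken_fraction -
  classify_broken(control$distance_nm, thr)$broken_fraction
#> [1] 0.031                                           # recovers the planted 3%

tail_test(0.029, n = 1000)
#> tail test: P* = 0.029 (n = 1000), x = 0.01592, margin = 0.01308 -> tail non-empty (significant)

territory_association(matrix(c(30, 70, 10, 90), 2, byrow = TRUE))[c("statistic", "fold")]
#> $statistic
#> [1] 12.5
#> $fold
#> [1] 3
```

The small-field `broken_fraction` above is a 20-pair estimate and lands
near the ~5% definitional floor + noise; the cohort-scale run is the
calibrated measurement. A 4C run:

```r
tr <- simulate_fourc_dataset(n_reads = 1e4, junk_fraction = 0, seed = 3)
res <- run_fourc_pipeline(tr$genome, tr$reads, tr$anchors)
res$anchors$anchor1$r_min           # replicate window-profile correlation
#> [1] 0.9477454
res$anchors$anchor1$trans_fraction  # signal-bearing fragments off the bait chromosome
#> [1] 0.6537949
```

(Read-level, ~91% of simulated contacts are cis; the fragment-level
trans fraction is higher because cis fragments saturate.)

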