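---
title: "musselkit: models, parameters and design notes"
author: "musselkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{musselkit: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what musselkit computes and why the defaults
are what they are: the spectral model behind the genome-size and
heterozygosity estimators, the semantics of the curation cascade, the
Poisson expansion test and its multiple-testing control, what the
synthetic-data generators emulate (and deliberately do not), and the
numerical corner cases. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

# The k-mer spectrum model

A k-mer histogram tabulates, for each multiplicity $m$ (the number of
times a distinct k-mer was observed in the reads), the number of
distinct k-mers at that multiplicity. For a diploid genome sequenced
at homozygous depth $c$:

* sequencing errors create near-unique k-mers piling up at $m \le 3$
  or so — the descending *error limb*;
* k-mers shared by both haplotypes are sampled at depth $\approx c$
  (the homozygous peak);
* k-mers overlapping a heterozygous site exist on one haplotype only
  and are sampled at $\approx c/2$ (the heterozygous peak). Each
  isolated heterozygous site creates about $2k$ such
  haplotype-specific k-mers ($k$ per haplotype) while destroying about
  $k$ shared ones.

`detectErrorThreshold()` returns the first local minimum of the
smoothed count curve scanning upward from $m=1$; a dip qualifies only
if the curve later rises to at least twice its height, so noise
wiggles in a monotone tail are not mistaken for the error/signal
valley and an error-free spectrum correctly reports "no valley found".
Smoothing is a centered moving average, window 3 by default
(`smoothWindow`, odd; 1 disables smoothing) — raw histograms are noisy
at high multiplicity, while a wide window would displace shallow
valleys at low coverage.

`detectPeaks()` reports local maxima of the smoothed curve above the
threshold. `classifyPloidy()` calls "diploid-heterozygous" when
exactly two dominant peaks (height at least `dominanceFrac = 0.05` of
the tallest) sit at a depth ratio within $2 \pm \tau$
($\tau = 0.35$); one dominant peak is "haploid-like", anything else
"ambiguous".

**The homozygous-shoulder rescue.** At high heterozygosity and
moderate $k$ the haplotype-specific class can dwarf the shared class
(at $r = 3\%$ and $k = 25$, only $1 - kr \approx 25\%$ of positions
yield shared k-mers, while $2kr \approx 150\%$ of positions yield
haplotype-specific ones), and the homozygous peak degrades to a
shoulder that is not a local maximum. `profileSpectrum()` therefore
checks, when a single dominant peak is found, what fraction of the
retained volume lies beyond $1.5\times$ its depth. A single Poisson
component cannot carry more than a fraction of a percent there, so a
fraction above `shoulderFrac = 0.05` indicates a buried second
component; the homozygous depth is then placed at exactly twice the
dominant depth (the shoulder's own argmax is tilted leftward by the
het tail, so it would underestimate the depth).

## Genome size

$$G = \frac{T - T_{err}}{c_{hom}},$$

with $T$ the total volume $\sum_m m \cdot \mathrm{count}(m)$ and
$T_{err}$ the volume at multiplicities strictly below the error
threshold. The identity
$(G - kS)\,c + 2kS\,(c/2) = G\,c$ (with $S$ heterozygous sites) shows
why dividing by the homozygous depth recovers $G$ regardless of
heterozygosity. The high-multiplicity repeat tail is deliberately kept
in $T$; no repeat correction is applied.

## Heterozygosity

The estimator integrates the spectrum over the heterozygous window
(valley between the error threshold and the het peak, up to the valley
between the two peaks), converts the volume $A_{het}$ to distinct
haplotype-specific k-mers $D_{het} = A_{het}/c_{het}$, then to sites
$H = D_{het}/2k$ and a rate $r = H/G$. Because the two Poisson
components overlap at low coverage, the valley window can capture well
under 100% of the het mass (about 74% at coverage 30); the estimator
divides by the captured-mass fraction implied by Poisson($c_{het}$)
(`truncationCorrection = TRUE`), using
$\sum_{m=a}^{b} m\,f(m;\lambda) = \lambda \sum_{m=a-1}^{b-1} f(m;\lambda)$.
The correction is skipped when the implied fraction is below 0.1,
which indicates the window itself is wrong. The exact variant of the
published het-peak formula is not stated in the original sources; this
volume-ratio model is the standard spectral argument and is validated
by parameter recovery on simulations rather than against a closed-form
reference.

# Assembly statistics

N50 is computed by sorting lengths descending and returning the first
length at which the running sum reaches 50% of the total; the result
is always an observed length. Size-class rows count scaffolds
*strictly* longer than 1 kb / 1 Mb / 50 kb — the convention that
reproduces the published comparison-table spot checks. Displayed
integers use round-half-away-from-zero (banker's rounding would print
a different mean for some totals); size-class percentages print at one
decimal, genome-fraction and BUSCO percentages at two. Internal values
are never rounded. Soft-masked (lowercase) positions count toward the
masked percentage; N/n positions count as assembly gaps, not as
masking, following the RepeatMasker soft-masking convention. Contig
statistics split scaffolds at runs of at least 10 N's (`minGapRun`),
a conventional choice since the original split rule is not published.

# The curation cascade

Filters run in the order: protein coverage → exon count → redundancy
→ repeat overlap. Semantics worth spelling out:

* **Best hit.** Evidence is reduced per model by smallest e-value,
  ties by larger aligned span, then lexicographic subject id —
  deterministic, so the cascade is reproducible.
* **Coverage.** `aligned span / query length >= 0.90`, boundary
  inclusive ("90% or more"). Models with no hit fail with reason
  `no-hit`.
* **Exon count.** `minExons = 4` encodes the strict reading of "more
  than 3 exons"; `minExons = 3` gives the inclusive variant. The
  original boundary intent is ambiguous, so it is a documented switch.
* **Redundancy.** Pair overlap is shared exon-projected bases divided
  by the *shorter* model's CDS length (configurable to `longer` or
  `union`). Removal proceeds in simultaneous rounds: every
  over-threshold pair among current survivors designates its shorter
  member (CDS ties keep the lexicographically smaller id), the union
  of losers is removed, and the process repeats to a fixed point. This
  makes the result independent of input order, which
  remove-one-pair-at-a-time semantics would not be.
* **Repeats.** One shared base disqualifies ("free of repeat
  regions"). Intervals live in `GRanges` (1-based closed); BED input
  (0-based half-open) is shifted at the reader, so abutting intervals
  do not overlap and a single shared base does — exactly the half-open
  arithmetic, in the Bioconductor coordinate convention.
* `curateModels()` drops evidence rows referencing models outside its
  input set (with a message), so the cascade is idempotent: re-running
  it on its own survivors with the original evidence changes nothing.
  A direct `coverageFilter()` call still treats unknown ids as an
  error, which catches mismatched input files.

# The domain expansion test

Counts are normalized to frequencies by each genome's total
Pfam-assigned count, compensating genome size and annotation depth.
The focal genome's expectation for domain $d$ is the arithmetic mean
of the reference genomes' frequencies times the focal total. The test
is the exact Poisson cumulative tail in each direction; no pseudocount
ever enters it (the pseudocount, default 0.5, exists only in the
log2-ratio display matrix). At $\lambda = 0$ the distribution is a
point mass: any positive observation has upper-tail probability zero
and is an automatic expansion — users should interpret calls on
domains absent from every reference accordingly.

**Bonferroni family.** Two one-sided tests are run per domain. The
default family size is therefore $2m$ over $m$ tested domains
(`familySize = "directions"`): under this count Bonferroni guarantees
family-wise error at most $\alpha$, which the calibration suite
verifies. Counting only $m$ (`familySize = "domains"`) bounds the
family-wise error at $2\alpha$ only; it is retained as a config option
because which family the original analysis used is not stated.
Plugging in an estimated $\lambda$ (from 9 finite references) adds
variance the Poisson model does not see, so the realized family-wise
error under full-table resampling exceeds the conditional one; the
calibration null therefore resamples the focal genome from the
reference-derived expectation, which isolates the property the test
can guarantee. This plug-in anti-conservatism is a real limitation of
the method on few reference genomes.

**Clustering.** Similarity between two ratio vectors is their dot
product divided by the vector length ("average dot product"; cosine
similarity is available as config). Distances are obtained by
subtracting similarities from the maximal off-diagonal similarity, so
the most similar pair sits at distance 0 and all distances are
non-negative; whether the original similarity was centered is
unknowable from the published description, so the raw product is the
default. Agglomeration is complete linkage with ties broken by the
lexicographic order of cluster labels (a cluster is labelled by its
smallest member), which makes dendrograms byte-reproducible; the
merge sequence is cross-checked against an independent cubic-time
agglomerator in the tests.

# What the generators emulate — and what they do not

All generators are deterministic given their parameters and a seed,
and record a truth object sufficient to recompute every expected
output.

**Spectra.** The default "direct" mode samples k-mer multiplicities
from the three-component model above (shared k-mers at
Poisson($c$), haplotype-specific at Poisson($c/2$), error k-mers as
unique species with multiplicity $1 + \mathrm{Geom}$, mean 1.3, in
volume $G \cdot c \cdot k \cdot \mathrm{errorRate}$). The "sequence"
mode builds both haplotype sequences and enumerates their k-mers,
validating the analytic mode on small genomes. Neither mode simulates
repeats, GC bias, or clustered heterozygosity, so recovery results
speak to the estimator's window and peak logic, not to repeat-rich
real spectra. The recovery suite covers 0.5–2 Mb genomes, coverage
30–60, heterozygosity 0.5–3% (scaled-down problem sizes keep the suite
fast; the estimators are scale-free in genome length).

**Gene models.** Each model either passes every filter or carries
exactly one planted violation, placed so that it survives all stages
before its own; models sit on separate scaffolds (redundant twins
share one) so no accidental interactions arise. This probes the
cascade's logic, not the messiness of real PASA output, where a model
can violate several filters at once (the cascade handles that too —
the first rejecting stage records the reason — but the planted truth
would be ambiguous).

**Domain matrices.** 2000 domains share 40 000 instances per genome —
the scale of a real Pfam annotation of a molluscan proteome. Baseline
frequencies follow a gamma(shape 2) law floored at 5 expected counts
per genome: the floor keeps the recovery suite away from the
degenerate $\lambda = 0$ corner, which is unit-tested separately.
Expansions and contractions are planted mass-balanced (the contraction
baselines are paired at fold × the expansion baselines), because under
a fixed multinomial total an unbalanced plant genuinely depresses
every unplanted domain's frequency — the truth table would then call
"neutral" domains that the sampling model itself has contracted. Even
so, a calibrated procedure with family-wise error $\le \alpha$ is
*expected* to produce a false call in roughly $\alpha$ of runs; over a
20-seed recovery suite the chance of at least one such call is
substantial, which is a property of the $\alpha = 0.05$ design, not of
the implementation.

# Numerical choices and degenerate inputs

* k-mer counts and volumes are doubles throughout (volumes exceed
  2^31 for gigabase genomes).
* Histograms with a Jellyfish-style catch-all last bin are accepted at
  the bin's nominal multiplicity (`dropLastBin = TRUE` removes it).
* Empty multiplicty ranges integrate to zero; an empty FASTA yields an
  empty record table, while zero-length records and duplicate ids are
  errors that name the offender.
* All file writers stage to a temporary file in the destination
  directory and rename, so failed runs never leave partial outputs.
* The error-volume identity `errorVolume + retained == totalVolume`
  holds exactly (same summation, disjoint ranges).
* `set.seed()` is called inside the generators (documented), so they
  perturb the caller's RNG state; tests that interleave generators and
  their own sampling re-seed explicitly.

# Known limitations

* The spectrum profiler fits no mixture model; it reads landmarks off
  the smoothed curve. Genomes with strong repeat structure need the
  landmark overrides (`errorThreshold`, `hetPeakDepth`,
  `homPeakDepth`) or a dedicated mixture fitter.
* The heterozygosity estimator assumes isolated heterozygous sites;
  at rates where sites fall within $k$ of each other it measures the
  model's effective rate, not the biological one.
* The Poisson test treats the reference-derived expectation as exact;
  with few reference genomes the upper tail is anti-conservative for
  abundant families (see above).
* The published end-to-end counts that depend on the original
  sequencing data (total genome size, curated-model count, numbers of
  expanded/contracted families) are not reproducible without that
  data; the synthetic recovery suite is the substitute evidence.
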