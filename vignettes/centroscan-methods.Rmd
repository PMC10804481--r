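---
title: "Mapping centromere-proximal crossovers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping centromere-proximal crossovers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centroscan)
```

## The problem

Plant centromeres are built from megabase-scale satellite repeat arrays
that load CENH3 nucleosomes and assemble the kinetochore. Meiotic
crossovers are strongly suppressed in and around these arrays: a core
region shows no crossovers at all (the non-recombining zone, NRZ), and
recombination stays depressed for another one to two megabases on each
side (the low-recombining zones, LRZs). centroscan implements the
computational side of mapping this landscape in *Arabidopsis thaliana*
Col/Ler recombinant populations: filtering diagnostic SNP markers,
calling crossovers from low-coverage resequencing of backcross (BC1) and
F2 plants, delineating the NRZ and LRZs from windowed genetic maps,
fine-mapping crossovers around a centromere with fluorescence-selected
seed and KASP marker genotyping, and testing interval overlap and
nucleotide diversity by permutation.

Because the original sequencing data are large external accessions, the
package ships a synthetic-data generator that emulates every input with
the statistical structure the analysis assumes. All downstream stages
are exercised end-to-end against simulated truth.

## Coordinates and conventions

All coordinates are 0-based, half-open internally. Readers and writers
convert to and from 1-based positions where a format requires it (marker
TSV, VCF). A BC1 plant samples one meiotic gamete; an F2 plant samples
two independent gametes, so `n_gametes = n_plants` for BC1 and
`2 * n_plants` for F2. Genetic distance follows the standard definition:
1 cM is one crossover per 100 gametes, so a window's cM is
`100 * crossovers / n_gametes` and map totals are conserved under any
windowing.

## The synthetic-data generator

A `recombination_landscape()` is a piecewise-constant crossover
intensity over one chromosome, normalised to a total genetic length. A
`zero_zone` (the satellite array) has intensity exactly zero, so no
simulated crossover can fall inside it. Crossover counts per gamete are
Poisson with mean `total_cm / 100` and positions are drawn by
inverse-CDF sampling of the intensity.

Two generator options matter for validation:

* `interference_nu` switches crossover placement from a Poisson process
  to a thinned gamma renewal process (chiasma-scale inter-arrivals
  `Gamma(nu, 2 nu)` in Morgans, each chiasma transmitted to the sampled
  chromatid with probability 1/2). Values around 5 give the strong
  positive interference typical of Arabidopsis, which in practice
  eliminates same-chromatid double crossovers within a megabase. The
  default is `NULL` (no interference), because the callers themselves
  never model interference.
* `deterministic_reads` replaces Poisson depth and binomial allele
  sampling with their expectations. This is the idealised "error-free"
  regime used to validate the caller: with stochastic reads, a
  heterozygous marker next to a breakpoint can by chance show five or
  more reads of a single parent (probability about `2^-5` per
  crossover) and no finite read-count rule can bound the breakpoint
  with certainty.

Read data follow the low-coverage resequencing design: marker positions
are a Poisson process (default mean spacing 1 kb, matching the ~2.5
SNPs/kb of a Col/Ler marker set after filtering at desk scale), depth
per marker per sample is Poisson (default 1 read), and allele reads are
binomial with the expected parental fraction perturbed by the allele
error rate (default 0.2%). Contaminant samples are uniformly homozygous
for one parent; low-coverage samples are sequenced at one twentieth of
the target depth.

The fluorescent-reporter simulator inverts the map-distance estimator:
at true distance `d` cM the probability that a seed is single-colour
recombinant is `f = (1 - (1 - d/100)^2) / 2`, split equally between
green-alone and red-alone. The KASP plate simulator encodes one
crossover per selected plant as the colour-consistent genotype
transition, plus configurable numbers of uniformly Col/Col contaminants
and double-chromatid plants (from selected homozygous fluorescent
seed).

What the generator does **not** emulate: read-level sequence content,
alignment artefacts near structural variants (marker filters are tested
against parametrically skewed profiles instead), segregation distortion,
and chromosome-specific marker gaps. Passing tests therefore demonstrate
the correctness of the algorithms under the stated statistical model,
not robustness to every artefact of real sequencing data.

## Marker filtering

Population-level filters retain markers whose read and genotype profile
matches Mendelian expectation. For a Col-backcross population: Col
allelic read ratio in (0.6, 0.9), homozygous-Col sample fraction in
(0.4, 0.7), heterozygous fraction in (0.3, 0.6), homozygous-Ler fraction
below 0.1, and more than 70 genotyped samples. For an F2 population: Col
allelic ratio in (0.3, 0.7), each genotype-class fraction in (0.1, 0.9),
and more than 5 genotyped samples. All comparisons are strict
inequalities, exactly as the thresholds are stated. Every failed
criterion emits a reason code. Markers near annotated repeats or
structural variants can be removed with a configurable flank (default
0 bp, since no specific flank is prescribed for this step).

## The crossover caller

Calling proceeds in three stages per sample and chromosome:

1. **Window genotyping.** Sliding 70-kb windows with a 35-kb step are
   called from the Col read fraction of their markers: homozygous at a
   fraction of 0.9 or beyond (`hom_threshold`), heterozygous in between,
   missing below 5 informative markers (`min_markers`). The thresholds
   0.9 and 5 are package defaults chosen so that clean simulated data is
   called perfectly; both are exposed.
2. **Transition detection.** Runs of constant window call (missing
   skipped) become genotype segments; boundaries between successive
   distinct segments are crossover candidates. Interior runs shorter
   than 2 windows (`min_run`) are unstable noise and are skipped — but a
   run truncated by a chromosome end is exempt, because it cannot be
   longer; without this exemption every crossover within one window of
   a chromosome end would be missed. For BC1 only
   recurrent-homozygote/heterozygote transitions are legal. For F2,
   homozygote-to-homozygote boundaries are resolved into two crossovers
   flanking a short heterozygous tract only when marker-level evidence
   for the tract exists; otherwise they are rejected, since a single
   chromatid cannot switch between homozygotes.
3. **Read-level refinement.** Within the candidate region the breakpoint
   is placed at the inter-marker split minimising the cumulative
   log-likelihood ratio between the two genotypes (binomial read model
   with a 1% error floor). The caller then walks outward from the split,
   accumulating reads at markers whose evidence supports that side's
   genotype; a marker with strong opposite evidence resets the
   accumulator. Each side must accumulate at least 5 reads
   (`min_reads`); the reported interval spans exactly to the
   accumulation-completion marker on each side, so the interval is as
   wide as the five-read support rule requires and no wider. On dense
   well-covered data this reduces to the two markers flanking the
   breakpoint.

Sample QC removes samples with mean depth below 0.1 reads/marker (the
proxy for 0.1x coverage) and samples where more than 2% of called
windows have a Col fraction inside [0.8, 0.9] — the signature of a
mixture of genotypes. "First-allele frequency" is read as the
Col-allele fraction and is configurable.

The population double-crossover filter targets mis-genotyping: in 1-Mb
sliding windows (500-kb step), when the fraction of crossover-bearing
samples that carry a *double* crossover exceeds 4% (strictly), those
double calls are removed. A double is defined as a pair of calls whose
genotype path returns to its starting state (X to Y and back to X) —
the mis-genotyping signature. Progressive transitions in an F2
(Col/Col to Col/Ler to Ler/Ler) are two genuine crossovers on different
chromatids and are not counted. Note that the 4% threshold is
calibrated for study-scale populations (thousands of crossover-bearing
samples per window); in small populations a single genuine
return-path double can exceed it and be removed. This is a faithful
property of the frequency rule, visible in the package's own F2
simulations, and is the main reason F2 recovery at a few hundred plants
is near-perfect rather than perfect.

Crossover calls are represented by their interval midpoint in all
windowed tallies, a choice the package makes explicitly since several
representations are defensible.

## Zone delineation

Crossover midpoints are tallied in non-overlapping 100-kb windows
(10-kb windows are used for plotting-resolution maps; both are
parameters). The NRZ is the maximal run of consecutive zero-crossover
windows that maximally overlaps the annotated satellite array — the
anchor disambiguates multiple zero runs. Each LRZ extends outward from
an NRZ boundary, accumulating window cM until the running total first
reaches 1 cM; the threshold-crossing window is *included*, so the
attained cM lies in `[1, 1 + cM of the outermost window)`. The
inclusion choice is recorded in the output (`attained_cm`), since
either convention is defensible. If a chromosome end arrives first the
LRZ is truncated and flagged.

## Interval genetics

The fluorescent-reporter estimator converts seed counts to genetic
distance with `100 * (1 - sqrt(1 - 2 (NG + NR) / NT))`; the square root
reflects that a single-colour seed requires one recombinant and one
non-recombinant gamete. The estimator is exact on its domain
(recombinant fraction at most 1/2) and strictly increasing, and is the
exact inverse of the simulator's recombinant-fraction model.

The KASP caller classifies each plant from its ordered genotype vector,
skipping missing calls: a single colour-consistent transition
(green-alone: Col/Ler to Ler/Ler; red-alone: the reverse) is one
crossover; Col/Col to Col/Ler to Ler/Ler patterns are two crossovers on
different chromatids, both counted; uniformly Col/Col plants are
contaminants and excluded; Col/Ler to Col/Col to Col/Ler to Ler/Ler
patterns carry one single-crossover chromatid and one double-crossover
chromatid, and only the colour-consistent crossover is counted.
Transitions whose flanking informative markers are non-adjacent are
ambiguous: their unit tally is divided among the spanned intervals in
proportion to the unambiguous crossovers already mapped there (equal
split when all candidates are empty). The proportional rule is applied
over however many intervals the missing run spans; total tally mass is
conserved exactly.

Hotspots and coldspots are detected per interval with a 1-df chi-square
on the `[in-interval, elsewhere]` partition against an expectation
proportional to physical interval length ("even distribution" read as
uniform per bp; a uniform-per-interval alternative is available).
P-values are Bonferroni-corrected by the number of intervals in the map
under test; analyses of different genotypes are corrected within
genotype. No continuity correction is applied by default — matching the
exact-binomial oracle used in the tests — but one is available.
Between-genotype and between-region comparisons use 2x2 chi-square
tests; the regional test defaults to the Yates correction, the standard
for 2x2 tables.

## Permutation statistics

`permute_overlap()` compares the number of query loci overlapping a
feature set (at least 1 bp) with the counts from placements of the same
number of loci, with the same widths, uniformly at random within the
background. Placements are independent, may overlap each other, and are
weighted across background intervals by the number of valid start
positions for each width. Empirical p-values use the add-one estimator
`(r + 1) / (n + 1)`, whose floor at 10,000 permutations is
9.999e-5. The estimator is deliberately conservative under ties; the
package's calibration check measures a type-I rate of about 4% at a
nominal 5%.

Per-gene nucleotide diversity is the mean over qualifying sites of
`2 j (m - j) / (m (m - 1))`, the average pairwise difference over the
`m` non-missing haploid calls of which `j` carry the alternate allele.
Sites qualify when at most 15% of calls are missing; monomorphic
covered sites are included in the denominator (the per-gene value is a
per-site average over covered length). Accessions are treated as
haploid — appropriate for a selfing species — with heterozygous calls
set missing upstream. Gene sets are filtered to at least 50% sequencing
coverage and masked against repeats, organellar insertions and assembly
inversions before analysis. The zone-versus-arm comparison permutes
equal-sized draws from the arm gene pool *without* replacement (the
choice is not prescribed; with a pool much larger than the zone set the
difference is negligible) and compares medians.

## Pipeline, configuration and problem sizes

`run_pipeline()` chains simulate, filter, call, zones, fluorescent and
KASP stages, writes TSV/BED outputs plus a JSON manifest of every
parameter, and is bit-reproducible given the same configuration.
Configuration is YAML (`pipeline_config()`), with every stage parameter
exposed; a thin command-line dispatcher over the exported functions is
installed at `inst/cli/centroscan.R`.

The test and acceptance runs use a 10-Mb chromosome with a 2-Mb central
zero zone and 100-kb unmarked telomeric caps (real assemblies carry no
diagnostic SNPs in the terminal repeat arrays), 500 gametes at 1
marker/kb for caller validation, 4,000 gametes for zone recovery on a
12-Mb chromosome with a 2.5-Mb zero zone and 1.2-cM suppressed flanks,
and 1,000 replicate experiments for permutation calibration. These
sizes make every check a genuine population-scale computation while
keeping the full suite runnable on a laptop in a few minutes. Matching
of noisy-data calls to true crossovers allows 20 kb of slack around the
called interval, since read noise blurs interval endpoints; error-free
validation requires exact containment.

## Known limitations

* Crossovers within roughly half a window of an unmarked chromosome
  terminus are invisible to any 70-kb window caller.
* In F2 plants, two crossovers on different chromatids falling within
  the same megabase produce a return-path genotype pattern that is
  indistinguishable from mis-genotyping at the single-plant level; at
  small population sizes the frequency-based double filter removes
  them.
* Interval endpoints on low-coverage data are support bounds, not
  credible intervals; a heterozygous marker that by chance shows only
  one parent's reads can shift an endpoint by a marker or two.
* The diversity module consumes genotype matrices; it does not perform
  variant calling or coverage estimation from raw alignments.
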