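---
title: "Forensic Y-STR diversity and population structure with ystrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic Y-STR diversity and population structure with ystrtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrtools)
```

## The problem

Y-chromosomal short tandem repeats (Y-STRs) are strictly paternally
inherited and highly polymorphic, which makes them the standard tool for
male-lineage identification in forensics and for tracing paternal
population structure. A panel is validated in a reference population by
typing a few hundred unrelated males and reporting, per locus and for the
whole haplotype, a small set of direct-count statistics; the haplotypes
then feed between-population comparisons. `ystrtools` covers that
workflow: table ingestion with the naming edge cases real data contain,
the forensic summary statistics, Rst distances by haploid AMOVA, and MDS /
Neighbor-Joining summaries of the resulting distance matrix, plus a
simulator that generates all of the above synthetically.

## Data model

A haplotype table has one row per male and one column per marker. Allele
names follow forensic convention:

* STR alleles are repeat counts; a microvariant with an incomplete repeat
  is written with one fractional digit (`14.1` = 14 repeats + 1 bp). The
  printed label is preserved through parsing and re-export.
* Multi-copy loci (DYS385, DYF387S1, DYS527, DYF404S1) return two or more
  alleles per male. The unordered multiset is one allelic state:
  `"14,11"` and `"11,14"` are the same call, canonicalized to ascending
  numeric order. Copy-number anomalies — a bi-allelic pattern at a
  single-copy locus, a tri-allelic pattern at a double-copy locus — are
  ordinary calls of size 2 or 3.
* Y-InDels are two-state categorical markers with no repeat semantics.

Missing cells are missing markers: an individual missing any locus of a
panel is excluded from that panel's haplotype-level statistics but still
counts in the allele spectra of the loci it does carry. DYS389II is stored
as typed, with no subtraction of DYS389I; if your data follow the
subtraction convention, transform before import.

Panels are configuration, not code: `default_panels()` ships the classic
kit ladder (9-STR minimal haplotype, PowerPlex Y, Yfiler, PowerPlex Y23,
Yfiler Plus) plus a 44-marker extended panel (41 Y-STRs + 3 Y-InDels) of
the kind used by six-dye megaplex kits. Because the exact roster of such
kits varies and is typically published only in kit documentation, the
extended default names the commonly reported loci and is meant to be
edited; `read_panel_config()` / `write_panel_config()` exchange panel
definitions as YAML.

## Diversity statistics

All frequencies are direct counts. For a spectrum with frequencies
$P_i$ over $n$ observations:

$$\mathrm{GD\ or\ HD} = \frac{n\,(1 - \sum_i P_i^2)}{n-1}, \qquad
  \mathrm{HMP} = \sum_i P_i^2, \qquad
  \mathrm{DC} = N_\mathrm{diff}/N.$$

The same estimator serves gene diversity (per-locus allele spectrum) and
haplotype diversity (whole-haplotype spectrum). For a multi-copy locus the
combined call is the state, which is why such loci show both the largest
allele counts and the highest GD values. InDel loci use the same formula
on their two-state spectra.

```{r diversity}
dong_like <- sample_from_spectrum(list(c(1, 296), c(2, 8)), seed = 1)
diversity_stats(haplotype_spectrum(dong_like))
```

Internally everything is kept at full precision; the reporting layer
(`run_diversity()`'s JSON summary) also carries values rounded in the
style of forensic reports — HD and HMP to 5 decimals, DC to 4. Note that
DC over 312 individuals with 304 haplotypes is 0.974359…, which prints as
0.9744.

`panel_report()` compares kits on one sample. Because a sub-panel is a
projection, it can only merge haplotype classes: DC and HD are
non-decreasing and HMP non-increasing in panel growth. This monotonicity
is asserted property-style in the test suite.

## Rst by haploid AMOVA

Between-population distances use the STR-specific differentiation
statistic Rst, computed here from first principles rather than through an
external service. The molecular distance between two haplotypes is the
squared repeat difference summed over loci; microvariant fractions enter
numerically (14.1 vs 14 differs by 0.1), preserving allele identity
without an intermediate-allele exclusion list. Multi-copy and InDel loci
are excluded by default (`rst_loci()`), since repeat differences are
undefined for unordered multi-allele states and InDels are not STRs; the
locus set is a plain argument, so any other convention is one call away.
Individuals with missing or anomalous calls at an included locus are
dropped listwise for that comparison.

The AMOVA partitions sums of squared deviations: the total SSD is the sum
of pairwise distances over all $N$ individuals divided by $N$; the within
component is the analogous per-population sum divided by the population
size; among is the difference. With $P$ populations,
$df_a = P-1$, $df_w = N-P$,
$\sigma^2_w = SSD_w/df_w$,
$\sigma^2_a = (SSD_a/df_a - \sigma^2_w)/n_0$ with
$n_0 = (N - \sum_p n_p^2/N)/(P-1)$, and
$R_{ST} = \sigma^2_a/(\sigma^2_a+\sigma^2_w)$.

Negative Rst estimates (sampling noise around zero differentiation) are
reported as computed in `$rst` and clamped to zero in `$distance`, because
downstream ordination and tree building need non-negative dissimilarities.
`rst_permutation_p()` adds a label-permutation significance test with the
usual $+1$ correction — a convenience companion; published Y-STR studies
often report Rst without p-values.

```{r rst}
pair <- simulate_divergent_pair(sim_config(n = 40, generations = 100,
                                           delta = 2, seed = 3,
                                           panel = default_panels()$minimal))
amova_rst(pair, rst_loci(default_panels()$minimal))
```

## Ordination and trees

`classical_mds()` is Torgerson metric MDS — double centering of squared
distances and eigendecomposition, computed via `stats::cmdscale` —
chosen over iterative stress-majorization variants because it is
deterministic and exactly testable: on a Euclidean-realizable matrix it
reproduces the input distances to numerical precision. Negative
eigenvalues (Rst matrices are generally non-Euclidean) are truncated; the
reported `stress` is the normalized residual
$\sqrt{\sum (d - \hat d)^2 / \sum d^2}$, so users can judge how faithful
the plane is. Axes follow a fixed sign convention (first non-zero loading
positive) so repeated runs are identical.

`neighbor_joining()` implements canonical NJ with two determinism rules:
ties in the Q criterion are broken by the lowest pair of node indices (in
input label order), and a negative branch length is clamped to zero with
the subtraction transferred to its sibling edge, preserving the pair's
total length. On additive matrices NJ provably recovers the generating
topology and branch lengths, which the tests exercise on randomized trees
up to 8 leaves; `ape::nj` serves as an independent cross-check there. The
tree is returned as an `ape` `"phylo"` object; `to_newick()` /
`from_newick()` serialize with proper quoting of labels containing spaces.

## The simulator

The generator is a forward stepwise-mutation model: every lineage descends
independently from a common founder haplotype for $g$ generations, and per
generation each allele copy mutates with probability $\mu$, stepping
$\pm 1$ repeat with equal probability. Defaults are chosen to look like
real Y-STR panels: $\mu = 3.35\times10^{-3}$ (the commonly cited average
Y-STR mutation rate), founder repeats drawn uniformly from 10–25, $g =
200$, $n = 312$ individuals — the reference-sample size the package's
examples emulate. Microvariant lineages carry an inherited +0.1 fractional
offset at configured loci (2% of lineages by default), mutating in whole
steps, mirroring how 14.1-type alleles behave; multi-copy loci evolve one
value per copy with a small rate of extra-copy (tri-allelic) patterns;
InDels are drawn from fixed state frequencies. `simulate_divergent_pair()`
shifts population B's founder by $+\delta$ repeats before within-population
drift, giving a single differentiation dial: $\delta = 0$ is the null case
and large $\delta$ relative to drift variance saturates Rst at 1.

`sample_from_spectrum()` is different in kind: it realizes an exact
haplotype frequency spectrum (so many states seen once, so many twice, …)
by encoding state indices in a mixed radix over the panel's STR loci, with
seeded shuffling of allele alphabets and row order. It is the right tool
when a test or report needs the spectrum itself to be exact rather than
drift-realistic — e.g. 296 singletons + 8 doubletons over 44 markers.

What the simulator deliberately does not model: population growth and
coalescent genealogy (lineages are independent, so haplotype sharing is
rarer than in a real pedigree-structured population), multi-step
mutations, locus-specific mutation rates, and linkage between the Y
markers' mutation histories beyond their shared founder. Passing tests on
simulated data therefore validate the statistical machinery, not any
demographic claim about a real population.

## Numerical choices and edge cases

* Spectra validate $\sum P_i = 1$ to 1e-12; AMOVA asserts SSD additivity
  to 1e-9.
* `gene_diversity` requires $n \ge 2$ (the correction is undefined at
  $n = 1$); an all-identical sample gives exactly 0, two distinct states
  at $n = 2$ give exactly 1.
* MDS of an all-zero matrix returns all points at the origin with zero
  stress; requesting $k \ge$ the number of populations is an error.
* Problem sizes in the test suite are deliberately small (populations of
  tens of individuals, trees to 8 leaves, 100–200 Monte-Carlo
  replicates): large enough to pin the properties, small enough that the
  whole suite runs in well under a minute.

## Known limitations

* Rst only; no allele-identity Fst, and no hierarchical (region ×
  population) AMOVA.
* No confidence intervals on the diversity statistics, and no bootstrap
  support on NJ trees.
* The MDS is the classical metric variant; proprietary tools ship
  iterative variants whose coordinates will differ by more than rotation
  when the matrix is strongly non-Euclidean — compare via the reported
  stress.
* The shipped 44-marker roster approximates the megaplex kits in common
  use; for exact kit work, supply the kit's locus list as configuration.
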