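# ystrtools

Forensic Y-STR haplotype diversity, AMOVA Rst distances, and population
structure summaries in R.

Forensic laboratories characterize a Y-marker panel in a reference
population by typing a few hundred unrelated males and summarizing the
result with a handful of direct-count statistics; the same haplotype data
then feed population-comparison analyses. `ystrtools` implements that whole
workflow on plain delimited haplotype tables, including the awkward
naming edge cases real Y-STR data contain: microvariant alleles (`14.1` =
14 repeats + 1 bp), multi-copy loci whose unordered 2–3 allele calls form a
single state (`19,21,22` at DYS527), and binary Y-InDel markers.

## The statistics

For a locus (or a whole haplotype) with state frequencies `P_i` estimated
by direct counting over `n` individuals:

- **Gene / haplotype diversity** `GD or HD = n (1 − Σ P_i²) / (n − 1)` —
  the small-sample-corrected probability that two random males differ.
- **Haplotype match probability** `HMP = Σ P_i²`.
- **Discrimination capacity** `DC = N_diff / N` — distinct haplotypes over
  sample size.
- **Rst** between populations, from a haploid analysis of molecular
  variance (AMOVA) over the squared repeat-difference distance
  `d(h₁,h₂) = Σ_loci (r₁ − r₂)²`: with among/within variance components
  `σ²_a, σ²_w`, `Rst = σ²_a / (σ²_a + σ²_w)`. Pairwise Rst matrices are
  summarized by classical (Torgerson) MDS and a Neighbor-Joining tree
  written as Newick.

A stepwise-mutation-model simulator (per generation, each allele mutates
with probability μ, default 3.35 × 10⁻³, stepping ±1 repeat) generates
fully synthetic populations, divergent population pairs with a tunable
founder shift δ, and samples realizing an exact haplotype frequency
spectrum, so every stage is testable without any external data.

## Worked example

A sample constrained to the published frequency spectrum of a 312-male
Dong reference sample — 296 haplotypes seen once and 8 seen twice over 44
Y-markers:

```r
library(ystrtools)
dong_like <- sample_from_spectrum(list(c(1, 296), c(2, 8)), seed = 1)
diversity_stats(haplotype_spectrum(dong_like))
#>     n n_distinct n_unique diversity  match_prob disc_capacity
#> 1 312        304      296 0.9998351 0.003369494      0.974359
```

Rounded to report precision these are HD = 0.99984, HMP = 0.00337 and
DC = 0.9744: the discrimination figures a 44-marker panel achieves in a
population where nearly every male carries a private haplotype.

Panel comparison on a simulated population (312 males, 40 generations of
stepwise mutation) shows the kit ladder behaving as expected — DC and HD
rise and HMP falls as loci are added:

```r
pop <- simulate_population(sim_config(n = 312, generations = 40, seed = 20))
panel_report(pop, default_panels()[c("minimal", "powerplex_y", "yfiler",
                                     "powerplex_y23", "yfiler_plus",
                                     "extended_44")])
#>          panel n_loci   n n_haplotypes     dc     hd      hmp
#>        Minimal      8 312          112 0.3590 0.8832 0.119617
#>    PowerPlex Y     11 312          153 0.4904 0.9325 0.070533
#>         Yfiler     16 312          220 0.7051 0.9811 0.022025
#>  PowerPlex Y23     22 312          275 0.8814 0.9962 0.007006
#>    Yfiler Plus     25 312          295 0.9455 0.9985 0.004684
#>    Extended 44     40 312          312 1.0000 1.0000 0.003205
```

Two populations simulated from a common founder with a 2-repeat founder
shift differentiate sharply:

```r
pair <- simulate_divergent_pair(sim_config(n = 80, generations = 150,
                                           delta = 2, seed = 3))
amova_rst(pair, rst_loci(default_panels()$extended_44))
#> <amova_rst> haploid AMOVA
#>   SSD among/within/total: 5485.0395 / 2516.4935 / 8001.5330
#>   df among/within: 1 / 158, n0 = 80.000
#>   sigma2 among/within: 68.36390 / 15.92717
#>   Rst = 0.81105 (distance 0.81105)
```

`pairwise_rst()` builds the full labelled distance matrix,
`classical_mds()` and `neighbor_joining()` summarize it, and
`run_diversity()` / `run_structure()` orchestrate the file-in/file-out
pipeline (there is also a thin CLI at `inst/cli/ystr-pipeline.R`).

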