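# rsmregulon

Plasmids do more than ferry accessory genes: many carry homologues of the
bacterial Rsm/CsrA family of small, homodimeric translational regulators.
These proteins bind `GGA`-core motifs — canonically `AnGGA`, presented open
at the apex of an mRNA hairpin loop near the ribosome-binding site — and
thereby repress or activate translation of hundreds of host transcripts,
switching behaviours such as motility, biofilm formation and carbon-source
use. `rsmregulon` implements the computational toolkit for studying such a
plasmid-borne regulator end to end, for microbial genomicists and molecular
microbiologists:

* **Carriage surveys** — contingency tables of regulator carriage across
  plasmid taxa, Fisher exact tests (exact hypergeometric for 2×2; exact
  network or seeded Monte Carlo for 2×k), carriage-by-mobility association
  with Bonferroni correction, plasmid size-distribution summaries, and
  Kolmogorov–Smirnov comparisons of predicted binding-site density.
* **A sequence-plus-structure binding model** — scanning of `AnGGA` (full)
  and `GGA` (minimal) motifs in each gene's 5′ window (up to 500 nt
  upstream plus the first 100 nt of the ORF), maximum base-pairing folding
  of 30-nt probes centred on each hit (Nussinov dynamic programming with
  G–U wobble, minimum loop 3), classification of motif exposure
  (APEX / PARTIAL / OCCLUDED / LINEAR), and qualitative binding calls
  (STRONG / TRANSIENT / NONE, with one-level attenuation for H43A/R44A
  binding-surface mutants).
* **Quantitative SPR analysis** — theoretical Rmax from the mass-ratio
  relation `Rmax = s·(MW_A/MW_L)·RU_immob`, %Rmax, three-way binding calls
  at the 50% line, and two-factor (site × variant) ANOVA.
* **Homologue divergence** — alignment hygiene (majority-gap column
  filtering at >60%, nucleotide-identical deduplication), Jukes–Cantor
  distances `d = -(3/4)·ln(1 - 4p/3)` with saturation handling, and
  Bonferroni-corrected Wilcoxon comparisons of chromosome–chromosome,
  chromosome–plasmid and plasmid–plasmid distance classes.
* **Regulon classification** — integration of protein and mRNA fold-change
  tables under the 2-fold rule, post-transcriptional discordance modes,
  direct/indirect partition against binding-site predictions, and COG
  tabulation.
* **Trait statistics** — relative fitness (ratio of Malthusian
  parameters), the Simonsen-type end-point conjugation-rate estimator
  `γ = ψ·ln(1 + T·N/(R·D))/(N − N0)`, Miller units
  `1000·(A420 − 1.75·A550)/(t·v·OD600)`, and the swarming index.

Every input the pipeline consumes can be generated by the package's
synthetic-data module with ground-truth labels, so the full analysis is
testable without any external download. All user-facing functions take and
return tibbles and compose with the pipe; `plot_*()` functions give ggplot2
views of the main result types.

## Worked example

Simulate a regulatory genome in which half of the 50 target genes carry a
full `AnGGA` site at a hairpin apex and a quarter carry the minimal `GGA`,
predict the direct regulon from sequence and structure, and integrate it
with simulated proteomics:

```r
library(rsmregulon)

cfg     <- regulon_config(n_targets = 50, n_background = 150, seed = 42)
sim     <- sim_regulatory_genome(cfg)
pred    <- predict_regulon(sim$genes, sim$genome)
expr    <- sim_expression_tables(sim$truth, cfg)
classes <- classify_fold_changes(expr$protein, expr$mrna)
direct_indirect_partition(classes, pred$genes)$summary
#> # A tibble: 3 × 3
#>   site_class     n fraction
#>   <chr>      <int>    <dbl>
#> 1 FULL          25     0.5
#> 2 SHORT_ONLY    12     0.24
#> 3 NONE          13     0.26
```

All 50 planted targets are recovered as repressed (positive protein log2
fold change with a quiet mRNA layer — the post-transcriptional signature),
and the site fractions among regulated genes recover the generator's
50% / 25% configuration. The structural side of the binding model is
equally inspectable:

```r
fold_oligo("GCCCCCAACGGAAGGGGGC")
#> <rsm_fold> 19 nt, 6 pairs
#>  GCCCCCAACGGAAGGGGGC
#>  ((((((.......))))))
```

with the `ACGGA` motif sitting unpaired in the terminal loop — an APEX
exposure, hence a STRONG predicted interaction for the wild-type protein.
On the published per-family carriage table, the non-uniformity of carriage
across taxa is decisive:

```r
fisher_exact(compass_family_counts()[1:4, ])$p_value
#> [1] 1e-05   # Monte Carlo lower bound; far below 0.0005
```

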