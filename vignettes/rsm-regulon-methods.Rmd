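---
title: "Methods: surveying, predicting and quantifying a plasmid-borne Rsm regulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying, predicting and quantifying a plasmid-borne Rsm regulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsmregulon)
```

`rsmregulon` models the biology of plasmid-encoded Rsm/CsrA-family
translational regulators along five connected axes: where regulator
homologues occur across plasmid collections, which mRNAs they can bind,
how strongly they bind in vitro, how divergent plasmid homologues are from
chromosomal ones, and what the regulon looks like when mRNA and protein
abundance changes are integrated. This vignette explains the models behind
each axis, the parameters that matter, what the synthetic-data generators
do and do not emulate, and the numerical decisions taken where the design
was genuinely open.

## The binding model

Rsm/CsrA proteins recognise a short RNA element: a `GGA` core, usually
embedded in the extended `AnGGA` motif, presented single-stranded at the
apex of a hairpin loop near the ribosome-binding site. The package
operationalises this in three steps.

**Motif scanning.** `scan_motifs()` reports every `AnGGA` occurrence
(class FULL) and every `GGA` that is not contained in a reported FULL hit
(class SHORT). The two classes are deliberately disjoint so that per-gene
summaries ("has a full site" vs "has only the minimal site") partition
cleanly; overlapping hits of the same class are all reported. T and U are
interchangeable throughout: the in vitro binding work this model reflects
used ssDNA probes as a structural proxy for RNA, and nothing in the model
depends on the distinction.

**Folding.** `fold_oligo()` computes a maximum base-pairing nested
structure (Nussinov-style dynamic programming) with Watson–Crick and,
by default, G–U wobble pairs and a minimum hairpin loop of 3 nt — the
steric minimum. This is an intentional simplification: the pipeline uses
folds only *qualitatively*, to decide whether a motif is open at a
terminal loop or sequestered in a stem, and a maximum-pairing structure
answers that reproducibly and fast. A thermodynamic folding engine could
be substituted behind the same `rsm_fold` contract (sequence, pair list,
loop decomposition) without touching anything downstream. Among co-optimal
structures the traceback is deterministic: the 5′ base of the current
interval is paired if any optimal structure pairs it, with the outermost
partner preferred, before considering leaving it unpaired. All results are
therefore reproducible to the byte.

**Exposure and binding calls.** `classify_exposure()` assigns exactly one
class per (structure, hit): APEX when every motif base is unpaired and all
lie in a single terminal loop; OCCLUDED when every motif base is paired;
LINEAR when the whole molecule is unpaired; PARTIAL otherwise (e.g. a
motif straddling a stem and its loop). `predict_binding()` then encodes
the qualitative rule table observed by surface plasmon resonance: an apex
motif binds strongly regardless of FULL/SHORT class; a linear or partially
occluded motif binds transiently; an occluded motif (or no motif) does not
bind; and the H43A/R44A substitutions in the conserved RNA-binding surface
attenuate the call by one level.

**Windows and probes.** `predict_regulon()` scans, per gene, the region up
to 500 nt upstream of the start codon plus the first 100 nt of the ORF —
the span in which a bound regulator can plausibly affect translation
initiation — truncated at contig ends and at short ORFs. Exposure is
evaluated not on the whole window but on a 30-nt probe centred on each
hit, mirroring the 30-bp probe design used for the binding assays; probes
at window boundaries shift asymmetrically to preserve their length. Both
spans and the probe length are arguments, because "upstream" is not
defined identically in every analysis tradition. `decompose_ncrna()`
applies the same machinery to regulator-sequestering small RNAs, tiled
into 25-nt segments (the stem-loop probe length).

## The survey statistics

Carriage of a regulator homologue is detected by local protein alignment
(`Biostrings::pairwiseAlignment`, BLOSUM62, gap open 10 / extend 1)
against a reference set, with defaults of identity ≥ 0.35 over ≥ 70% of
the reference — conventional thresholds for a ~60-residue family, exposed
as arguments since annotation pipelines differ. The downstream statistics
are classical and are delegated to R's implementations: Fisher's exact
test (two-sided 2×2 p as the hypergeometric sum of tables no more probable
than the observed; exact network algorithm for small 2×k tables; seeded
Monte Carlo with the (b+1)/(B+1) estimator above a configurable total),
the two-sample Kolmogorov–Smirnov test, and Wilcoxon rank-sum tests. The
test suite verifies these against independent oracles written for the
purpose: full hypergeometric enumeration for every 2×2 table with total
≤ 30, and a brute-force ECDF supremum for small samples. Fisher's test and
the exact KS null are discrete and therefore conservative; the null
simulations in the test suite assert nominal size for the (continuous)
Wilcoxon and near-nominal, never anticonservative, behaviour for Fisher
and KS.

Carrier size ranks use a midrank-among-others convention: a carrier's
quantile rank within its family is computed against the *other* family
members, counting ties as half. A carrier larger than all others ranks
1.0; in an all-equal family every carrier ranks 0.5.

## SPR quantification

The theoretical maximum response is the standard mass-ratio relation
`Rmax = s · (MW_analyte / MW_ligand) · RU_immobilised`. The analyte is
treated by default as the regulator homodimer (Rsm proteins act as
dimers) with stoichiometry `s = 1`; both are arguments because published
%Rmax values do not always state which convention was used. Binding calls
use a strict 50% threshold (BOUND means *greater than* 50%) and a 10%
noise floor below which a response is called NONE; the floor is an
artefact-handling decision needed for a three-way call, not a published
constant. Values above 100% are legitimate and flagged as potential
higher-order binding. Technical replicates are averaged before group
statistics; site × variant panels are decomposed by fixed-effects ANOVA,
with the interaction dropped and flagged when cells lack replication.

## Divergence analysis

Alignment hygiene follows the usual comparative-genomics conventions:
columns that are strictly majority-gap (> 60%) are removed (a column at
exactly 60% is retained), and nucleotide-identical sequences are collapsed
to one representative before analysis. Jukes–Cantor distances use
pairwise deletion by default (each pair is compared over its own
gap- and ambiguity-free sites; complete deletion is available), with
`d = -(3/4)·ln(1 − 4p/3)` undefined and flagged saturated at p ≥ 3/4.
Distance sets for the three origin classes (chromosome–chromosome,
chromosome–plasmid, plasmid–plasmid) are compared by Wilcoxon rank-sum
tests with Bonferroni correction over the three comparisons. Pairwise
distances sharing a sequence are not independent observations; the
comparison treats them as if they were — as is conventional for this
analysis — and says so in its method note.

## Regulon integration

The fold-change contrast is fixed as regulator-deleted over
regulator-present, so a **positive** protein log2 fold change means the
protein is more abundant without the regulator, i.e. *repressed* by it;
every classification table carries this contrast string to prevent sign
errors. The 2-fold rule (|log2FC| ≥ 1) with a BH-adjusted p ≤ 0.05 defines
regulation; both thresholds are arguments, and significance can be
disabled to classify on fold change alone, since published counts are
sometimes defined by fold change only. Genes detected in one layer are
classified on that layer with mode UNDETERMINED rather than dropped. Modes
compare layers: POST_TRANSCRIPTIONAL (protein regulated, mRNA quiet or
opposite), CONCORDANT (both, same direction), TRANSCRIPTIONAL (mRNA
only). The partition against binding-site predictions conserves counts by
construction, and regulated genes missing from the prediction table are
counted as no-site with a warning rather than silently vanishing.

## Trait formulas

Relative fitness is the ratio of Malthusian parameters. The conjugation
rate uses the Simonsen-type end-point estimator with the population growth
rate computed from total density `N = D + R + T`; zero-transconjugant
replicates return `γ = 0` flagged below detection, mirroring the
convention of excluding such replicates from aggregate means. Miller units
and the swarming index are the standard closed forms. Degenerate inputs
(zero growth, zero denominators, colony larger than plate) error rather
than returning misleading numbers.

## The synthetic-data generators

The generators produce every input the pipeline consumes, with ground
truth emitted alongside, and are deterministic given seed and
configuration. Defaults encode the study conditions the analyses assume:

* **Survey** (`survey_config()`): four focal families with 196, 67, 29 and
  3,621 plasmids at carriage probabilities 0.21, 0.18, 0.72 and 0 — the
  published per-family carriage pattern — log-normal sizes centred at
  ~50 kb (sdlog 0.8) with carriers shifted upwards (carriers sit at the
  large end of each family's distribution), and a
  conjugative/mobilizable/non-mobilizable mix of 0.30/0.25/0.45, optionally
  conditioned on carriage.
* **Regulon** (`regulon_config()`): among target genes, 50% planted FULL
  and 25% SHORT sites (the observed coverage of the regulated set), a +2
  protein log2 fold-change effect on a 0.1 log2 noise floor with no mRNA
  effect (the post-transcriptional signature), upstream regions of
  150–400 nt and 500-nt ORFs so that one gene's search window never
  reaches into a neighbour's upstream region. Adjusted p-values are BH
  corrections of two-sided z-tests under the same effect/noise model. The
  mRNA noise model for which no published value exists is the same
  Gaussian log-ratio noise; any plausible log-scale noise serves the
  recovery tests equally.
* **Motif constructs**: background sequence is uniform A/C/G/T, keeping
  the chance-GGA rate analytically computable (1/64 per position). Apex
  constructs flank the motif with perfectly complementary 6-bp stems
  (`GCCCCC…GGGGGC`) and single-base loop margins chosen so no background
  base can out-pair the designed hairpin; the margin switches to C when
  the motif's variable base is T, which would otherwise wobble-pair into
  the loop. By default, chance `GGA` occurrences outside planted
  constructs are scrubbed (including motifs formed across segment
  junctions) so "motif-free" genes are truly motif-free and recovery is
  exactly scoreable; with `scrub_background = FALSE` the analytic chance
  background is retained.
* **SPR** (`sim_spr_responses()`): percent-Rmax means of 85 / 30 / 1 for
  STRONG / TRANSIENT / NONE with 4-point Gaussian noise, floored at zero —
  comfortably separated across the 50% and 10% decision lines, as the
  published panels are.

What the generators do **not** emulate: codon usage and operon structure,
read-level RNA-seq or spectrum-level proteomics noise, real plasmid gene
content, or thermodynamic folding landscapes. Passing the recovery tests
therefore demonstrates that the pipeline's logic is correct under its own
assumptions, not that real data are this clean; on real sequence, apex
exposure depends on a thermodynamic ensemble and recovery will be lower.

## Problem sizes and numerics

The test and acceptance workloads use deliberately compact sizes chosen to
exercise every code path: planted genomes of 80–200 genes, homologue
screens of ~30 plasmids × 3–4 proteins, 1,000-replicate null simulations,
the full enumeration of 2×2 tables with total ≤ 30 (46,375 tables), and
1,000 random ≤ 18-nt oligos for the folding oracle. Numerical choices:
Fisher point-probability ties use a relative tolerance of 1e-7; the
Monte Carlo Fisher path uses a fixed default seed (12345) and 1e5
replicates; Wilcoxon uses the normal approximation with tie correction
(exact available for tiny samples), with fully tied samples returning
p = 1 directly; fold tracebacks are deterministic as described; sequences
too short to pair fold to the trivial unpaired structure rather than
erroring.

## Known limitations

Maximum base-pairing over-predicts structure relative to free-energy
models and has no notion of competing conformations; exposure classes are
therefore best treated as a screen, with PARTIAL calls especially
sensitive to the probe window. The binding-call rules are qualitative by
design and do not model concentration dependence or kinetics (no ka/kd
fitting). The homologue screen is alignment-based and will not resolve
the deep paralogy structure an HMM or phylogenetic placement would. The
Wilcoxon divergence comparison inherits the non-independence caveat noted
above. None of these limitations affect the package's statistical
primitives, which are oracle-verified.
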