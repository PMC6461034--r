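---
title: "Inferring kinase activity from single-sample phosphoproteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring kinase activity from single-sample phosphoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inka)
```

## The model

A hyperactive kinase leaves two distinct footprints in a phosphoproteome:
its own protein is phosphorylated (notably in the activation segment of the
kinase domain), and its substrates are phosphorylated. This package scores
both footprints per kinase and per sample and integrates them.

Evidence is quantified as a *phosphosignal*. On the kinase-centric side each
phosphopeptide assigned to the kinase contributes its spectral count
multiplied by its number of phospho modifications, accounting linearly for
all phosphorylation on the peptide; summing over all kinase peptides gives
the kinome arm `C_Kinome`, and summing over the annotated activation-segment
peptides gives `C_ActivationLoop`. On the substrate-centric side each
peptide's multiplied count is further divided by the number of phosphosites
inferred for that peptide — the inferred-site count can exceed the true
number of modifications, and the division keeps the signal from being
exaggerated — then contributions of all peptides harboring a site are summed
into a site phosphosignal, which is credited in full to every kinase linked
to the site by a curated (`C_PSP`) or predicted (`C_NWK`) relation. With

$$C_{kin} = C_{Kinome} + C_{ActivationLoop}, \qquad
  C_{sub} = C_{PSP} + C_{NWK},$$

the integrated score is the geometric mean
$\mathrm{INKA} = \sqrt{C_{kin} \, C_{sub}}$, and the evidence balance is
$\mathrm{skew} = \tfrac{2}{\pi}\arctan\sqrt{C_{sub}/C_{kin}} \in [0,1]$
(0 all kinase-centric, 1 all substrate-centric, 0.5 balanced, undefined and
reported as `NA` when both sums are zero). The geometric mean means a
non-zero score requires *both* lines of evidence, which is precisely what
makes the integrated ranking more robust than any single arm: a lone hot
peptide inflates only one side.

Assumptions worth keeping in mind: spectral counts are treated as a linear
abundance proxy; relations are taken at face value (a site claimed by
several kinases credits each in full, with no fractional splitting — shared
peptides of close homologs likewise credit every matching kinase); and the
activation-loop arm deliberately re-counts peptides already in the kinome
arm, up-weighting activation-segment evidence in `C_kin`.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| class I cutoff | 0.75 | site localization probability must exceed this (strict) |
| prediction floor | 2.0 | minimum prediction score for a relation |
| relative prediction cutoff | 0.9 | score must also exceed 90% of the site's best (strict >; the maximum always survives the relative rule) |
| plot fraction | 0.1 | scatter shows kinases with INKA ≥ 10% of the top score |
| top n | 20 | bar graph and network size cap |
| out-of-scope minimum | 2 | raw spectral counts required for the out-of-scope bar (intensity mode: non-zero quantification in ≥ 2 peptide rows, since "two spectral counts" has no intensity analogue) |
| permutation iterations | 100000 | null-distribution size (tests use 1000) |
| skew formula | `sqrt` | see below |

All thresholds are arguments of the corresponding functions so boundary
behavior is testable; the defaults are the published operating point.

**Skew formula.** The anchor values 0, 0.5 and 1 are satisfied both by
$\tfrac{2}{\pi}\arctan\sqrt{C_{sub}/C_{kin}}$ and by
$\tfrac{2}{\pi}\arctan(C_{sub}/C_{kin})$. We default to the square-root
form — it is the normalized angle of the point
$(\sqrt{C_{kin}}, \sqrt{C_{sub}})$, whose radius is the INKA score, so score
and skew are the polar coordinates of one evidence point — and expose the
alternative via `skew_formula = "ratio"`.

## Data processing decisions

- Peptide rows listing several gene symbols are deconvoluted to one row per
  symbol; decoy/contaminant flags are honored when the columns exist.
  Rows with zero phospho modifications are dropped.
- Site rows listing several accessions or peptides are split; after symbol
  normalization, one accession is kept per (site, gene): the best rank in an
  optional accession-priority table, then the lexicographically smallest
  accession. The original procedure delegates this to a proprietary
  annotation ranking that is not published; an explicit priority input keeps
  the choice deterministic and testable.
- `n_inferred_sites` for a peptide is the number of distinct class I sites
  linked to it in the merged table — the closest observable quantity to the
  search engine's inferred-site count.
- Kinase-centric evidence is drawn from the *merged* table, so a kinase
  peptide without any class I site contributes nothing; this follows the
  published table construction.
- Relations match observed sites on (official symbol, position, residue);
  isoform position offsets are out of scope. Predictions lacking a residue
  column match on (symbol, position).
- Quantification mode: identical formulas apply to intensities
  (`quant_mode = "intensity"`); counts are the recommended default.

## Significance

Null INKA scores are generated by a double randomization per iteration:
the sample's non-zero quantifications are permuted among the peptides that
had non-zero values (zeros stay zero, so identification structure is
preserved), and every relation's kinase is replaced by a uniform draw from
the pool of kinases present in the pooled relation tables. Counts are
permuted at the peptide level and propagated to all site rows of a peptide,
keeping duplicated rows consistent; permutation is within-sample only. The
one-sided upper-tail p-value uses the add-one estimator
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + B)$, which is standard,
conservative, and never returns zero. No multiple-testing correction is
applied by default (raw p < 0.05 is the published flag); Benjamini–Hochberg
adjusted values are available as a clearly-labeled extension
(`adjust = TRUE`). A kinase with a zero observed score has $p = 1$
identically — every null score is non-negative — so distributional checks of
the p-values concern the kinases with positive scores.

## The synthetic-data generator

`simulate_experiment()` emulates the full input bundle at toy scale with
known ground truth. Defaults: 50 catalog kinases, 100 substrate proteins,
2 own phosphopeptides per kinase (the first annotated as activation-loop),
3 substrate sites per kinase, background counts Poisson with mean 2, one
driver kinase whose own and substrate peptides get a 10-fold boosted mean,
70% of kinases (drivers first) present in the relation tables, 85% of
localization probabilities above 0.75 (the rest straddle the cutoff to
exercise the class I filter), relations split roughly evenly between the
curated and predicted sources with 15% in both, 1–2 phospho modifications
per peptide. `dispersion_sdlog` optionally mixes a lognormal per-peptide
abundance factor into the Poisson means for overdispersed counts; the
default 0 keeps the background exactly Poisson. The file renderings plant a
decoy row, a contaminant row, a non-phospho row, a shared two-kinase
peptide, a multi-accession site, non-human curated relations, sub-threshold
predictions and a gene alias, so every reader-side filter is exercised on
the file path as well.

What it does *not* emulate: missing-value structure from data-dependent
acquisition, shared peptides across unrelated proteins, isoform position
ambiguity, realistic kinase-substrate network topology (hubs), or
correlated peptide abundances within a protein. Passing the driver-recovery
and null-uniformity checks therefore demonstrates correctness of the
scoring machinery under controlled conditions, not performance on real
spectra.

Test problem sizes are chosen to keep the suite fast while leaving no
behavior untested: oracle comparisons run on hundreds of random instances
of at most 50 rows; driver recovery uses 100 generator seeds at the default
conditions; permutation checks use 1,000 iterations (standing in for the
production default of 100,000) with 200 kinases for the null-uniformity
check.

## Numerical and tie-breaking choices

- All rankings sort by descending score with alphabetical kinase symbol as
  the tie-break, making outputs deterministic.
- `skew(0, 0)` is `NA`; `inka(0, x) = 0` exactly.
- Degenerate inputs: an all-zero sample permutes to itself; an empty
  ranking yields an empty network with a warning; an all-zero activity list
  or an empty kinase pool is a fatal error; zero logIC50 spread normalizes
  to all-zero efficacies with a warning.
- Layout: Fruchterman–Reingold coordinates use `niter = 100·N`; the grid
  variant's `area = N^1.8`, `repulse.rad = N^1.5` and `ncell = N^3` are not
  exposed by the igraph backend and are recorded as graph attributes
  instead, so an exporter with a grid FR implementation can apply them.
- Network membership: edges come from the top-n INKA kinases; kinases with
  substrate links to those same sites but no own observed phosphopeptide
  join as *inferred* (pentagon) nodes — they can never enter the INKA
  ranking themselves, since their kinase-centric sum is zero and the
  reciprocal analysis is deliberately not performed.
- The substrate-centric sum adds the curated and predicted arms as printed;
  a site claimed by the same kinase in both resources is counted in both
  arms (the network tags such links `both`).
- Drug-impact comparison: "a nonparametric test paired over cell lines" is
  implemented as the Wilcoxon signed-rank test on per-sample paired
  differences (a Mann–Whitney test is unpaired by construction; the
  unpaired variant is available via `test = "mann-whitney"`). Impact is
  computed per sample; samples of the same cell line are paired per sample.
  Identical impact curves give p = 1 at every list length.

## Limitations

Rankings depend on the coverage and quality of the relation resources:
kinases without curated substrates or reliable motifs can only appear in
the out-of-scope list, however active they are. Spectral counts saturate
for very abundant peptides, compressing differences at the top. Permutation
p-values inherit the granularity of the iteration count and are raw, not
FDR-controlled, by default. The impact score treats all drug-target links
as equal (binary `g_ij`) and logIC50 normalization is per cell line, so
impact values are comparable across ranking methods within a cell line, not
across cell lines.
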