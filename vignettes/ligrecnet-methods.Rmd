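---
title: "Methods: building ligand–receptor cell-to-cell communication networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building ligand–receptor cell-to-cell communication networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligrecnet)
```

## Scope and model

`ligrecnet` reconstructs a draft map of intercellular signalling among human
primary cell types from three ingredients: a gene-level expression atlas in
tags/transcripts per million (TPM), a curated and inferred set of directed
ligand–receptor pairs, and simple threshold logic. A cell type A can signal
to a cell type B through pair (L, R) when A expresses the ligand L and B
expresses the receptor R at or above a detection threshold; the strength of
that path is summarised as the product of the two expression levels. The
package also carries the two statistical companions of that map: binomial
enrichment tests on where pairs reach their maximal expression (lineage
analysis), and a binomial test of whether receptors tend to predate their
cognate ligands on a phylostratigraphic age scale (evolutionary analysis).

The pipeline is deliberately assembled from transparent primitives —
set algebra on gene symbols, thresholded boolean matrices, exact binomial
and Mann–Whitney tests — because each step mirrors a decision that was made
on the real atlas data and must remain auditable.

## Subcellular localization consensus

Candidate ligands must be secreted and candidate receptors must sit in the
plasma membrane, so the pipeline starts with a per-protein localization
consensus over three evidence channels:

1. **Tier 1, curated annotation (UniProt-style).** Experimentally verified
   or probable compartments are accepted as-is. No transmembrane-helix
   (TMH) requirement applies: curated evidence outranks topology
   predictions.
2. **Tier 1, literature-backed annotation (HPRD-style).** Accepted only
   with an attached PubMed ID. A plasma-membrane call from this channel
   additionally requires at least one predicted TMH; an annotation failing
   that check falls through to Tier 2 rather than being trusted.
3. **Tier 2, prediction.** The predicted compartment is accepted with two
   topology constraints: plasma membrane needs `tmh_count >= 1`, secreted
   needs `tmh_count <= 1`. Records failing these are unclassifiable
   (`n/a`).

Compartments outside cytoplasm/nucleus/plasma membrane/secreted collapse to
`other` through a user-extensible synonym map. Where one accepted source
reports two or more distinct core compartments the protein is labelled
`multiple`. When the two Tier-1 channels disagree the curated channel wins;
this is a design choice (the tie-break is not dictated by the evidence
model) and is kept deliberately simple and deterministic.

The published analysis reports 12,976 Tier-1, 5,906 Tier-2 and 171
unclassifiable proteins on its 2014 annotation snapshot. Those counts
depend on the snapshot and are not reproducible from rules alone; they are
treated as documentation, not as tests.

## Pair assembly and provenance

Known pairs from several database exports are unioned as *directed*
(ligand, receptor) pairs with per-pair source and PMID provenance. The same
unordered pair appearing with swapped roles in two sources is a hard error:
silently keeping either orientation would corrupt every downstream
direction-sensitive statistic.

Candidate sets are then widened (known ligands ∪ orphan ligands ∪ secreted
proteins not known as receptors, and the mirror image for receptors), and
novel pairs are inferred from PPI evidence: HPRD-style interactions with
in vitro / in vivo / yeast two-hybrid evidence, or STRING-style
physical-binding / experimental channels with confidence ≥ 700 (inclusive,
the two channels evaluated independently). PPI endpoint order is ignored.
Self-pairs are dropped by default (`allow_self = TRUE` overrides).

A manual curation table is applied last: `add` introduces a pair, `exclude`
retains it with status `excluded` but bars it from every network module
(enforced by `active_pairs()` and tested), and `keep` attaches a PMID. A
non-excluded pair is `reference` when at least one PMID is attached and
`putative` otherwise.

## Expression networks

* **Detection** is `TPM >= threshold`, default 10 (the conservative
  calibration of roughly three transcript copies per cell for CAGE data);
  50 and 100 are the other presets. The operator is configurable because
  some published figures use a strict `>` at a different cutoff.
* **Breadth** is the number of cell types detecting a gene. Ligand and
  receptor medians are taken over pair-participating genes; a gene is
  *specific* when its breadth is at or below its role's median. The `<=`
  tie rule keeps the median gene specific — with the `<` alternative a
  data set of identical breadths would have no specific genes at all,
  which reads wrong for the intended "restricted half" semantics.
* **Path counts** between ordered cell pairs include the diagonal:
  autocrine edges (A = B) are genuine signalling paths here, and the
  diagonal entries equal the autocrine numerators by construction (a
  cross-checked invariant).
* **Edge weights** are exactly `ligand_tpm * receptor_tpm`, stored
  alongside both factors; `top_n` truncation breaks weight ties by ligand,
  receptor, source cell and target cell names so exports are deterministic.
* Pair genes absent from the atlas are treated as never detected, with a
  warning rather than an error — real pair collections routinely contain
  genes outside any given expression panel.
* TSV exports carry 6 significant digits; GraphML and JSON exports carry
  full precision.

## Lineage statistics

For every pair, the *major transmitter* is the cell type with the highest
ligand TPM and the *major receiver* the one with the highest receptor TPM
(argmax ties broken by the lexicographically smallest cell-type name).
Cross-tabulating these by a six-lineage map (endothelial, epithelial,
haematopoietic, mesenchymal, nervous, other) gives a 6×6 matrix whose total
equals the number of pairs.

Two exact binomial test families follow, each Benjamini–Hochberg adjusted
as its own family (12 and 36 tests respectively):

* **Representation**: per lineage and role, is the lineage's share of
  max-expression cells different from its share of cell types? Two-sided
  tests, with the over/under direction reported separately, because both
  enrichment and depletion are of interest.
* **Path bias**: per ordered lineage pair, is the (A → B) count different
  from the product of the observed transmitter and receiver marginals?

The path-bias null deserves a caveat. With the plug-in product-of-marginals
p0 the exact binomial is conservative, for the same reason contingency-table
standardized residuals need the `(1 - p_A)(1 - p_B)` variance correction:
the marginals are estimated from the same matrix. At a uniform 6×6 null we
measure a rejection rate near 0.02 at α = 0.05. The function therefore also
accepts a fixed `null_p0` matrix (under which the test is calibrated up to
the discreteness of the binomial — our calibration runs sit near 0.045 at
α = 0.05 with n = 600 pairs), and a marginal-preserving permutation variant
(`n_perm`) that is calibrated by construction. The default remains the
plug-in binomial because that is the transparent, reproducible form of the
analysis this package re-implements.

## Evolutionary statistics

Phylostratum ranks use the convention larger = more recent origin, and
"ligand younger" means the ligand's rank exceeds the receptor's. Because
gene-age estimates are biased by protein length (ligands, median 267 aa,
are far shorter than receptors, median 515 aa), the null for the
receptor-before-ligand test is calibrated empirically: among generic
interacting protein pairs with one partner in the lower length quartile and
one in the upper quartile (boundary values included in the quartile, a
documented choice), p0 is the fraction where the younger protein is the
shorter one, with age ties excluded. The test itself is a one-sided exact
binomial of the ligand-younger proportion against that p0, with a one-sided
95% Clopper–Pearson lower bound on the proportion. From the published
counts — 1,082 ligand-younger of 1,513 untied pairs against p0 = 0.591 —
the package reproduces p < 0.001 and a lower bound of 0.695.

Class-level comparisons of cell-type specificity or age use two-sided
Mann–Whitney U tests over the five classes cytoplasm, nucleus, other,
plasma membrane and secreted (the `multiple` and `n/a` classes join on
request), BH-adjusted over the class pairs. The specificity score itself is
the package's own stand-in, since the original figure does not define one:
the default is `1 - breadth/n_cells` (linear in detection breadth), with a
normalised-entropy alternative on expression shares for users who want
graded rather than thresholded specificity.

## Synthetic data: what it emulates, and what it does not

The generator produces every input the pipeline consumes, with the
statistical structure the analysis assumes:

* **Atlas**: 24 cell types (4 per lineage) × 300 genes by default — a
  deliberate scale-down of the 144-cell-type atlas that keeps full runs in
  seconds. Housekeeping genes (180) draw from one log-normal
  (`meanlog = log 30`, `sdlog = 1.2` — heavy-tailed like CAGE TPM) across
  all cells; restricted genes (120) are boosted 10× in one home lineage
  and drop to zero elsewhere with probability 0.9. These defaults are the
  study conditions for all recovery tests and are not tuned per test.
* **Pairs and PPI**: 120 planted pairs; half draw both partners from genes
  restricted to one lineage (the planted lineage bias the representation
  test must flag), half from the remaining genes. Ligand and receptor
  pools are disjoint, so the generator cannot create self-pairs or
  swapped-role conflicts. A quarter of pairs are withheld from the three
  overlapping mock known-pair sources and given qualifying PPI support
  instead, so PPI inference must recover exactly the withheld set. Decoy
  PPIs connect dedicated non-candidate proteins with STRING-style scores
  straddling the 700 boundary.
* **Ages and lengths**: receptor strata are drawn first (ranks 5–15 of
  1–20); ligands tie with probability 0.15 and are otherwise younger with
  probability 0.5 + ε. Each gene gets a single age, so the planted ε is
  exact only when genes are not reused across pairs; recovery tests
  therefore use pair tables with unique genes (n = 1,500). A separate
  generator plants the younger-shorter probability q in a
  quartile-discordant PPI set (n = 2,000) for recovering the length-bias
  null.
* Every generator is a pure function of the configuration: it seeds the
  RNG from `cfg$seed` plus a fixed per-generator offset and restores the
  previous RNG state, so outputs are bit-identical across runs and
  independent of call order.

What the synthetic data does **not** emulate: promoter-level structure and
replicate noise of CAGE libraries, correlated expression within gene
families, hub structure of real PPI networks, or annotation errors in
localization databases. Green recovery tests therefore demonstrate that the
implementation is correct and well-calibrated under the assumed model, not
that the biological conclusions transfer to any particular real data set.

## Numerical and procedural choices

* Exact binomial machinery is `stats::binom.test` (two-sided for the
  lineage families, one-sided with Clopper–Pearson bound for the
  receptor-first test); rank tests are `stats::wilcox.test`; FDR is
  `stats::p.adjust(method = "BH")`. Test code cross-checks the one-sided
  p-value against a direct binomial tail summation and the U statistic
  against a pairwise comparison count.
* Degenerate nulls are handled explicitly: p0 = 0 with a positive count is
  an error; p0 = 0 with a zero count, and p0 = 1 with a full count, give
  p = 1.
* Replicate collapsing is the arithmetic mean of per-sample TPM with no
  re-normalization; a cell type with a single library is its own mean.
* Problem sizes used by the shipped checks: oracle equivalence on atlases
  up to 20 genes × 6 cells; calibration at 600 pairs × 1,000 replicates;
  recovery at 1,500 pairs (ages), 2,000 PPI pairs (length bias) and 100
  seeded pipeline runs (lineage bias). These sizes give Monte-Carlo
  standard errors small enough for 3-SE assertions while keeping the whole
  suite under a minute.

## Known limitations

* mRNA detection stands in for functional protein at the membrane or in
  the secretome; the concordance arithmetic quantifies, but does not
  remove, that gap.
* The published pair counts (1,179 known; 2,422 curated; 1,894 reference)
  depend on 2013–2014 database snapshots and cannot be regenerated from
  rules alone.
* The plug-in path-bias binomial is conservative (see above); use the
  permutation variant when calibrated intra/inter-lineage p-values matter.
* Argmax-based major-signalling pairs ignore second-ranked cell types
  entirely; a cell expressing a ligand marginally below another's maximum
  contributes nothing to the lineage matrix.

## A worked example

```{r example}
cfg <- sim_config(seed = 1)
report <- run_all(cfg)
report

# the planted haematopoietic bias is recovered
rt <- report$representation_test
subset(rt, lineage == "haematopoietic")
```
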