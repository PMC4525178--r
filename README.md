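# ligrecnet

Cell-to-cell communication in a multicellular organism runs largely through
secreted **ligands** binding **receptors** on the surface of other (or the
same) cells. Given a gene-level expression atlas over many primary cell
types (TPM units) and a collection of directed ligand–receptor pairs,
`ligrecnet` reconstructs the resulting draft signalling network and the
statistics that describe it. It is written for computational biologists who
want a tested, reproducible version of this classic atlas-scale analysis —
the kind of pipeline behind FANTOM5-style cell-to-cell connectome maps and
the ancestor of tools such as CellPhoneDB.

The package covers five analysis stages plus a synthetic-data module:

1. **Localization consensus** — tiered classification of proteins into
   {cytoplasm, multiple, nucleus, other, plasma_membrane, secreted, n/a}:
   curated annotation first (plasma-membrane calls from literature-backed
   sources additionally need a predicted transmembrane helix), predictions
   second (PM needs ≥ 1 TMH, secreted ≤ 1 TMH).
2. **Pair assembly** — union of known-pair databases with provenance,
   candidate expansion from localization (secreted → candidate ligand, PM →
   candidate receptor), novel-pair inference from PPI evidence (HPRD-style
   evidence types; STRING-style channels at confidence ≥ 700), and a manual
   curation table. Pairs with a PMID are *reference*, the rest *putative*,
   excluded pairs never reach the network stages.
3. **Expression network** — detection at a TPM threshold (default 10,
   presets 50/100); per-cell ligand/receptor repertoires; autocrine
   fractions; specific/broad quadrants by a median split on expression
   breadth; cell × cell path-count matrices; weighted edges with
   `weight = ligand_TPM × receptor_TPM`, exported as TSV, GraphML
   (Cytoscape/Gephi) or hive-view JSON.
4. **Lineage analysis** — per pair, the *major transmitter* (argmax ligand
   TPM) and *major receiver* (argmax receptor TPM); a 6 × 6 lineage matrix;
   exact binomial tests for lineage over/under-representation
   (x successes of n pairs against p0 = lineage's share of cell types) and
   for intra/inter-lineage path bias (p0 = product of observed marginals),
   each family Benjamini–Hochberg adjusted.
5. **Evolutionary statistics** — ligand vs receptor phylostratum tallies;
   a length-bias-calibrated null (fraction of length-discordant interacting
   pairs whose younger member is the shorter, p0 = x/n); the
   receptor-before-ligand test, a one-sided exact binomial of the
   ligand-younger proportion against p0 with a one-sided 95%
   Clopper–Pearson lower bound; Mann–Whitney comparisons of specificity and
   age across localization classes.
6. **Synthetic data** — seeded generators for every input (lineage-blocked
   log-normal atlas, overlapping pair sources, PPI tables with planted
   novel pairs and decoys, age/length tables with a tunable
   receptor-older excess) so the whole pipeline is testable without any
   download.

## A worked example

Run the complete pipeline on the default synthetic inputs (24 cell types,
300 genes, 120 planted pairs):

```r
library(ligrecnet)
report <- run_all(sim_config(seed = 1))
report
#> Cell-to-cell signalling pipeline report (threshold 10 TPM)
#>   localized        300
#>   known_pairs      80
#>   inferred_pairs   40
#>   final_pairs      120
#>   excluded_pairs   0
#>   expressed_pairs  118
#>   edges            13571
#>   major_pairs      118
#>   receptor-before-ligand: estimate 0.642 vs p0 0.667 (p = 0.745)
```

All 300 genes are localized, the 80 known pairs plus 40 PPI-inferred pairs
reassemble the 120 planted pairs exactly, 118 of them are expressed above
10 TPM somewhere, and 13,571 directed cell-to-cell edges result. The
statistical core can also be driven directly from counts; with the
published pair-age counts it gives

```r
receptor_first_test(p0 = 0.591, x = 1082, n = 1513)
#> Receptor-before-ligand binomial test
#>   ligand-younger pairs: 1082 of 1513 (estimate 0.7151)
#>   null p0 = 0.591, one-sided p = 6.9e-24
#>   one-sided 95% CI: [0.695, 1]
```

i.e. even after correcting for the length bias of gene-age estimates,
ligands are younger than their receptors far more often than chance
(p < 0.001, lower confidence bound 0.695).

See `vignettes/ligrecnet-methods.Rmd` for the model, the parameter
conventions, the calibration properties of the binomial tests and the
design decisions.

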