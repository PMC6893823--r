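# pvlBBB

In silico blood-brain-barrier (BBB) permeability screening of the gut
microbial metabolites of dietary flavan-3-ols:
phenyl-gamma-valerolactones (PVLs), phenylvaleric acids (PVAs) and their
phase-II conjugates (sulfates, glucuronides, methyl ethers).

Flavan-3-ols from tea, cocoa, berries or grapes are barely absorbed
intact; the colon microbiota converts them into small phenolic
lactones/acids that circulate mostly as conjugates. For any
neuroprotective role, those circulating species must cross the BBB.
`pvlBBB` screens the whole circulating pool for that ability from
structure alone, for researchers in polyphenol metabolism and
nutritional neuroscience who need a reproducible, fully open
counterpart to proprietary ADMET screens.

## What it computes

* **Library builder** — a scaffold + conjugation grammar enumerates the
  67 PVL/PVA metabolites reported in human circulation (a documented
  reconstruction, pinned as `inst/extdata/manifest_v1.csv`), spanning
  ten conjugation classes. Includes a seeded random-phenolic fixture
  generator for property testing.
* **Descriptor engine** — a 12-descriptor panel per molecule: MW, H-bond
  donors/acceptors, topological PSA (Ertl), logP (Wildman-Crippen),
  rotatable bonds, predicted logBB
  (`logBB = 0.152 logP − 0.0148 PSA + 0.139`), Caco-2/MDCK permeability
  surrogates, albumin binding (logKhsa), and single-conformer dipole and
  van der Waals volume from a fully deterministic embedding.
* **Scoring** — Lipinski rule-of-five violations; a reduced `#stars`
  drug-likeness non-compliance count; and a 0-12 **BBB score**: the
  number of descriptors strictly inside calibrated BBB-permeability
  ranges (the logBB window is (−3.00, 1.20)).
* **Chemical-space analysis** — PCA of the z-scored descriptor matrix
  (PVLs and PVAs separately), silhouette + permutation-test
  quantification of conjugation-class clustering, and the census of the
  logBB CNS window.
* **Transport summaries** — luminal/abluminal concentration ratios and
  recovery fractions for two-chamber endothelial assays.

## Worked example

```r
library(pvlBBB)

lib <- pvlLibrary()          # the 67-metabolite library
ds  <- computeDescriptors(lib)
st  <- bbbScore(ds)
head(rankLibrary(st, lib), 6)
```

```
    id                                     systematic_name            class bbb_score lipinski stars
1 M004            5-(3'-hydroxyphenyl)-gamma-valerolactone unconjugated PVL        12        0     0
2 M005            5-(4'-hydroxyphenyl)-gamma-valerolactone unconjugated PVL        12        0     0
3 M047 5-(3'-hydroxyphenyl)-gamma-valerolactone-4'-methoxy      PVL-methoxy        12        0     0
4 M048 5-(4'-hydroxyphenyl)-gamma-valerolactone-3'-methoxy      PVL-methoxy        12        0     0
5 M052                      4-hydroxy-5-phenylvaleric acid unconjugated PVA        12        0     0
6 M002       5-(3',4'-dihydroxyphenyl)-gamma-valerolactone unconjugated PVL        11        0     0
```

Five metabolites — the two monohydroxy PVLs, their methoxy isomers and
4-hydroxy-5-phenylvaleric acid — pass all twelve descriptor ranges
(score 12/12): small, moderately lipophilic, low-polarity structures.
Heavy conjugates rank far lower; no glucuronide, sulfo-glucuronide or
disulfate reaches the maximum.

```r
man <- libraryManifest(lib)
cen <- logbbWindowCensus(ds, classes = man$class)
cen$percent_inside        # 83.58 (% of the library inside -3.00..1.20)
cen$outside_by_class      # all 11 outside members are sulfate-glucuronides
```

The transport module reproduces the two-chamber arithmetic for an
endothelial monolayer assay:

```r
summarizeTransport(data.frame(compound_id = "pvl-sulfate",
  dosed_conc = 5, upper_conc = 0.42, lower_conc = 0.05))
#   compound_id upper_lower_ratio dosed_upper_ratio recovery_fraction ratio_computable
# 1 pvl-sulfate               8.4          11.90476             0.094             TRUE
```

A full run (`runPipeline()`, or
`Rscript inst/scripts/pvlbbb.R run --out dir/`) writes the manifest,
descriptor table, score table, ranked report, PCA scores/loadings,
window census and a provenance-stamped `report.json`; identical config
and seed give byte-identical outputs.

## Package layout

```
R/                  S4 classes, library grammar, descriptor engine,
                    scoring, chemical-space analysis, pipeline
inst/extdata/       pinned manifest, grammar, QSPR + range-table configs
inst/scripts/       thin command-line front end (pvlbbb.R)
scripts/            acceptance.R (headline-number reproduction)
tests/testthat/     unit, property and acceptance test suites
vignettes/          methods vignette (models, calibration, limitations)
```
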