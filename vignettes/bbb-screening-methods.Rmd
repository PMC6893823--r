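---
title: "Screening flavan-3-ol metabolites for blood-brain-barrier permeability: models and methods"
author: "pvlBBB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening flavan-3-ol metabolites for blood-brain-barrier permeability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Dietary flavan-3-ols (catechins, proanthocyanidins) are poorly absorbed and
are transformed by the gut microbiota into smaller, more polar ring-fission
products: 5-phenyl-gamma-valerolactones (PVLs) and, after lactone opening,
phenylvaleric acids (PVAs). These circulate in humans mainly as phase-II
conjugates — sulfates, glucuronides and methyl ethers on the phenolic
hydroxyls. Whether any of them can passively cross the blood-brain barrier
(BBB) is the question this package addresses computationally: it predicts,
from structure alone, which members of the circulating PVL/PVA pool are
physicochemically compatible with passive BBB permeation.

The package implements three connected layers:

1. a **library builder** that enumerates the circulating metabolite space
   from a scaffold + conjugation grammar,
2. a **descriptor engine** computing a twelve-descriptor physicochemical
   panel with open predictors, and
3. a **scoring and analysis layer**: Lipinski drug-likeness, a reduced
   "star" non-compliance count, a 0-12 range-based BBB permeation score,
   PCA of descriptor space, and a census of the logBB CNS window. A small
   transport-summary module reduces two-chamber (luminal/abluminal)
   endothelial assay concentrations to the standard ratios.

## The metabolite library as a reconstruction

The pool of 67 PVL/PVA metabolites reported in human circulation is not
listed compound-by-compound in any single open source. The packaged
library is therefore an explicit *reconstruction*: a generative grammar
whose default configuration (`inst/extdata/grammar_default.yaml`) encodes

* PVL cores (`gamma-valerolactone` backbone) with the ring hydroxylation
  patterns of flavan-3-ol ring-fission products: 3',4',5'; 3',4'; 3',5';
  3'; 4';
* the full PVL phase-II repertoire: sulfation, glucuronidation,
  sulfo-glucuronidation, disulfation;
* PVA entries as the ring-opened 4-hydroxy-5-phenylvaleric acids (ring
  patterns up to the 3',4'-catechol) plus the terminal fully
  dehydroxylated 5-phenylvaleric acid, with sulfate, glucuronide and
  sulfo-glucuronide conjugation;
* methylation modelled as catechol-O-methyltransferase chemistry: at most
  one methyl per molecule, only at a position whose ring neighbour is
  hydroxylated (a catechol substrate), and for PVAs only on top of a
  sulfate or glucuronide (the class legend has no methoxy-only PVA
  class).

Expanding this grammar and removing 3'/5'-symmetry duplicates by canonical
SMILES yields exactly 67 structures across the ten conjugation classes
(unconjugated / methoxy / sulfate / glucuronide / sulfate-glucuronide /
disulfate PVLs; unconjugated / sulfate / glucuronide / sulfate-glucuronide
PVAs). The class-level counts are a reconstruction constrained by the
reported aggregate statistics (total of 67, the named example compounds,
and the legend classes), not a verbatim list; the manifest carries a
provenance note saying so, and `pvlLibrary(rebuild = TRUE)` regenerates it
from the grammar deterministically.

Two modelling conventions are fixed once: stereochemistry is omitted
(every descriptor used here is stereo-insensitive, and the lactone C5
configuration is not resolved in much of the source data), and all
structures are kept in the neutral (acid) protonation form. Both choices
favour determinism and make the open-descriptor substitution cleaner;
ionised species can be supplied by the user as SMILES if wanted. The
aliphatic 4-OH of the PVA backbone is never a conjugation site — only
phenolic hydroxyls accept sulfate, glucuronide or methyl, matching all
named metabolites.

```{r library, eval = FALSE}
library(pvlBBB)
lib <- pvlLibrary()
lib           # 67 metabolites, class breakdown
lib[["M002"]] # 5-(3',4'-dihydroxyphenyl)-gamma-valerolactone
```

## The twelve-descriptor panel

The BBB score judges each molecule on twelve descriptors. Six are
topological (2D) quantities computed with Open Babel (through
ChemmineR/ChemmineOB): molecular weight (g/mol), hydrogen-bond donor and
acceptor counts (integer counts, deliberately, rather than fractional
averaged numbers — reproducibility with open toolkits wins over parity
with proprietary conventions), topological polar surface area by the Ertl
fragment-contribution method (A^2), logP by the Wildman-Crippen
atomic-contribution method, and the rotatable-bond count (acyclic single
bonds between non-terminal heavy atoms).

Four are predictions from linear QSPR models whose coefficients are pinned
in `inst/extdata/qspr_default.yaml`:

* **logBB** — the published two-variable regression
  `logBB = 0.152 logP - 0.0148 PSA + 0.139`. Polarity dominates: every
  20 A^2 of PSA costs about 0.3 log units of brain penetration.
* **Caco-2 permeability** (log10 cm/s) — a package-calibrated linear
  surrogate in PSA and logP with a negative PSA coefficient. The config
  says explicitly this is not a published fit; it preserves the
  qualitative structure (permeability falls with polarity, rises with
  lipophilicity) that matters for range scoring.
* **MDCK permeability** — an affine map of the Caco-2 value, reflecting
  the strong empirical rank correlation between the two assays; under the
  defaults the two rank identically.
* **logKhsa** (serum-albumin binding) — a logP-dominated linear surrogate
  with a small flexibility term.

Two are single-conformer 3D quantities: the dipole moment
`|sum q_i r_i|` (Debye) over EEM partial charges, and the van der Waals
union volume counted on a 0.2 A cubic grid with Bondi radii (A^3).

### Deterministic conformer generation

Descriptor tables must be byte-identical across runs, so the conformer
stage avoids stochastic conformer searching entirely. `embedConformer()`
builds one conformation in three deterministic steps: a 2D structure
layout with explicit hydrogens; a seeded out-of-plane displacement of
every atom (+-0.5 A, drawn from an internal Lehmer linear-congruential
stream so R's RNG is untouched; conformer seed default 2019, recorded in
the result); and force-field energy minimisation (MMFF94, with UFF as
fallback where MMFF94 parameters are missing). The geometry is
sanity-checked (bond lengths, non-bonded contacts) and re-jittered from a
perturbed seed on failure.

The result is one reasonable *local-minimum* conformer, not a
Boltzmann-averaged ensemble or a global search. Dipole moments from
point charges on a single conformer are systematically larger and more
conformation-sensitive than quantum-chemical ensemble values; volume is
nearly conformation-insensitive. Consequently the dipole and volume
interval bounds used in scoring are calibrated on this package's own
scales and are not comparable to values from other software — the range
table marks them accordingly.

Numerical tolerances worth knowing: grid volume agrees with the analytic
sphere-union value to well under 5% on 1-3-atom toys at 0.2 A spacing;
centro-symmetric molecules give dipoles below 0.3 D (benzene computes to
about 0.001 D); EEM charges are renormalised so they sum exactly to the
net formal charge.

## Scoring

Three scores are computed per molecule, all from the same descriptor row:

* **Lipinski violations** (0-4) among mw > 500, logP > 5, HBD > 5,
  HBA > 10; boundary values do not violate.
* **Reduced star count**: how many descriptors fall outside ranges
  covering 95% of known drugs. The packaged table covers the seven
  externally-comparable descriptors (mw, hbd, hba, psa, logp, rotb,
  logbb); the five descriptors on package-specific scales are skipped
  with a warning. It is therefore a *reduced* star count and is labelled
  as such — absolute star values are not comparable to a full
  proprietary-panel star count.
* **BBB score** (0-12): the number of descriptors strictly inside their
  BBB-permeability interval.

Interval membership is *strictly inside* `(lo, hi)` everywhere: a
boundary hit counts as outside for the BBB score and as a star for the
non-compliance count. One convention, applied symmetrically, keeps the
two scores consistent; whether boundary values should count as inside is
genuinely undecidable from the available sources, so the package picks
the stricter reading and documents it.

### Calibration of the BBB range table

The twelve interval bounds (`inst/extdata/bbb_ranges_default.yaml`) could
not be copied from a single authoritative table: only the logBB window,
(-3.00, 1.20), is fixed by its source. The other eleven are assembled
from the CNS-permeability literature *and calibrated on this package's
descriptor scales* so that the screen reproduces the reported headline
behaviour: the five named low-polarity metabolites
(4-hydroxy-5-phenylvaleric acid, the two monohydroxy PVLs, and their two
methoxy-monohydroxy isomers) pass all twelve ranges, and no glucuronide,
sulfo-glucuronide or disulfate does. The binding constraints are the PSA
window (20, 60) A^2 — which separates the five (PSA 46.5-57.5) from the
dihydroxylated and conjugated bulk (66.8 and up) — and the logP window
(0, 2.0), which excludes the bare 5-phenylvaleric acid (logP 2.48) and
all acid-form sulfates (logP 1.9-2.5). The remaining windows (mw, hbd,
hba, rotb, caco2, mdck, dipole, volume, logkhsa) are set at
literature-typical CNS spans on the package's scales and are
non-binding for the packaged library. A regression test pins this
calibration; anyone replacing the QSPR config or the range table is
changing the experiment, and the vignette-level claim travels with the
defaults only.

```{r scoring, eval = FALSE}
ds <- computeDescriptors(lib)
st <- bbbScore(ds)
head(rankLibrary(st, lib))
```

## Chemical-space analysis

The descriptor matrix is z-scored per column with the population-sd
convention (divisor n, so a three-point column standardises to
-1.2247, 0, 1.2247); constant columns are dropped with a warning. PCA is
the eigendecomposition of the covariance matrix with a deterministic sign
convention (the largest-magnitude loading of each component is made
positive), explained-variance fractions reported over all components, and
PVLs and PVAs analysed separately by default (a combined mode exists
behind `combinedPCA`). On the packaged library PC1 carries ~81% of the
variance of the PVL block and orders molecules essentially by conjugation
bulk/polarity.

"The classes cluster" is made testable with silhouettes: mean silhouette
width per conjugation class on the first two components (Euclidean
distance), compared against the null distribution from label shuffling.
With 999 shuffles at a fixed seed the observed PVL silhouette (~0.52) sits
far above the 95th percentile of the shuffled values (~ -0.17). Classes
with fewer than two members are excluded from silhouettes with a warning.

The logBB window census reports the fraction of the library strictly
inside (-3.00, 1.20) and the class breakdown of the outside set. Under
the default grammar and QSPR config, 56 of 67 (83.6%) lie inside; all
eleven outside members are sulfate-glucuronide conjugates, the most
polar class (PSA above ~205 A^2).

## The synthetic-data generator

`randomPhenolic(seed, params)` draws seed-reproducible random phenolic
metabolites: a PVL or PVA scaffold bearing 0-3 ring hydroxyls, each
hydroxyl optionally sulfated, glucuronidated or methylated with
configurable probabilities. It deliberately samples *beyond* the curated
library — any position pattern and conjugation mix, including species the
default grammar excludes — because its job is to exercise structural edge
cases in property tests (round-tripping through canonicalisation, class
assignment totality, mass additivity), not to emulate the biological
pool. What passing those tests shows is that the structure machinery is
internally consistent; it says nothing about which conjugates real
microbiota/host enzymes produce, which is out of scope throughout.

## Problem sizes and determinism

The packaged analyses are desk-scale by design: 67 molecules, a
12-descriptor panel, 999-permutation silhouette tests, 300-draw fixture
sweeps. A full pipeline run (`runPipeline()`) takes well under a minute
on one CPU, and every stage is deterministic at a fixed config + seed:
identical runs produce byte-identical CSVs (sorting uses C-locale byte
order so results do not depend on the system locale). The run report
records the config hash, package version and seed.

## Known limitations

* The library is a reconstruction; compound-level identity of the 67 is
  pinned by the grammar, not by an authoritative list.
* The four predicted descriptors are open substitutes: parity with
  proprietary predictors is approximate by construction, and absolute
  values of the Caco-2/MDCK/logKhsa surrogates are only meaningful
  relative to the packaged range table.
* Single-conformer 3D descriptors; no conformational ensembles, no
  quantum-chemical dipoles.
* Neutral protonation forms only, stereochemistry omitted.
* The full 43-descriptor proprietary panel, its compliance count, and
  the absolute star-count distribution are out of scope; the reduced
  star count is not comparable to them.
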