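# Default scaffold + conjugation grammar.
# Reconstructs the 67 PVL/PVA metabolites reported to circulate in humans.
# Composition rationale:
#   * PVL (gamma-valerolactone) cores carry the ring hydroxylation patterns
#     observed for flavan-3-ol ring-fission products (3',4',5'; 3',4';
#     3',5'; 3'; 4') and undergo the full phase-II repertoire: sulfation,
#     glucuronidation, sulfo-glucuronidation, disulfation, and
#     catechol-O-methylation (alone or on top of a heavy conjugate).
#   * PVA entries are the ring-opened 4-hydroxy-valeric acids (up to the
#     3',4' catechol) plus the terminal dehydroxylated 5-phenylvaleric
#     acid; observed PVA conjugates are sulfates, glucuronides and
#     sulfo-glucuronides (no PVA disulfates or methoxy-only PVAs in the
#     class legend).
#   * Methylation requires a catechol-adjacent hydroxyl (COMT substrate)
#     and at most one methyl per molecule.
# 3'/5' ring symmetry duplicates are removed during enumeration.
version: "1.0"
provenance_note: >
  Curated reconstruction of the 67 circulating PVL/PVA metabolites from the
  published naming scheme and conjugation-class legend; the compound-level
  identity of the 67 is not printed in full anywhere, so counts per class
  are a reconstruction constrained by the reported aggregate statistics.
scaffolds:
  - kind: PVL
    backbone: gamma-valerolactone
    hydroxylation_patterns:
      - ["3'", "4'", "5'"]
      - ["3'", "4'"]
      - ["3'", "5'"]
      - ["3'"]
      - ["4'"]
    heavy_multisets:
      - []
      - [sulfate]
      - [glucuronide]
      - [sulfate, glucuronide]
      - [sulfate, sulfate]
    methyl:
      max: 1
      requires_catechol: true
      companions: [none, sulfate, glucuronide, sulfate+glucuronide, disulfate]
  - kind: PVA
    backbone: 4-hydroxy-5-phenylvaleric-acid
    hydroxylation_patterns:
      - []
      - ["3'"]
      - ["4'"]
      - ["3'", "4'"]
    heavy_multisets:
      - []
      - [sulfate]
      - [glucuronide]
      - [sulfate, glucuronide]
    methyl:
      max: 1
      requires_catechol: true
      companions: [sulfate, glucuronide]
  - kind: PVA
    backbone: 5-phenylvaleric-acid
    hydroxylation_patterns:
      - []
    heavy_multisets:
      - []
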