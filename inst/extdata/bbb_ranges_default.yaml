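# Calibrated twelve-descriptor interval table for BBB permeation scoring.
# A descriptor passes iff its value is STRICTLY inside (lo, hi); boundary
# hits count as outside. The logbb window is the published CNS interval;
# the remaining entries are CNS-permeability literature ranges calibrated
# on this package's descriptor scales (caco2/mdck are the packaged linear
# surrogates in log10 cm/s; dipole is the single-conformer EEM dipole in
# Debye; volume is the 0.2 A grid van der Waals volume in A^3).
mw:
  lo: 150
  hi: 450
  provenance: literature-default
hbd:
  lo: 0
  hi: 4
  provenance: literature-default
hba:
  lo: 1
  hi: 8
  provenance: literature-default
psa:
  lo: 20
  hi: 60
  provenance: literature-default
logp:
  lo: 0.0
  hi: 2.0
  provenance: literature-default
logbb:
  lo: -3.00
  hi: 1.20
  provenance: paper
caco2:
  lo: -5.0
  hi: -4.0
  provenance: literature-default
mdck:
  lo: -5.0
  hi: -4.0
  provenance: literature-default
dipole:
  lo: 0.5
  hi: 13.0
  provenance: literature-default
volume:
  lo: 150
  hi: 350
  provenance: literature-default
rotb:
  lo: -1
  hi: 8
  provenance: literature-default
logkhsa:
  lo: -1.5
  hi: 1.5
  provenance: vendor-doc
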