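# 95%-of-known-drugs ranges for the reduced star count.
# Only descriptors on externally comparable scales are listed; the star
# count skips (with a warning) any panel descriptor absent here.
mw:
  lo: 130
  hi: 725
  provenance: vendor-doc
hbd:
  lo: 0
  hi: 6
  provenance: vendor-doc
hba:
  lo: 2
  hi: 20
  provenance: vendor-doc
psa:
  lo: 7
  hi: 200
  provenance: vendor-doc
logp:
  lo: -2
  hi: 6.5
  provenance: vendor-doc
rotb:
  lo: 0
  hi: 15
  provenance: vendor-doc
logbb:
  lo: -3.0
  hi: 1.2
  provenance: vendor-doc
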