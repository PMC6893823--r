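# Default QSPR models for the predicted descriptors.
# Open substitutes for proprietary predictors; each model is a pure linear
# function of its declared inputs. Parity with the proprietary panel is
# approximate by construction.
logbb:
  inputs: [logp, psa]
  coefficients:
    logp: 0.152
    psa: -0.0148
    intercept: 0.139
  citation: >
    Clark (1999) two-variable linear logBB regression in ClogP and PSA
    (J Pharm Sci 88:815-821).
caco2:
  inputs: [psa, logp]
  coefficients:
    psa: -0.0118
    logp: 0.20
    intercept: -4.30
  citation: >
    Package-calibrated linear surrogate for Caco-2 log10 apparent
    permeability (cm/s); PSA coefficient negative so permeability falls
    with polarity (literature-default provenance, not a published fit).
mdck:
  inputs: [caco2]
  coefficients:
    caco2: 0.9
    intercept: -0.4
  citation: >
    Affine map from the Caco-2 surrogate reflecting the strong empirical
    Caco-2/MDCK rank correlation (literature-default provenance).
logkhsa:
  inputs: [logp, rotb]
  coefficients:
    logp: 0.27
    rotb: 0.004
    intercept: -0.54
  citation: >
    Package-calibrated logP-dominated linear surrogate for log K(HSA)
    (literature-default provenance, not a published fit).
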