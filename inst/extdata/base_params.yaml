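# Base-case parameters of the decision model (toxicity-weighted cycle payoffs).
# pLowRisk has no literature point estimate; 0.40 is the reconstructed value
# that reproduces the published surveillance base case of 1.3419 cycles, and
# should be overridden when a cohort's actual risk mix is known.
pLowRisk: 0.40
pRelapseLowrisk: 0.15
pRelapseHighrisk: 0.60
pRelapsePostPrimChemo: 0.05
pRelapsePostSalvChemo: 0.05
tSecondChemo: 1.3
nPrimaryCycles: 1
nSalvageCycles: 3
nSecondLineCycles: 3
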