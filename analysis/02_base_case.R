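#!/usr/bin/env Rscript
# Step 2: base case. Roll back both strategy trees at the point estimates
# (pLowRisk = 0.40, the reconstructed default) and report the expected
# toxicity-weighted chemotherapy exposure of each strategy.

suppressPackageStartupMessages(library(cs1decision))

params <- read_parameters(
  system.file("extdata", "base_params.yaml", package = "cs1decision")
)
cmp <- run_base_case(params, out_dir = "results")
print(cmp)

message(
  "Surveillance exposes the average child to ",
  sprintf("%.4f", cmp$surveillance),
  " toxicity-weighted cycles versus ",
  sprintf("%.4f", cmp$risk_adapted),
  " under risk-adapted treatment; ", cmp$preferred, " is preferred."
)
message(
  "Note: the originally published risk-adapted figure (0.7965) matches a ",
  "variant tree that applies the post-salvage progression probability twice ",
  "in the high-risk arm; the canonical tree gives 0.88755 (see base_case.json)."
)
message("Wrote results/base_case.json and results/base_case.txt")
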