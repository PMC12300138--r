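#!/usr/bin/env Rscript
# Stage 5 — one-shot end-to-end run through the pipeline orchestrator:
# regenerates everything under results/pipeline/ with a single seed and
# writes the combined JSON + Markdown report.

library(soilmetals)

report <- run_pipeline(list(out_dir = "results/pipeline", seed = 1,
                            n_sites = 72, n_iter = 10000,
                            n_restarts = 20, delta = 0.1))
cat(readLines("results/pipeline/report.md"), sep = "\n")
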