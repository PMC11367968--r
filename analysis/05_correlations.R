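#!/usr/bin/env Rscript
# Pool the per-case sweep tables and report the Pearson correlation panels
# (pressure gradient / peak velocity / TKE against severity and flow), the
# per-case analogue of the study's statistical analysis.

suppressPackageStartupMessages({library(stenoflow); library(dplyr)})

read_sweep <- function(path) read.csv(path, comment.char = "#")
paths <- sprintf("results/case%d_sweep.csv", 1:2)
if (!all(file.exists(paths))) stop("run analysis/04_sweep.R first")

for (p in paths) {
  tab <- read_sweep(p)
  cat("\n==", p, "==\n")
  rank <- match(tab$severity, c("OS", "AS1", "AS2"))
  panel <- bind_rows(
    pearson_test(tab$gradient_mmHg, tab$csa_mm2, "gradient_vs_csa"),
    pearson_test(tab$gradient_mmHg, rank, "gradient_vs_severity_rank"),
    pearson_test(tab$gradient_mmHg, tab$flow_lpm, "gradient_vs_flow"),
    pearson_test(tab$peak_velocity_ms, tab$flow_lpm, "peak_velocity_vs_flow"),
    pearson_test(tab$gradient_mmHg, tab$peak_velocity_ms, "gradient_vs_peak_velocity"))
  print(as.data.frame(panel))
}
cat("\nExpected structure: gradients rise with device flow and fall with\n",
    "narrowest CSA; peak velocity tracks flow closely.\n")
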