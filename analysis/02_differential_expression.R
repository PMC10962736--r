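#!/usr/bin/env Rscript
# Differential expression for every model and tissue: stress vs control in
# the modifier-intact background, and stress/KO vs stress/modifier+ at the
# same |linear FC| >= 2, BH FDR <= 5% gates. Reads the fixtures written by
# 01_simulate.R and writes one contrast table per comparison.

suppressPackageStartupMessages(library(mtisr))
fixdir <- "results/fixtures"
outdir <- "results/de"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

for (tissue in c("heart", "bat", "gastroc")) {
  inp <- read_expression(file.path(fixdir, paste0(tissue, "_matrix.tsv")),
                         file.path(fixdir, paste0(tissue, "_samples.tsv")))
  for (m in unique(inp$samples$model)) {
    stress <- run_contrast(inp$matrix,
                           arm_samples(inp$samples, m, "stress_wt"),
                           arm_samples(inp$samples, m, "control"))
    ko <- run_contrast(inp$matrix,
                       arm_samples(inp$samples, m, "stress_ko"),
                       arm_samples(inp$samples, m, "stress_wt"))
    write_tsv(stress, file.path(outdir, sprintf("%s_%s_stress.tsv", tissue, m)))
    write_tsv(ko, file.path(outdir, sprintf("%s_%s_ko.tsv", tissue, m)))
    cat(sprintf("%s / %s: %d stress DEGs (%d up, %d down), %d KO-contrast DEGs\n",
                tissue, m, sum(stress$is_deg), sum(stress$direction == "up"),
                sum(stress$direction == "down"), sum(ko$is_deg)))
  }
}
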