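#!/usr/bin/env Rscript
# Dependence classification and signature derivation. Classifies each
# model's stress DEGs as modifier-dependent (significant opposite-direction
# KO contrast), quantifies percent dependence, intersects dependent sets
# across the three heart models, and computes the cross-tissue and
# cross-species overlaps of the resulting core signature.

suppressPackageStartupMessages(library(mtisr))
dedir <- "results/de"
outdir <- "results/signature"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

read_de <- function(tissue, model, contrast) {
  read_tsv(file.path(dedir, sprintf("%s_%s_%s.tsv", tissue, model, contrast)))
}

heart_models <- c("g58r", "s59l", "tfam")
stress <- list(); dep <- list()
for (m in heart_models) {
  stress[[m]] <- read_de("heart", m, "stress")
  dep[[m]] <- classify_dependent(stress[[m]], read_de("heart", m, "ko"),
                                 model = m)
  write_tsv(dep[[m]], file.path(outdir, sprintf("dependence_heart_%s.tsv", m)))
}

shared <- shared_degs(stress)
core <- k_of_n_dependent(dep, 3)
two_of_three <- k_of_n_dependent(dep, 2)
thr50 <- threshold_dependent_set(shared, dep, 50)
frac <- dependent_fraction(dep)

cat(sprintf("heart: %d shared stress DEGs across the three models\n", length(shared)))
cat(sprintf("core signature (dependent in all 3 models): %d genes\n", length(core)))
cat(sprintf("additional dependent DEGs in exactly 2 of 3 models: %d genes\n",
            length(two_of_three)))
cat(sprintf(">=50%%-dependence alternative set: %d genes (core is a subset: %s)\n",
            length(thr50), all(core %in% thr50)))
cat("per-model dependent fraction of stress DEGs:\n")
print(frac, row.names = FALSE)

write_tsv(signature_report(stress, dep), file.path(outdir, "signature_report.tsv"))

# BAT cold stress: dependent DEGs and their percent-dependence range
bat_dep <- classify_dependent(read_de("bat", "bat", "stress"),
                              read_de("bat", "bat", "ko"), model = "bat")
write_tsv(bat_dep, file.path(outdir, "dependence_bat.tsv"))
bat_pct <- bat_dep$pct_dependence[bat_dep$is_dependent]
cat(sprintf("BAT: %d dependent DEGs, dependence range %.0f-%.0f%%\n",
            sum(bat_dep$is_dependent), min(bat_pct), max(bat_pct)))

# Cross-tissue overlap of the heart core signature with gastrocnemius
gas_dep <- classify_dependent(read_de("gastroc", "gastroc", "stress"),
                              read_de("gastroc", "gastroc", "ko"),
                              model = "gastroc")
write_tsv(gas_dep, file.path(outdir, "dependence_gastroc.tsv"))
ov <- tissue_overlap(core, gas_dep$gene_id[gas_dep$is_dependent])
cat(sprintf("heart core in gastrocnemius: %d of %d (%.0f%%)\n",
            ov$n_overlap, ov$n_signature, ov$fraction_pct))

# Cross-species: orthologs upregulated >= 2-fold on average across studies
cs <- load_cross_species_fixture()
xs <- suppressWarnings(cross_species_overlap(core, cs$ortholog_map,
                                             cs$study_fc, min_mean_fc = 2))
cat(sprintf("human-ortholog genes with mean FC >= 2 across studies: %d (%d unmapped)\n",
            length(xs$genes), xs$n_unmapped))
write_tsv(xs$table, file.path(outdir, "cross_species_table.tsv"))

jsonlite::write_json(
  list(n_shared_degs = length(shared), n_core = length(core),
       n_two_of_three = length(two_of_three), n_threshold50 = length(thr50),
       bat_dependent = sum(bat_dep$is_dependent),
       bat_pct_range = range(bat_pct),
       tissue_overlap = ov$n_overlap,
       cross_species = length(xs$genes)),
  file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
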