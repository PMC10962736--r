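#!/usr/bin/env Rscript
# Generate every fixture used by the downstream analyses and write them,
# with their planted truth tables, under results/fixtures/. All generators
# are seeded, so re-running this script reproduces the files byte for byte.

suppressPackageStartupMessages(library(mtisr))
seed <- 1L
outdir <- "results/fixtures"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

# Three-model heart transcriptomics fixture (three arms x 6 replicates/model)
heart <- generate_expression_fixture(preset_heart_threemodel(seed = seed))
write_expression(heart, file.path(outdir, "heart_matrix.tsv"),
                 file.path(outdir, "heart_samples.tsv"),
                 comment = sprintf("preset heart_threemodel, seed %d", seed))
write_tsv(heart$truth, file.path(outdir, "heart_truth.tsv"))
cat(sprintf("heart fixture: %d genes x %d samples, 3 models\n",
            nrow(heart$matrix), ncol(heart$matrix)))

# Brown-adipose cold-stress fixture (7 replicates per arm)
bat <- generate_expression_fixture(preset_bat_coldstress(seed = seed))
write_expression(bat, file.path(outdir, "bat_matrix.tsv"),
                 file.path(outdir, "bat_samples.tsv"),
                 comment = sprintf("preset bat_coldstress, seed %d", seed))
write_tsv(bat$truth, file.path(outdir, "bat_truth.tsv"))
cat(sprintf("BAT fixture: %d genes x %d samples\n",
            nrow(bat$matrix), ncol(bat$matrix)))

# Gastrocnemius overlay fixture (dependent set overlapping the heart core)
gas <- generate_expression_fixture(preset_gastroc_overlay(seed = seed))
write_expression(gas, file.path(outdir, "gastroc_matrix.tsv"),
                 file.path(outdir, "gastroc_samples.tsv"),
                 comment = sprintf("preset gastroc_overlay, seed %d", seed))
write_tsv(gas$truth, file.path(outdir, "gastroc_truth.tsv"))

# Mitochondrial ellipse-population mask (200 shapes, 22% planted nano)
pop <- preset_s59l_population(seed = seed)
mask <- generate_mask_fixture(pop$shapes, pop$pixel_size_nm, pop$image_shape,
                              seed = seed)
write_mask(mask$labels, file.path(outdir, "mito_mask.tif"))
write_tsv(mask$truth, file.path(outdir, "mito_truth.tsv"))
cat(sprintf("mask fixture: %d labels, planted nano fraction %.0f%%\n",
            nrow(mask$truth), 100 * mean(mask$truth$is_nano)))

# Myofiber fixture (planted group CSA means 330.0 / 446.9 um^2,
# intensity ratio 2.712)
fib <- generate_fiber_fixture(seed = seed)
write_mask(fib$labels, file.path(outdir, "fiber_mask.tif"))
write_mask(round(fib$intensity), file.path(outdir, "fiber_intensity.tif"))
write_tsv(fib$truth, file.path(outdir, "fiber_truth.tsv"))
write_tsv(fib$annotations, file.path(outdir, "fiber_annotations.tsv"))
cat(sprintf("fiber fixture: %d fibers in 2 groups\n", nrow(fib$truth)))
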