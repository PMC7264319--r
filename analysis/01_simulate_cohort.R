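#!/usr/bin/env Rscript

# Simulate the study cohort: ~61 patients, ~210 contrast-enhancing brain
# metastases (1-12 per patient, 3-40 mm), each patient carrying a binary
# mutation label that shifts the intralesional texture (2x correlation
# length for mutants). Volumes/masks are written as NIfTI-1 plus a CSV
# manifest under results/cohort/.

suppressPackageStartupMessages(library(bmradiomics))

out_dir <- "results/cohort"
cfg <- cohort_config(seed = 1L)
co <- generate_cohort(cfg, dir = out_dir, keep_volumes = FALSE)
m <- co$manifest

cat("cohort written to", out_dir, "\n")
cat(sprintf("  patients: %d   lesions: %d\n",
            length(unique(m$patient_id)), nrow(m)))
cat(sprintf("  class balance (lesions): %d wild type / %d mutant\n",
            sum(m$label == 0), sum(m$label == 1)))
cat(sprintf("  diameter: mean %.1f mm, range %.1f-%.1f mm\n",
            mean(m$diameter_mm), min(m$diameter_mm), max(m$diameter_mm)))
cat(sprintf("  small (<10 mm): %d   large (>=10 mm): %d\n",
            sum(m$diameter_mm < 10), sum(m$diameter_mm >= 10)))
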