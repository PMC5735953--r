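#!/usr/bin/env Rscript
# Step 1: generate the synthetic promoter study.
#
# The design mirrors the real study layout: 50 auxin-induced (Class I),
# 20 non-auxin-regulated (Class II) and 500 background promoters, each a
# 3000-nt upstream window, with the combined AuxRE, the BZR1 G-box and the
# extended PIF5-like motif planted at the per-class presence rates observed
# in real promoter sets. Writes the bundle (FASTA, labels, ground truth,
# design echo) under results/synthetic_study/.

suppressMessages(library(auxrescan))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 2026L
design <- study_design(seed = seed)
study <- generate_study(design)

print(study)
message("planted instances by motif and class:")
cls <- sub("_[0-9]+$", "", study$truth$gene_id)
print(table(study$truth$motif, cls))

write_study_bundle(study, "results/synthetic_study")
message("bundle written to results/synthetic_study/")
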