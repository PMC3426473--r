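#!/usr/bin/env Rscript
# Step 1 — simulate the survey inputs.
#
# Generates the truth genome (50 multi-exon protein-coding genes on two
# chromosomes) and derives a draft assembly from it: chromosomes tiled
# into 5-15 kb contigs joined by 100-N gaps, with the full default defect
# mix injected (sequencing errors, exon-deleting gaps, misassigned /
# unintegrated / flipped / chimeric contigs, annotation errors). Writes
# every artifact a real audit would start from, plus the ground-truth
# defect log, under results/survey/.

suppressMessages(library(exonaudit))

seed <- 1L
outdir <- "results/survey"

cfg <- sim_config(seed = seed)
truth <- generate_truth(cfg)
dd <- derive_draft(truth$assembly, truth$models, default_defect_specs(),
                   tiling_config(), seed = seed)

dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
write_fasta(truth$assembly, file.path(outdir, "truth.fa"))
write_gff3(truth$models, file.path(outdir, "truth.gff3"))
write_fasta(dd$draft, file.path(outdir, "draft.fa"))
write_gff3(dd$draft_models, file.path(outdir, "draft.gff3"))
write_placements(dd$draft$placements, file.path(outdir, "placements.tsv"))
write_roles(dd$draft$role, file.path(outdir, "roles.tsv"))
write_synteny(dd$synteny, file.path(outdir, "synteny.tsv"))
write_defect_log(dd$defects, file.path(outdir, "defects.tsv"))

message(sprintf("truth: %d genes on %d chromosomes (%s bp)",
                length(truth$models), cfg$n_chromosomes,
                format(sum(nchar(truth$assembly$sequences)), big.mark = ",")))
message(sprintf("draft: %d sequences, %d contigs, %d defect records on %d genes",
                length(dd$draft$sequences), nrow(dd$draft$placements),
                nrow(dd$defects), length(unique(dd$defects$gene_id))))
message("wrote ", outdir)
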