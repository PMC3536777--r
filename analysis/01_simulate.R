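#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Emulates the factorial design of the TR subtype study in a HepG2-like
# background: parental / TRalpha / TRbeta cells, +/- T3 at 3, 6 and 24 h,
# a cycloheximide arm at 3 h, and a T3 dose series at 24 h. Ground-truth
# per-gene labels are written alongside so later stages can score recovery.

library(trtargets)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genes = 2000, seed = 1234)
effects <- draw_gene_effects(cfg)
tc <- simulate_timecourse(effects, cfg)
chx <- simulate_chx_arm(effects, cfg)
dose <- simulate_dose_series(effects, cfg)

hdr <- sprintf("trtargets %s | stage 01 | seed=%d",
               as.character(packageVersion("trtargets")), cfg$seed)
write_expression(tc$matrix, file.path(out, "timecourse_matrix.tsv"), comment = hdr)
write_design(tc$design, file.path(out, "timecourse_design.tsv"), comment = hdr)
write_expression(chx$matrix, file.path(out, "chx_matrix.tsv"), comment = hdr)
write_design(chx$design, file.path(out, "chx_design.tsv"), comment = hdr)
write_expression(dose$matrix, file.path(out, "dose_matrix.tsv"), comment = hdr)
write_design(dose$design, file.path(out, "dose_design.tsv"), comment = hdr)
write_gene_effects(effects, file.path(out, "ground_truth.tsv"))

responsive <- sum(!is.na(effects$direct))
message(sprintf(
  "simulated %d genes: %d (%.0f%%) T3-responsive, %d late TRbeta-preferential, %.0f%% of responsive direct",
  cfg$n_genes, responsive, 100 * responsive / cfg$n_genes,
  sum(effects$late_beta),
  100 * mean(effects$direct[!is.na(effects$direct)])))
message("wrote matrices, designs and ground truth under ", out)
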