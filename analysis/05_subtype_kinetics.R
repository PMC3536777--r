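#!/usr/bin/env Rscript
# Stage 5: TR subtype concordance and response kinetics.
#
# Compares TRalpha and TRbeta responses over time: gate-passing counts per
# receptor and time, fold-fold correlation and total-least-squares slope
# (beta on alpha) over the union of passers, kinetic classes (alpha-early,
# beta-late, concordant, discordant), and direction-stratified overlap
# counts at 24 h.

library(trtargets)

de_dir <- "results/de"
if (!file.exists(file.path(de_dir, "de_24h_t3_TRA.tsv")))
  stop("run analysis/02_differential_expression.R first")
out <- "results/subtype"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_de <- function(t, nm) read.delim(file.path(de_dir, sprintf("de_%gh_%s.tsv", t, nm)))
times <- c(3, 6, 24)
resA <- lapply(setNames(times, times), read_de, nm = "t3_TRA")
resB <- lapply(setNames(times, times), read_de, nm = "t3_TRB")

conc <- do.call(rbind, lapply(times, function(t)
  concordance(resA[[as.character(t)]], resB[[as.character(t)]], time_hr = t)))
write.table(conc, file.path(out, "concordance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("per-time concordance (n_alpha / n_beta / overlap / r / slope):")
for (i in seq_len(nrow(conc)))
  message(sprintf("  %2g h  %4d %4d %4d  r=%.2f  slope=%.2f",
                  conc$time_hr[i], conc$n_alpha[i], conc$n_beta[i],
                  conc$n_overlap[i], conc$pearson_r[i], conc$slope[i]))

kin <- kinetic_classify(resA, resB)
write.table(kin, file.path(out, "kinetic_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
tab <- table(kin$class)
message("kinetic classes: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))

ov <- overlap_table(list(TRA = gate_significant(resA[["24"]]),
                         TRB = gate_significant(resB[["24"]])))
write.table(ov$counts, file.path(out, "overlap_counts_24h.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("24 h overlaps (induced/repressed): ",
        paste(sprintf("%s %d/%d", ov$counts$combo, ov$counts$induced,
                      ov$counts$repressed), collapse = "; "),
        if (length(ov$discordant)) sprintf(" | %d discordant-direction probes",
                                           length(ov$discordant)) else "")
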