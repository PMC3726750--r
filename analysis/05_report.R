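#!/usr/bin/env Rscript
# Step 5 -- the quality report: integrity (CS/GS), accuracy (mEST/sEST),
# the proportion of 0.1 Mb segments with matching ESTs, abundance bins,
# the four-level classification, and the GC / repeat correlations with
# per-segment EST matching. Also checks the measured accuracy against
# the planted matchable fraction from the truth ledger.

library(estqc)

state <- readRDS("results/sim/sim_state.rds")
mapres <- readRDS("results/map/map_state.rds")
prof <- readRDS("results/profile/profile_state.rds")
out <- "results/report"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

asm <- state$chromosome$assembly
seg <- segment_match_profile(mapres$hits, asm)
binned <- abundance_bins(seg$profiles, c(1, 2, 3, 4))
write.table(binned, file.path(out, "segment_matches.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

gc_avg <- 100 * sum(vapply(seq_len(nrow(asm$records)), function(i)
  gc_fraction(asm$records$seq[i]) * asm$records$length[i], numeric(1))) /
  asm$assembled_size

# per-segment association of EST matching with GC and repeat load
stopifnot(nrow(prof$profiles) == nrow(seg$profiles))
cors <- list(
  gc_vs_est = correlate(prof$profiles$gc, seg$profiles$est_match_count),
  repeat_vs_est = correlate(prof$profiles$repeat_length,
                            seg$profiles$est_match_count))

report <- summarize_quality(asm, mapres, seg, gc_avg_pct = gc_avg,
                            correlations = cors)
print(report)
message(sprintf("GC avg %.2f%%; GC~EST r = %.3f (rho %.3f); repeat~EST r = %.3f",
                gc_avg, cors$gc_vs_est$pearson, cors$gc_vs_est$spearman,
                cors$repeat_vs_est$pearson))

pmf <- planted_matchable_fraction(state$truth)
message(sprintf("planted matchable fraction %.4f vs measured accuracy %.2f%%",
                pmf, report$accuracy_pct))

write_report_json(report, file.path(out, "quality_report.json"))
row <- data.frame(
  assembly = "simulated", kind = report$assembly_kind,
  integrity_pct = report$integrity_pct, accuracy_pct = report$accuracy_pct,
  selected = report$selected_count, matched = report$matched_count,
  segment_pct = report$pct_segments_matched, gc_avg_pct = round(gc_avg, 2),
  level = as.character(report$level))
write.table(row, file.path(out, "quality_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/report/")
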