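#!/usr/bin/env Rscript
# Step 3 -- spliced mapping of the selected clean ESTs onto the
# defective chromosome assembly. Alignment windows are k-mer seeded;
# the intron bound is set to 2 kb to match the simulated intron range
# (60-400 bp). One best hit per EST; matched means identity >= 0.95
# and coverage >= 0.50.

library(estqc)

state <- readRDS("results/sim/sim_state.rds")
clean <- readRDS("results/clean/clean_state.rds")
out <- "results/map"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

params <- align_params(max_intron = 2000L, min_seed_hits = 10L)
t0 <- Sys.time()
res <- map_all(clean$selected, state$chromosome$assembly, params)
message(sprintf("mapped %d ESTs in %.1f min: %d matched (mEST/sEST = %.2f%%)",
                res$selected_count,
                as.numeric(Sys.time() - t0, units = "mins"),
                res$matched_count,
                accuracy_ratio(res$matched_count, res$selected_count)))

write_hits_tsv(res$hits, file.path(out, "hits.tsv"))
write_hits_bed12(res$hits, file.path(out, "hits.bed12"))
saveRDS(res, file.path(out, "map_state.rds"))
message("wrote results/map/")
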