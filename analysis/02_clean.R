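#!/usr/bin/env Rscript
# Step 2 -- two-round stratified sampling and cleaning. The simulated
# library stands in for a dbEST download: round 1 samples accessions by
# the 50%/100% rule, cleaning clips vector/adaptor ends and removes
# rRNA/bacterial/organelle reads, and round 2 draws the mapping set by
# the 1%/10%/100% rule keyed to the (simulated) dbEST total.

library(estqc)

state <- readRDS("results/sim/sim_state.rds")
out <- "results/clean"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ests <- state$ests
n_dbest <- nrow(ests)   # the whole simulated library plays the dbEST role

r1 <- first_round_sample(ests$id, n_dbest, seed = state$config$seed)
message(sprintf("round 1: %d of %d accessions selected", length(r1), n_dbest))

classes <- sub("^class=", "", state$refs$desc)
cl <- run_cleaning(ests[match(r1, ests$id), ],
                   state$refs[classes == "vector", ],
                   state$refs[classes != "vector", ])
tab <- table(cl$outcomes$action)
message(sprintf("cleaning: %s",
                paste(names(tab), tab, sep = "=", collapse = ", ")))
reasons <- table(cl$outcomes$removal_reason)
if (length(reasons))
  message(sprintf("  removal reasons: %s",
                  paste(names(reasons), reasons, sep = "=", collapse = ", ")))

r2 <- second_round_sample(cl$clean$id, n_dbest, seed = state$config$seed)
message(sprintf("round 2: %d clean ESTs selected for mapping", length(r2)))

selected <- cl$clean[match(r2, cl$clean$id), ]
write_fasta(selected, file.path(out, "clean_selected.fa"))
write_cleaning_tsv(cl$outcomes, file.path(out, "cleaning_outcomes.tsv"))
jsonlite::write_json(
  list(round1 = unclass(sampling_decision(n_dbest, 1L, length(r1),
                                          n_dbest, state$config$seed)),
       round2 = unclass(sampling_decision(n_dbest, 2L, length(r2),
                                          nrow(cl$clean), state$config$seed))),
  file.path(out, "sampling_decisions.json"), auto_unbox = TRUE)
saveRDS(list(selected = selected, outcomes = cl$outcomes),
        file.path(out, "clean_state.rds"))
message("wrote results/clean/")
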