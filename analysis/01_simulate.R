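#!/usr/bin/env Rscript
# Step 1 -- simulate the study system: a 5-chromosome 2 Mb genome with
# genes biased toward chromosome ends, three repeat classes, regional GC
# variation and N gaps; a derived chromosome assembly missing 20% of the
# sequence; a scaffold assembly of the same genome; contaminant
# references; and an EST library (600 reads here, ~1% error, with vector
# flanks and organelle/rRNA/bacterial contaminants).

library(estqc)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 42L, est_count = 600L)

message("simulating genome ...")
g <- simulate_genome(cfg)
message(sprintf("  %d chromosomes, %s bases, %d genes, %d repeat intervals",
                nrow(g$assembly$records),
                format(g$assembly$assembled_size, big.mark = ","),
                nrow(g$truth$gene_placements),
                nrow(g$truth$repeat_intervals)))

message("deriving defective assemblies ...")
chr <- derive_assembly(g, config = cfg, kind = "chromosome")
scf <- derive_assembly(g, config = cfg, kind = "scaffold")
message(sprintf("  chromosome-kind: %s of %s bases kept (%.2f%%)",
                format(chr$assembly$assembled_size, big.mark = ","),
                format(chr$assembly$genome_size, big.mark = ","),
                integrity_ratio(chr$assembly$assembled_size,
                                chr$assembly$genome_size)))
message(sprintf("  scaffold-kind: %d scaffolds", nrow(scf$assembly$records)))

refs <- simulate_references(cfg)
e <- simulate_ests(g, g$truth, refs, cfg)
message(sprintf("  %d ESTs: %s", nrow(e$ests),
                paste(names(table(e$truth$est_labels$label)),
                      table(e$truth$est_labels$label),
                      sep = "=", collapse = ", ")))

write_fasta(g$assembly$records, file.path(out, "genome.fa"))
write_fasta(chr$assembly$records, file.path(out, "assembly_chromosome.fa"))
write_fasta(scf$assembly$records, file.path(out, "assembly_scaffold.fa"))
write_fasta(refs, file.path(out, "references.fa"))
write_fasta(e$ests, file.path(out, "ests.fa"))

truth <- chr$truth
truth$est_labels <- e$truth$est_labels
write.table(truth$est_labels, file.path(out, "truth_est_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(truth$repeat_intervals, file.path(out, "truth_repeats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(truth$dropped_regions, file.path(out, "truth_dropped.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(config = cfg, genome = g, chromosome = chr, scaffold = scf,
             refs = refs, ests = e$ests, truth = truth),
        file.path(out, "sim_state.rds"))
message("wrote results/sim/")
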