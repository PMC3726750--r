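test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- tiny_config()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$assembly$records$seq, g2$assembly$records$seq)
  expect_identical(g1$truth$gene_placements, g2$truth$gene_placements)
  r1 <- simulate_references(cfg)
  r2 <- simulate_references(cfg)
  expect_identical(r1, r2)
  e1 <- simulate_ests(g1, g1$truth, r1, cfg)
  e2 <- simulate_ests(g2, g2$truth, r2, cfg)
  expect_identical(e1$ests$seq, e2$ests$seq)
  d1 <- derive_assembly(g1, config = cfg)
  d2 <- derive_assembly(g2, config = cfg)
  expect_identical(d1$assembly$records$seq, d2$assembly$records$seq)
})

test_that("full end bias places every gene midpoint in the outer quarters", {
  cfg <- tiny_config(gene_end_bias = 1, n_genes = 60L)
  g <- simulate_genome(cfg)
  genes <- g$truth$gene_placements
  mid <- (genes$span_start + genes$span_end) / 2
  L <- cfg$chrom_length
  expect_true(all(mid < L / 4 | mid > 3 * L / 4))
})

test_that("regional GC tracks the configured targets within two points", {
  cfg <- tiny_config(n_gap_fraction = 0, gc_levels = c(0.35, 0.45, 0.25),
                     gc_region_length = 75000L)
  g <- simulate_genome(cfg)
  regions <- g$truth$gc_regions
  big <- regions[regions$end - regions$start >= 50000, ]
  for (i in seq_len(nrow(big))) {
    rec <- g$assembly$records[g$assembly$records$id == big$target_id[i], ]
    gc <- gc_fraction(substr(rec$seq, big$start[i] + 1L, big$end[i]))
    expect_lt(abs(gc - big$gc_target[i]), 0.02)
  }
})

test_that("derived chromosome assemblies excise the configured fraction", {
  cfg <- tiny_config(drop_fraction = 0)
  g <- simulate_genome(cfg)
  d0 <- derive_assembly(g, config = cfg)
  expect_equal(d0$assembly$assembled_size, d0$assembly$genome_size)
  expect_equal(integrity_ratio(d0$assembly$assembled_size,
                               d0$assembly$genome_size), 100)

  cfg25 <- tiny_config(drop_fraction = 0.25, drop_chunk_mean = 20000L)
  g2 <- simulate_genome(cfg25)
  d <- derive_assembly(g2, config = cfg25)
  total <- g2$assembly$assembled_size
  expect_lt(abs(d$assembly$assembled_size - 0.75 * total), 1000)
  expect_equal(d$assembly$genome_size, total)
  # dropped regions are disjoint and account for the removed bases
  dr <- d$truth$dropped_regions
  expect_equal(sum(dr$end - dr$start), total - d$assembly$assembled_size)
  for (id in unique(dr$target_id)) {
    sub <- dr[dr$target_id == id, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
})

test_that("scaffold derivation fragments chromosomes around the mean length", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 500000L,
                    n_genes = 40L, fragmentation = 50000L,
                    unplaced_fraction = 0, seed = 9L)
  g <- simulate_genome(cfg)
  d <- derive_assembly(g, config = cfg, kind = "scaffold")
  n <- nrow(d$assembly$records)
  expect_gte(n, 10L)   # 1 Mb at ~50 kb per scaffold
  expect_lte(n, 40L)
  expect_equal(d$assembly$kind, "scaffold")
  expect_equal(d$assembly$assembled_size, d$assembly$genome_size)
  # with unplaced scaffolds, size drops and the ledger records them
  cfg2 <- sim_config(n_chromosomes = 2L, chrom_length = 500000L,
                     n_genes = 40L, fragmentation = 50000L,
                     unplaced_fraction = 0.2, seed = 9L)
  d2 <- derive_assembly(simulate_genome(cfg2), config = cfg2,
                        kind = "scaffold")
  expect_lt(d2$assembly$assembled_size, d2$assembly$genome_size)
  expect_gt(nrow(d2$truth$dropped_regions), 0)
})

test_that("references are labelled, bounded and reproducible", {
  cfg <- tiny_config()
  refs <- simulate_references(cfg)
  expect_gte(nrow(refs), 5L)
  classes <- sub("^class=", "", refs$desc)
  expect_setequal(unique(classes),
                  c("vector", "rRNA", "bacterial", "chloroplast",
                    "mitochondrial"))
  vec <- refs[classes == "vector", ]
  expect_true(all(vec$length >= 30 & vec$length <= 3000))
})

test_that("error-free genic ESTs are exact spliced substrings of their gene", {
  cfg <- tiny_config(est_count = 40L)
  g <- simulate_genome(cfg)
  refs <- simulate_references(cfg)
  e <- simulate_ests(g, g$truth, refs, cfg)
  genes <- g$truth$gene_placements
  for (i in seq_len(nrow(e$ests))) {
    lab <- e$truth$est_labels[i, ]
    gi <- match(lab$gene_id, genes$gene_id)
    rec <- g$assembly$records[g$assembly$records$id == genes$chrom[gi], ]
    tx <- estqc:::gene_transcript(rec$seq, genes[gi, ])
    est <- e$ests$seq[i]
    if (lab$orientation == "-") est <- reverse_complement(est)
    expect_true(grepl(est, tx, fixed = TRUE))
  }
})

test_that("contaminant labels follow the configured mixture", {
  cfg <- tiny_config(est_count = 1000L,
                     contaminant_mix = c(vector_flanked = 0.1))
  g <- simulate_genome(cfg)
  refs <- simulate_references(cfg)
  e <- simulate_ests(g, g$truth, refs, cfg)
  n_vec <- sum(e$truth$est_labels$label == "vector_flanked_genic")
  expect_lt(abs(n_vec - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  # all-contaminant mixture
  cfg2 <- tiny_config(est_count = 50L,
                      contaminant_mix = c(chloroplast = 1.0))
  e2 <- simulate_ests(g, g$truth, refs, cfg2)
  expect_true(all(e2$truth$est_labels$label == "chloroplast"))
  chl <- refs$seq[sub("^class=", "", refs$desc) == "chloroplast"]
  expect_true(all(vapply(e2$ests$seq, grepl, logical(1), x = chl,
                         fixed = TRUE)))
})

test_that("planted EST identity equals one minus the error rate", {
  cfg <- tiny_config(est_count = 60L, est_error_rate = 0.02)
  g <- simulate_genome(cfg)
  refs <- simulate_references(cfg)
  e <- simulate_ests(g, g$truth, refs, cfg)
  lab <- e$truth$est_labels
  # by construction coordinates: recorded error counts over window length
  lens <- lab$tx_end - lab$tx_start
  expect_equal(lens, e$ests$length)
  rate <- sum(lab$n_errors) / sum(lens)
  se <- sqrt(0.02 * 0.98 / sum(lens))
  expect_lt(abs(rate - 0.02), 3 * se)
  # the recorded counts agree with a direct comparison against the
  # source transcript window
  genes <- g$truth$gene_placements
  for (i in c(1L, 17L, 42L)) {
    gi <- match(lab$gene_id[i], genes$gene_id)
    rec <- g$assembly$records[g$assembly$records$id == genes$chrom[gi], ]
    tx <- estqc:::gene_transcript(rec$seq, genes[gi, ])
    est <- e$ests$seq[i]
    if (lab$orientation[i] == "-") est <- reverse_complement(est)
    win <- substr(tx, lab$tx_start[i] + 1L, lab$tx_end[i])
    d <- sum(strsplit(est, "")[[1]] != strsplit(win, "")[[1]])
    expect_equal(d, lab$n_errors[i])
  }
  # the aligner's measured identity tracks the planted identity closely
  res <- map_all(e$ests, g$assembly, test_align_params())
  expect_lt(abs(mean(1 - res$hits$identity) - rate), 0.006)
})

test_that("infeasible EST lengths are rejected", {
  cfg <- tiny_config(est_length = c(50000L, 60000L))
  g <- simulate_genome(cfg)
  refs <- simulate_references(cfg)
  expect_error(simulate_ests(g, g$truth, refs, cfg), "exonic span")
})
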