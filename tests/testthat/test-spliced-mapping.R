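test_that("a perfect ungapped substring scores match x length", {
  withr::with_seed(10, {
    tg <- rnd_dna(1000)
  })
  est <- substr(tg, 301, 600)
  h <- spliced_align_exhaustive(est, tg)
  expect_equal(h$score, 300L)
  expect_equal(h$identity, 1)
  expect_equal(h$coverage, 1)
  expect_true(h$matched)
  expect_equal(h$n_blocks, 1L)
  expect_equal(h$blocks[[1]][1, ], c(300L, 600L), ignore_attr = TRUE)
})

test_that("a two-exon EST recovers both exons across a GT..AG intron", {
  inst <- two_exon_instance()
  p <- align_params(max_intron = 2000L)
  h <- spliced_align_exhaustive(inst$est, inst$target, p)
  expect_equal(h$score, 300L - 20L)   # 300 matches minus spliced intron
  expect_equal(h$n_blocks, 2L)
  b <- h$blocks[[1]]
  expect_equal(b[1, ], c(inst$e1_start, inst$e1_end), ignore_attr = TRUE)
  expect_equal(b[2, ], c(inst$e2_start, inst$e2_end), ignore_attr = TRUE)
  # independent check: naive reference DP agrees on the optimum
  expect_equal(h$score, oracle_spliced_score(inst$est, inst$target, p))
})

test_that("non-canonical intron boundaries cost exactly the full penalty", {
  # same construction with CT..AC boundaries; the no-G alphabet ensures
  # no spurious GT donor or AG acceptor exists anywhere in the target
  gt <- two_exon_instance(donor = "GT", acceptor = "AG")
  ct <- two_exon_instance(donor = "CT", acceptor = "AC")
  p <- align_params(max_intron = 2000L)
  h_gt <- spliced_align_exhaustive(gt$est, gt$target, p)
  h_ct <- spliced_align_exhaustive(ct$est, ct$target, p)
  expect_equal(h_gt$score, 280L)
  expect_equal(h_ct$score, 260L)
  expect_equal(h_gt$score - h_ct$score,
               p$intron_open - p$spliced_intron_open)
  # without a splice-site anchor the intron can slide along equal-scoring
  # placements, so only its length is pinned down
  b <- h_ct$blocks[[1]]
  expect_equal(nrow(b), 2L)
  expect_equal(b[2, 1] - b[1, 2], 100L)
})

test_that("strand symmetry: reverse-complementing the EST flips the strand only", {
  inst <- two_exon_instance(seed = 77L)
  p <- align_params(max_intron = 2000L)
  fwd <- spliced_align_exhaustive(inst$est, inst$target, p)
  rev <- spliced_align_exhaustive(reverse_complement(inst$est), inst$target, p)
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
  expect_equal(rev$score, fwd$score)
  expect_equal(rev$blocks[[1]], fwd$blocks[[1]])
  expect_equal(rev$identity, fwd$identity)
})

test_that("appending matching residues never decreases the optimal score", {
  withr::with_seed(21, {
    for (r in 1:10) {
      tg <- rnd_dna(400)
      s0 <- sample(50:150, 1)
      len <- sample(50:120, 1)
      est <- substr(tg, s0, s0 + len - 1)
      sc0 <- spliced_align_exhaustive(est, tg)$score
      ext <- sample(10:40, 1)
      est2 <- substr(tg, s0, s0 + len + ext - 1)
      sc1 <- spliced_align_exhaustive(est2, tg)$score
      expect_gte(sc1, sc0)
    }
  })
})

test_that("exhaustive mode rejects oversized targets with a capacity error", {
  expect_error(
    estqc:::.spliced_align_cpp(strrep("ACGT", 5000), strrep("ACGT", 100000),
                               1L, -1L, 2L, 40L, 20L, 30L, 1000L, 1.5e8),
    "map_est")
})

test_that("seeded windows find planted loci and stay empty for foreign sequence", {
  withr::with_seed(31, {
    recs <- sequence_records(c("c1", "c2"),
                             c(rnd_dna(20000), rnd_dna(20000)))
  })
  asm <- assembly_set(recs, "chromosome", genome_size = 40000)
  p <- align_params(max_intron = 1000L)
  est <- substr(recs$seq[2], 5001, 5400)
  win <- seed_candidates(est, asm, p)
  expect_true(any(win$target_id == "c2" & win$start <= 5000 & win$end >= 5400))
  # a foreign random EST shares no 12-mers with overwhelming probability
  withr::with_seed(32, foreign <- rnd_dna(60))
  win2 <- seed_candidates(foreign, asm, p)
  expect_lte(nrow(win2), 1L)  # at most a spurious low-support window
  # tandem duplication: both copies end up inside returned windows
  tandem <- paste0(recs$seq[1], substr(recs$seq[1], 1001, 1600))
  asm2 <- assembly_set(sequence_records("t", tandem), "chromosome", 20600)
  win3 <- seed_candidates(substr(recs$seq[1], 1001, 1600), asm2, p)
  expect_true(any(win3$start <= 1000 & win3$end >= 1600))
  expect_true(any(win3$end >= 20600 - 1))
})

test_that("map_est equals the exhaustive DP on random related pairs", {
  # oracle-equivalence sweep at reduced seeding stringency so that every
  # related pair opens a window covering the whole target
  p <- align_params(seed_k = 8L, min_seed_hits = 1L, max_intron = 150L,
                    seed_max_freq = Inf)
  withr::with_seed(41, {
    for (r in 1:60) {
      tg <- rnd_dna(sample(120:200, 1))
      s0 <- sample.int(nchar(tg) - 60, 1)
      est <- substr(tg, s0, s0 + sample(25:59, 1))
      # sprinkle up to 2 substitutions
      nmut <- sample(0:2, 1)
      if (nmut > 0) {
        ch <- strsplit(est, "")[[1]]
        at <- sample(seq_along(ch), nmut)
        ch[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
        est <- paste(ch, collapse = "")
      }
      asm <- assembly_set(sequence_records("t", tg), "chromosome", nchar(tg))
      ex <- spliced_align_exhaustive(est, tg, p)
      mp <- map_est(est, asm, p)
      expect_false(is.null(mp))
      expect_equal(mp$score, ex$score)
    }
  })
})

test_that("map_est returns NULL for unmappable input", {
  withr::with_seed(51, {
    asm <- assembly_set(sequence_records("c1", rnd_dna(5000)),
                        "chromosome", 5000)
  })
  expect_null(map_est(strrep("N", 300), asm))
  withr::with_seed(52, foreign <- rnd_dna(300))
  h <- map_est(foreign, asm, align_params(max_intron = 500L))
  expect_true(is.null(h) || !h$matched)
})

test_that("map_all counts one decision per EST against planted truth", {
  cfg <- tiny_config()
  g <- simulate_genome(cfg)
  refs <- simulate_references(cfg)
  e <- simulate_ests(g, g$truth, refs, cfg)
  res <- map_all(e$ests, g$assembly, test_align_params())
  expect_equal(res$selected_count, nrow(e$ests))
  # error-free genic ESTs on the intact genome all match
  expect_equal(res$matched_count, nrow(e$ests))
  expect_equal(accuracy_ratio(res$matched_count, res$selected_count), 100)
  # hits land on the chromosome the source gene sits on
  genes <- g$truth$gene_placements
  src <- genes$chrom[match(e$truth$est_labels$gene_id, genes$gene_id)]
  expect_equal(res$hits$target_id[match(e$ests$id, res$hits$est_id)], src)
})

test_that("BED12 and TSV hit writers emit consistent block structure", {
  inst <- two_exon_instance()
  p <- align_params(max_intron = 2000L)
  h <- spliced_align_exhaustive(inst$est, inst$target, p,
                                est_id = "e1", target_id = "chr1")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed12(h, bed)
  f <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(length(f), 12L)
  expect_equal(f[1], "chr1")
  expect_equal(as.integer(f[10]), 2L)
  sizes <- as.integer(strsplit(f[11], ",")[[1]])
  starts <- as.integer(strsplit(f[12], ",")[[1]])
  expect_equal(sizes, as.integer(h$blocks[[1]][, 2] - h$blocks[[1]][, 1]))
  expect_equal(as.integer(f[2]) + starts,
               as.integer(h$blocks[[1]][, 1]))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(h, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$score, h$score)
  expect_equal(back$matched, h$matched)
})
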