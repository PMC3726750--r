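test_that("planted tandem arrays are reported with canonical motifs", {
  withr::with_seed(61, bg <- rnd_dna(3000))
  seq <- paste0(substr(bg, 1, 1000), strrep("AT", 20), substr(bg, 1041, 3000))
  hits <- find_simple_repeats(seq)
  at <- hits[hits$motif == "AT" & hits$start >= 990 & hits$end <= 1050, ]
  expect_equal(nrow(at), 1L)
  expect_lte(at$start, 1000L)     # may extend by chance boundary matches
  expect_gte(at$end, 1040L)
  # homopolymer reports unit "A", not a longer rotation of it
  mono <- find_simple_repeats(paste0("CGCGT", strrep("A", 30), "TGCGC"))
  expect_true(any(mono$motif == "A" & (mono$end - mono$start) >= 30))
  # "TA" canonicalizes to "AT"
  expect_equal(estqc:::canonical_rotation("TA"), "AT")
  expect_equal(estqc:::canonical_rotation("GAT"), "ATG")
})

test_that("simple-repeat detector agrees exactly with the brute-force oracle", {
  withr::with_seed(62, {
    for (r in 1:25) {
      # AT-rich composition makes chance short runs common
      seq <- rnd_dna(2000, c("A", "A", "T", "T", "C", "G"))
      det <- find_simple_repeats(seq, min_length = 24L, min_copies = 8L)
      ora <- oracle_simple_repeats(seq, min_length = 24L, min_copies = 8L)
      expect_equal(nrow(det), nrow(ora))
      if (nrow(det)) {
        expect_equal(det$start, ora$start)
        expect_equal(det$end, ora$end)
        expect_equal(det$motif, ora$motif)
      }
    }
  })
})

test_that("entropy windows flag biased tracts and pass uniform sequence", {
  # 2-bit sequence never flags at a 1-bit threshold
  expect_equal(nrow(find_low_complexity(strrep("ACGT", 100),
                                        window = 64L, entropy_max = 1.0)), 0L)
  # strongly biased tract flags
  withr::with_seed(63, {
    tract <- paste(sample(c("A", "C"), 400, TRUE, prob = c(0.95, 0.05)),
                   collapse = "")
    bg <- rnd_dna(2000)
  })
  seq <- paste0(substr(bg, 1, 1000), tract, substr(bg, 1001, 2000))
  lc <- find_low_complexity(seq)
  expect_gt(nrow(lc), 0L)
  expect_true(any(lc$start >= 900 & lc$end <= 1500))
  # uniform random: flagged fraction at most 1%
  withr::with_seed(64, unif <- rnd_dna(100000))
  flagged <- find_low_complexity(unif)
  expect_lte(sum(flagged$end - flagged$start) / 100000, 0.01)
})

test_that("k-mer frequency detector recovers a dispersed family", {
  cfg <- tiny_config()
  g <- simulate_genome(cfg)
  iv <- find_interspersed(g$assembly)
  planted <- g$truth$repeat_intervals
  fam <- planted[planted$class == "interspersed", ]
  covered <- 0L
  well_covered <- 0L
  for (i in seq_len(nrow(fam))) {
    det <- iv[iv$target_id == fam$target_id[i], ]
    ov <- sum(pmax(0L, pmin(det$end, fam$end[i]) - pmax(det$start, fam$start[i])))
    covered <- covered + ov
    if (ov >= 0.8 * (fam$end[i] - fam$start[i]))
      well_covered <- well_covered + 1L
  }
  expect_gte(well_covered / nrow(fam), 0.9)
  # unique random sequence stays clean
  withr::with_seed(65, uni <- rnd_dna(100000))
  asm <- assembly_set(sequence_records("u", uni), "chromosome", 100000)
  expect_equal(nrow(find_interspersed(asm)), 0L)
  # duplicated chromosomes: everything flagged at copy_min 2
  asm2 <- assembly_set(sequence_records(c("a", "b"), c(uni, uni)),
                       "chromosome", 200000)
  iv2 <- find_interspersed(asm2, copy_min = 2L)
  expect_gte(sum(iv2$end - iv2$start) / 200000, 0.99)
})

test_that("planted repeat bases of all three classes are recovered", {
  cfg <- tiny_config()
  g <- simulate_genome(cfg)
  planted <- g$truth$repeat_intervals
  detected <- list(
    interspersed = find_interspersed(g$assembly),
    simple = do.call(rbind, lapply(seq_len(nrow(g$assembly$records)),
      function(i) find_simple_repeats(g$assembly$records[i, ]))),
    low_complexity = do.call(rbind, lapply(seq_len(nrow(g$assembly$records)),
      function(i) find_low_complexity(g$assembly$records[i, ]))))
  for (cls in names(detected)) {
    p <- planted[planted$class == cls, ]
    d <- detected[[cls]]
    rec_bases <- 0L
    for (i in seq_len(nrow(p))) {
      sub <- d[d$target_id == p$target_id[i], ]
      rec_bases <- rec_bases +
        sum(pmax(0L, pmin(sub$end, p$end[i]) - pmax(sub$start, p$start[i])))
    }
    expect_gte(rec_bases / sum(p$end - p$start), 0.9)
  }
  # false masking on a repeat-free control stays at or below 2% of bases
  withr::with_seed(66, ctrl <- rnd_dna(150000))
  rec <- sequence_records("ctrl", ctrl)
  asm <- assembly_set(rec, "chromosome", 150000)
  masked <- rbind(find_simple_repeats(rec), find_low_complexity(rec),
                  find_interspersed(asm))
  expect_lte(sum(masked$end - masked$start) / 150000, 0.02)
})

test_that("per-segment repeat counts follow overlap arithmetic", {
  rec <- sequence_records("t", strrep("A", 250))
  iv <- tibble::tibble(target_id = "t", start = 50L, end = 150L,
                       class = "simple", motif = "A")
  prof <- repeat_profile(rec, iv, width = 100L)
  expect_equal(prof$repeat_count, c(1L, 1L, 0L))
  expect_equal(prof$repeat_length, c(50L, 50L, 0L))
  # no intervals -> zeros
  p0 <- repeat_profile(rec, iv[0, ], width = 100L)
  expect_true(all(p0$repeat_count == 0L) && all(p0$repeat_length == 0L))
  # exact tiling sums to the width
  iv2 <- tibble::tibble(target_id = "t", start = c(100L, 130L),
                        end = c(130L, 200L), class = "simple", motif = "A")
  p2 <- repeat_profile(rec, iv2, width = 100L)
  expect_equal(p2$repeat_length[2], 100L)
  # conservation: segment masked lengths sum to the merged-interval total
  withr::with_seed(67, {
    starts <- sort(sample.int(220, 12)) - 1L
    ends <- pmin(starts + sample.int(25, 12), 250L)
  })
  m <- estqc:::merge_touching(starts, ends)
  ivr <- tibble::tibble(target_id = "t", start = as.integer(m[, 1]),
                        end = as.integer(m[, 2]), class = "simple",
                        motif = NA_character_)
  pr <- repeat_profile(rec, ivr, width = 100L)
  expect_equal(sum(pr$repeat_length), sum(ivr$end - ivr$start))
})

test_that("gc_profile matches the length-weighted mean identity", {
  cfg <- tiny_config()
  g <- simulate_genome(cfg)
  rec <- g$assembly$records[1, ]
  prof <- gc_profile(rec, width = 40000L)
  lens <- prof$segments$end - prof$segments$start
  expect_lt(abs(prof$overall - sum(prof$segments$gc * lens) / sum(lens)),
            1e-9)
  # pure-N segment reports 0 in n_inclusive mode
  recN <- sequence_records("n", paste0(strrep("N", 100), "ACGT"))
  pN <- gc_profile(recN, width = 100L)
  expect_equal(pN$segments$gc[1], 0)
  # a uniform 50% GC chromosome stays near 0.5 in every segment
  withr::with_seed(68, half <- rnd_dna(300000))
  ph <- gc_profile(sequence_records("h", half))
  expect_true(all(abs(ph$segments$gc - 0.5) < 0.03))
})

test_that("repeat BED6 output is well formed", {
  iv <- tibble::tibble(target_id = "chr1", start = 10L, end = 60L,
                       class = "low_complexity", motif = NA_character_)
  path <- withr::local_tempfile(fileext = ".bed")
  write_repeats_bed6(iv, path)
  f <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(f, c("chr1", "10", "60", "low_complexity", "0", "."))
})
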