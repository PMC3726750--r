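# Shared fixtures and independent oracles.

rnd_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a small, fast simulation config used across tests; overrides win
tiny_config <- function(...) {
  base <- list(
    n_chromosomes = 2L, chrom_length = 150000L, n_genes = 40L,
    n_gap_fraction = 0.01, n_gap_mean = 2000L,
    repeat_config = list(
      simple = list(n_arrays = 10L, motifs = c("AG", "AT"),
                    array_length = c(60L, 160L)),
      low_complexity = list(n_tracts = 6L,
                            tract_length = c(300L, 500L),
                            major_base = "A", major_prob = 0.85),
      interspersed = list(n_families = 1L, unit_length = 400L,
                          copies = 12L, divergence = 0.02)),
    est_count = 100L, est_error_rate = 0,
    contaminant_mix = c(chloroplast = 0), seed = 5L)
  args <- utils::modifyList(base, list(...))
  do.call(sim_config, args)
}

# desk-scale mapping parameters matching the simulated intron range
test_align_params <- function(...) {
  align_params(max_intron = 2000L, min_seed_hits = 10L, ...)
}

# Independent simple-repeat oracle: naive per-position extension for each
# unit length, then the same maximality / containment / canonical-motif /
# merge semantics the detector promises. Quadratic; for short sequences.
oracle_simple_repeats <- function(seq, min_unit = 1L, max_unit = 6L,
                                  min_length = 20L, min_copies = 4L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  found <- list()   # list of c(start, end, unit)
  for (u in min_unit:max_unit) {
    pos <- 1L
    while (pos + u <= n) {
      # extend the periodic run starting here
      e <- pos
      while (e + u <= n && ch[e] != "N" && ch[e + u] != "N" &&
             ch[e] == ch[e + u]) e <- e + 1L
      if (e > pos) {
        run_start <- pos - 1L          # 0-based
        run_end <- e + u - 1L          # 0-based half-open
        len <- run_end - run_start
        if (len >= min_length && len >= min_copies * u) {
          contained <- FALSE
          for (f in found)
            if (f[3] < u && f[1] <= run_start && f[2] >= run_end) {
              contained <- TRUE
              break
            }
          if (!contained)
            found[[length(found) + 1L]] <- c(run_start, run_end, u)
        }
        pos <- e + u   # past this maximal run
      } else pos <- pos + 1L
    }
  }
  if (!length(found))
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0)))
  rot_min <- function(m) {
    k <- nchar(m)
    min(vapply(seq_len(k) - 1L, function(i)
      paste0(substr(m, i + 1L, k), substr(m, 1L, i)), character(1)))
  }
  df <- data.frame(
    start = vapply(found, `[`, numeric(1), 1),
    end = vapply(found, `[`, numeric(1), 2),
    motif = vapply(found, function(f)
      rot_min(substr(seq, f[1] + 1L, f[1] + f[3])), character(1)))
  out <- list()
  for (mo in unique(df$motif)) {
    sub <- df[df$motif == mo, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    ms <- sub$start[1]; me <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= me) me <- max(me, sub$end[i])
      else {
        out[[length(out) + 1L]] <- data.frame(start = ms, end = me, motif = mo)
        ms <- sub$start[i]; me <- sub$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(start = ms, end = me, motif = mo)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Independent reference DP for the spliced aligner (one strand), naive
# O(m * n * max_intron); for tiny instances only.
oracle_spliced_score <- function(est, target, p) {
  m <- nchar(est); n <- nchar(target)
  ec <- strsplit(est, "")[[1]]; tc <- strsplit(target, "")[[1]]
  H <- matrix(0L, m + 1L, n + 1L)
  for (i in 1:m) for (j in 1:n) {
    s <- if (ec[i] != "N" && ec[i] == tc[j]) p$match else p$mismatch
    v <- max(0L, H[i, j] + s, H[i, j + 1L] - p$gap_per_base,
             H[i + 1L, j] - p$gap_per_base)
    lo <- max(0L, j - p$max_intron); hi <- j - p$min_intron
    if (hi >= lo) for (jp in lo:hi) {
      spliced <- jp + 2L <= n && tc[jp + 1L] == "G" && tc[jp + 2L] == "T" &&
        j >= 2L && tc[j - 1L] == "A" && tc[j] == "G"
      pen <- if (spliced) p$spliced_intron_open else p$intron_open
      v <- max(v, H[i + 1L, jp + 1L] - pen)
    }
    H[i + 1L, j + 1L] <- v
  }
  max(H)
}

# two-exon instance over {A,C,T} so no spurious GT donor or AG acceptor
# can occur anywhere; splice dinucleotides are planted explicitly
two_exon_instance <- function(seed = 42L, exon = 150L, intron_inner = 96L,
                              donor = "GT", acceptor = "AG") {
  withr::with_seed(seed, {
    noG <- c("A", "C", "T")
    E1 <- rnd_dna(exon, noG); E2 <- rnd_dna(exon, noG)
    mid <- rnd_dna(intron_inner, noG)
    flank1 <- rnd_dna(50, noG); flank2 <- rnd_dna(50, noG)
    list(est = paste0(E1, E2),
         target = paste0(flank1, E1, donor, mid, acceptor, E2, flank2),
         e1_start = 50L, e1_end = 50L + exon,
         e2_start = 50L + exon + 4L + intron_inner,
         e2_end = 50L + 2L * exon + 4L + intron_inner)
  })
}
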