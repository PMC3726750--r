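# Genome simulator: background with regional GC, planted N gaps, three
# repeat classes, and spliced genes biased toward chromosome ends. All
# planting happens on per-chromosome character vectors; sequences are
# pasted once at the end.

#' Simulate a multi-chromosome genome with planted truth
#'
#' Deterministic given `config$seed`. Genes are coordinate annotations on
#' the background sequence (no insertion), so EST truth is exact; repeats
#' and N gaps overwrite the background and are recorded. Intron boundaries
#' are overwritten with canonical splice dinucleotides (GT..AG on the
#' gene strand).
#'
#' @param config [sim_config()]
#' @return list with `assembly` (chromosome-kind [assembly_set()] whose
#'   genome_size equals its assembled size) and `truth` ledger
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- empty_truth()
  chrom_ids <- sprintf("chr%d", seq_len(config$n_chromosomes))
  L <- config$chrom_length

  chroms <- with_stream(config$seed, "genome", {
    lapply(seq_len(config$n_chromosomes), function(ci) {
      sim_background(ci, L, config)
    })
  })
  for (ci in seq_along(chroms)) {
    truth$gc_regions <- rbind(truth$gc_regions, tibble::tibble(
      target_id = chrom_ids[ci],
      start = chroms[[ci]]$regions$start,
      end = chroms[[ci]]$regions$end,
      gc_target = chroms[[ci]]$regions$gc_target))
  }
  seqv <- lapply(chroms, `[[`, "chars")

  # occupied[[ci]]: matrix-free interval ledger to keep planted features
  # disjoint (N gaps, repeats, genes)
  occupied <- lapply(seq_along(seqv), function(i)
    tibble::tibble(start = integer(), end = integer()))

  gaps <- with_stream(config$seed, "n_gaps",
                      plan_n_gaps(config, chrom_ids))
  for (i in seq_len(nrow(gaps))) {
    ci <- match(gaps$target_id[i], chrom_ids)
    seqv[[ci]][(gaps$start[i] + 1L):gaps$end[i]] <- "N"
    occupied[[ci]] <- rbind(occupied[[ci]],
                            tibble::tibble(start = gaps$start[i], end = gaps$end[i]))
  }
  truth$n_gaps <- gaps

  planted <- with_stream(config$seed, "repeats",
                         plant_repeats(seqv, occupied, config, chrom_ids))
  seqv <- planted$seqv
  occupied <- planted$occupied
  truth$repeat_intervals <- planted$intervals

  genes <- with_stream(config$seed, "genes",
                       plant_genes(seqv, occupied, config, chrom_ids))
  seqv <- genes$seqv
  truth$gene_placements <- genes$genes

  records <- sequence_records(
    id = chrom_ids,
    seq = vapply(seqv, paste, character(1), collapse = ""),
    desc = "synthetic chromosome")
  assembly <- assembly_set(records, "chromosome",
                           genome_size = sum(records$length))
  list(assembly = assembly, truth = truth)
}

sim_background <- function(ci, L, config) {
  k <- length(config$gc_levels)
  starts <- seq.int(0L, L - 1L, by = config$gc_region_length)
  ends <- pmin(starts + config$gc_region_length, L)
  # offset the cycle per chromosome so chromosomes differ
  lev <- config$gc_levels[((seq_along(starts) - 1L + (ci - 1L)) %% k) + 1L]
  chars <- character(L)
  for (i in seq_along(starts)) {
    gc <- lev[i]
    n <- ends[i] - starts[i]
    chars[(starts[i] + 1L):ends[i]] <- sample(
      c("A", "C", "G", "T"), n, replace = TRUE,
      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  }
  list(chars = chars,
       regions = tibble::tibble(start = starts, end = ends, gc_target = lev))
}

plan_n_gaps <- function(config, chrom_ids) {
  out <- list()
  L <- config$chrom_length
  for (id in chrom_ids) {
    target <- round(config$n_gap_fraction * L)
    if (target <= 0) next
    placed <- tibble::tibble(start = integer(), end = integer())
    total <- 0L
    guard <- 0L
    while (total < target && guard < 10000L) {
      guard <- guard + 1L
      len <- max(500L, min(round(stats::rexp(1, 1 / config$n_gap_mean)),
                           target - total + 500L))
      s <- sample.int(L - len, 1L) - 1L
      if (overlaps_any(s, s + len, placed)) next
      placed <- rbind(placed, tibble::tibble(start = s, end = s + len))
      total <- total + len
    }
    if (nrow(placed))
      out[[id]] <- tibble::tibble(target_id = id, placed)
  }
  if (length(out)) do.call(rbind, out) else
    tibble::tibble(target_id = character(), start = integer(), end = integer())
}

overlaps_any <- function(s, e, intervals, pad = 0L) {
  nrow(intervals) > 0L &&
    any(intervals$start < e + pad & intervals$end > s - pad)
}

# place an interval of length len on a random chromosome, avoiding the
# occupied ledger; returns list(ci, start) or NULL after max_try failures
place_interval <- function(len, seq_lens, occupied, max_try = 200L, pad = 10L) {
  for (t in seq_len(max_try)) {
    ci <- sample.int(length(seq_lens), 1L)
    if (seq_lens[ci] <= len + 2L) next
    s <- sample.int(seq_lens[ci] - len, 1L) - 1L
    if (!overlaps_any(s, s + len, occupied[[ci]], pad))
      return(list(ci = ci, start = s))
  }
  NULL
}

random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_bases <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate & chars != "N")
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(alt[[b]], 1L), character(1))
  }
  chars
}

plant_repeats <- function(seqv, occupied, config, chrom_ids) {
  rc <- config$repeat_config
  lens <- vapply(seqv, length, integer(1))
  ivs <- list()
  add <- function(ci, s, e, class, motif, family) {
    occupied[[ci]] <<- rbind(occupied[[ci]], tibble::tibble(start = s, end = e))
    ivs[[length(ivs) + 1L]] <<- tibble::tibble(
      target_id = chrom_ids[ci], start = s, end = e,
      class = class, motif = motif, family = family)
  }

  sp <- rc$simple
  for (i in seq_len(sp$n_arrays)) {
    motif <- sample(sp$motifs, 1L)
    len <- sample(sp$array_length[1]:sp$array_length[2], 1L)
    len <- max(len, nchar(motif) * 4L)
    pos <- place_interval(len, lens, occupied)
    if (is.null(pos)) stop("infeasible packing: simple repeats")
    arr <- strsplit(strrep(motif, ceiling(len / nchar(motif))), "")[[1]][1:len]
    seqv[[pos$ci]][(pos$start + 1L):(pos$start + len)] <- arr
    add(pos$ci, pos$start, pos$start + len, "simple", motif, NA_character_)
  }

  lc <- rc$low_complexity
  bases <- c("A", "C", "G", "T")
  minor <- setdiff(bases, lc$major_base)
  for (i in seq_len(lc$n_tracts)) {
    len <- sample(lc$tract_length[1]:lc$tract_length[2], 1L)
    pos <- place_interval(len, lens, occupied)
    if (is.null(pos)) stop("infeasible packing: low-complexity tracts")
    tract <- sample(c(lc$major_base, minor), len, replace = TRUE,
                    prob = c(lc$major_prob, rep((1 - lc$major_prob) / 3, 3)))
    seqv[[pos$ci]][(pos$start + 1L):(pos$start + len)] <- tract
    add(pos$ci, pos$start, pos$start + len, "low_complexity",
        NA_character_, NA_character_)
  }

  it <- rc$interspersed
  for (f in seq_len(it$n_families)) {
    fam <- sprintf("fam%d", f)
    consensus <- strsplit(random_dna(it$unit_length, 0.45), "")[[1]]
    for (cp in seq_len(it$copies)) {
      pos <- place_interval(it$unit_length, lens, occupied)
      if (is.null(pos)) stop("infeasible packing: interspersed family copies")
      copy <- mutate_bases(consensus, it$divergence)
      seqv[[pos$ci]][(pos$start + 1L):(pos$start + it$unit_length)] <- copy
      add(pos$ci, pos$start, pos$start + it$unit_length, "interspersed",
          NA_character_, fam)
    }
  }

  list(seqv = seqv, occupied = occupied,
       intervals = if (length(ivs)) do.call(rbind, ivs) else
         empty_truth()$repeat_intervals)
}

# midpoint sampler: triangular peaks at each chromosome end with
# probability gene_end_bias, uniform otherwise
sample_midpoint <- function(L, bias) {
  if (stats::runif(1) < bias) {
    a <- L / 4
    x <- a * (1 - sqrt(1 - stats::runif(1)))   # decreasing triangular on [0, a]
    if (stats::runif(1) < 0.5) x else L - x
  } else {
    stats::runif(1) * L
  }
}

plant_genes <- function(seqv, occupied, config, chrom_ids) {
  lens <- vapply(seqv, length, integer(1))
  n <- config$n_genes
  rows <- vector("list", n)
  for (g in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(300L)) {
      ci <- sample.int(length(seqv), 1L)
      k <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
      ex <- sample(config$exon_length[1]:config$exon_length[2], k, replace = TRUE)
      ivl <- if (k > 1)
        sample(config$intron_length[1]:config$intron_length[2], k - 1L,
               replace = TRUE) else integer(0)
      span <- sum(ex) + sum(ivl)
      mid <- sample_midpoint(lens[ci], config$gene_end_bias)
      s <- as.integer(round(mid - span / 2))
      if (s < 0L || s + span > lens[ci]) next
      if (overlaps_any(s, s + span, occupied[[ci]], pad = 10L)) next
      strand <- sample(c("+", "-"), 1L)
      exon_starts <- s + cumsum(c(0L, utils::head(ex, -1) + ivl))
      exon_ends <- exon_starts + ex
      # canonical splice dinucleotides on the gene strand
      if (k > 1) {
        for (j in seq_len(k - 1L)) {
          is <- exon_ends[j]        # intron start (0-based)
          ie <- exon_starts[j + 1L] # intron end
          if (strand == "+") {
            seqv[[ci]][(is + 1L):(is + 2L)] <- c("G", "T")
            seqv[[ci]][(ie - 1L):ie] <- c("A", "G")
          } else {
            seqv[[ci]][(is + 1L):(is + 2L)] <- c("C", "T")
            seqv[[ci]][(ie - 1L):ie] <- c("A", "C")
          }
        }
      }
      occupied[[ci]] <- rbind(occupied[[ci]],
                              tibble::tibble(start = s, end = s + span))
      rows[[g]] <- tibble::tibble(
        gene_id = sprintf("gene%04d", g), chrom = chrom_ids[ci],
        strand = strand, exon_starts = list(exon_starts),
        exon_ends = list(exon_ends),
        span_start = s, span_end = s + span)
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible packing: could not place gene ", g)
  }
  list(seqv = seqv,
       genes = if (n) do.call(rbind, rows) else empty_truth()$gene_placements)
}

#' Derive a defective assembly from a simulated genome
#'
#' Chromosome kind: excises `drop_fraction` of each chromosome as a few
#' large chunks (mean `drop_chunk_mean`), recording them in
#' `truth$dropped_regions` (original coordinates). Scaffold kind: splits
#' chromosomes at Poisson breakpoints with mean spacing `fragmentation`
#' and leaves `unplaced_fraction` of scaffolds out, recorded as dropped.
#' Either way `genome_size` is set to the original genome total, creating
#' the integrity (CS/GS vs SS/GS) contrast.
#'
#' @param genome result of [simulate_genome()] (list assembly + truth),
#'   or an assembly_set with `truth` passed separately
#' @param truth truth ledger (defaults to `genome$truth`)
#' @param config [sim_config()]
#' @param kind "chromosome" or "scaffold"
#' @return list with `assembly` and updated `truth`
#' @export
derive_assembly <- function(genome, truth = genome$truth, config,
                            kind = c("chromosome", "scaffold")) {
  kind <- match.arg(kind)
  src <- if (inherits(genome, "assembly_set")) genome else genome$assembly
  stopifnot(config$drop_fraction < 1)
  gs <- sum(src$records$length)

  if (kind == "chromosome") {
    res <- with_stream(config$seed, "derive_chromosome", {
      recs <- src$records
      dropped <- list()
      newseq <- character(nrow(recs))
      for (i in seq_len(nrow(recs))) {
        L <- recs$length[i]
        target <- round(config$drop_fraction * L)
        if (target <= 0L) { newseq[i] <- recs$seq[i]; next }
        nc <- max(1L, round(target / config$drop_chunk_mean))
        w <- stats::runif(nc) + 0.2
        sizes <- pmax(1L, as.integer(round(target * w / sum(w))))
        sizes[nc] <- max(1L, target - sum(sizes[-nc]))
        ivs <- tibble::tibble(start = integer(), end = integer())
        for (len in sizes) {
          for (t in seq_len(500L)) {
            s <- sample.int(L - len, 1L) - 1L
            if (!overlaps_any(s, s + len, ivs)) {
              ivs <- rbind(ivs, tibble::tibble(start = s, end = s + len))
              break
            }
          }
        }
        ivs <- ivs[order(ivs$start), ]
        keep_s <- c(0L, ivs$end)
        keep_e <- c(ivs$start, L)
        pieces <- substring(recs$seq[i], keep_s + 1L, keep_e)
        newseq[i] <- paste(pieces, collapse = "")
        dropped[[length(dropped) + 1L]] <-
          tibble::tibble(target_id = recs$id[i], ivs)
      }
      recs$seq <- newseq
      recs$length <- nchar(newseq)
      list(recs = recs, dropped = dropped)
    })
    truth$dropped_regions <- rbind(truth$dropped_regions,
                                   if (length(res$dropped)) do.call(rbind, res$dropped))
    asm <- assembly_set(res$recs, "chromosome", genome_size = gs)
    return(list(assembly = asm, truth = truth))
  }

  # scaffold kind
  res <- with_stream(config$seed, "derive_scaffold", {
    out <- list(); dropped <- list(); sc <- 0L
    for (i in seq_len(nrow(src$records))) {
      L <- src$records$length[i]
      cuts <- 0L
      pos <- 0L
      while (TRUE) {
        step <- max(1000L, round(stats::rexp(1, 1 / config$fragmentation)))
        pos <- pos + step
        if (pos >= L) break
        cuts <- c(cuts, pos)
      }
      starts <- cuts
      ends <- c(cuts[-1], L)
      for (j in seq_along(starts)) {
        sc <- sc + 1L
        piece <- substr(src$records$seq[i], starts[j] + 1L, ends[j])
        if (stats::runif(1) < config$unplaced_fraction) {
          dropped[[length(dropped) + 1L]] <- tibble::tibble(
            target_id = src$records$id[i], start = starts[j], end = ends[j])
        } else {
          out[[length(out) + 1L]] <- tibble::tibble(
            id = sprintf("scaffold%05d", sc),
            desc = sprintf("from=%s:%d-%d", src$records$id[i], starts[j], ends[j]),
            seq = piece, length = nchar(piece))
        }
      }
    }
    list(recs = do.call(rbind, out), dropped = dropped)
  })
  truth$dropped_regions <- rbind(truth$dropped_regions,
                                 if (length(res$dropped)) do.call(rbind, res$dropped))
  asm <- assembly_set(res$recs, "scaffold", genome_size = gs)
  list(assembly = asm, truth = truth)
}
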