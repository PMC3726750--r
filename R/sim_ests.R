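# EST library simulator: spliced genic reads with substitution noise,
# vector-flanked reads, and contaminant reads drawn from synthetic
# rRNA/bacterial/organelle references.

#' Simulate contaminant and vector reference sequences
#'
#' One synthetic reference per contaminant class (rRNA, bacterial,
#' chloroplast, mitochondrial) plus a two-entry vector/adaptor library.
#' Random sequences are used: they share no content with the simulated
#' genome, so screening specificity is measurable. Deterministic given
#' `config$seed`.
#'
#' @param config [sim_config()]
#' @return tibble of sequence records; `desc` carries `class=<label>`
#' @export
simulate_references <- function(config) {
  with_stream(config$seed, "references", {
    spec <- list(
      c(id = "vec1", class = "vector", len = 600),
      c(id = "vec2", class = "vector", len = 1500),
      c(id = "rrna16s", class = "rRNA", len = 1500),
      c(id = "bact1", class = "bacterial", len = 20000),
      c(id = "chloro1", class = "chloroplast", len = 30000),
      c(id = "mito1", class = "mitochondrial", len = 20000)
    )
    sequence_records(
      id = vapply(spec, `[[`, character(1), "id"),
      seq = vapply(spec, function(s) random_dna(as.integer(s[["len"]]), 0.45),
                   character(1)),
      desc = paste0("class=", vapply(spec, `[[`, character(1), "class"))
    )
  })
}

# spliced transcript of a gene (5'->3' on the gene strand)
gene_transcript <- function(chrom_seq, gene) {
  ex <- substring(chrom_seq, gene$exon_starts[[1]] + 1L, gene$exon_ends[[1]])
  tx <- paste(ex, collapse = "")
  if (gene$strand == "-") reverse_complement(tx) else tx
}

#' Simulate an EST library with planted labels
#'
#' Genic ESTs are contiguous windows of a gene's spliced transcript with
#' per-base substitution noise at `est_error_rate`; half are delivered
#' reverse-complemented (single-pass reads come off either end of a
#' clone). Vector-flanked ESTs carry a vector substring prefix and suffix
#' of recorded length. Contaminant ESTs are noisy substrings of the class
#' reference. Labels and provenance are appended to the truth ledger.
#'
#' @param genome result of [simulate_genome()] or its `assembly`
#' @param truth truth ledger (defaults to `genome$truth`)
#' @param refs references from [simulate_references()]
#' @param config [sim_config()]
#' @return list with `ests` (record tibble) and updated `truth`
#' @export
simulate_ests <- function(genome, truth = genome$truth, refs, config) {
  asm <- if (inherits(genome, "assembly_set")) genome else genome$assembly
  genes <- truth$gene_placements
  if (nrow(genes) == 0L && sum(config$contaminant_mix) < 1)
    stop("no genes in truth ledger; cannot simulate genic ESTs")
  ref_class <- sub("^class=", "", refs$desc)
  vec_refs <- refs[ref_class == "vector", ]

  out <- with_stream(config$seed, "ests", {
    n <- config$est_count
    mix <- config$contaminant_mix
    labels <- sample(c(names(mix), "genic"), n, replace = TRUE,
                     prob = c(mix, 1 - sum(mix)))
    tx_cache <- new.env(parent = emptyenv())
    get_tx <- function(gi) {
      key <- as.character(gi)
      if (is.null(tx_cache[[key]])) {
        g <- genes[gi, ]
        cs <- asm$records$seq[asm$records$id == g$chrom]
        tx_cache[[key]] <- gene_transcript(cs, g)
      }
      tx_cache[[key]]
    }
    ok_genes <- which(vapply(seq_len(nrow(genes)), function(gi)
      sum(genes$exon_ends[[gi]] - genes$exon_starts[[gi]]), integer(1)) >=
        config$est_length[1])
    if (length(ok_genes) == 0L && any(labels %in% c("genic", "vector_flanked")))
      stop("est_length exceeds available exonic span for all genes")

    rows <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      lab <- labels[i]
      est_id <- sprintf("est%05d", i)
      len <- sample(config$est_length[1]:config$est_length[2], 1L)
      if (lab %in% c("genic", "vector_flanked")) {
        gi <- if (length(ok_genes)) sample(ok_genes, 1L) else
          stop("est_length exceeds available exonic span for all genes")
        tx <- get_tx(gi)
        use <- min(len, nchar(tx))
        off <- if (nchar(tx) > use) sample.int(nchar(tx) - use + 1L, 1L) - 1L else 0L
        s <- substr(tx, off + 1L, off + use)
        clean_chars <- strsplit(s, "")[[1]]
        chars <- mutate_bases(clean_chars, config$est_error_rate)
        n_err <- sum(chars != clean_chars)
        if (config$est_indel_rate > 0) chars <- apply_indels(chars, config$est_indel_rate)
        s <- paste(chars, collapse = "")
        orient <- sample(c("+", "-"), 1L)
        if (orient == "-") s <- reverse_complement(s)
        vp <- vs <- 0L
        if (lab == "vector_flanked") {
          vrow <- vec_refs[sample.int(nrow(vec_refs), 1L), ]
          vp <- sample(20:60, 1L); vs <- sample(20:60, 1L)
          po <- sample.int(vrow$length - vp + 1L, 1L) - 1L
          so <- sample.int(vrow$length - vs + 1L, 1L) - 1L
          s <- paste0(substr(vrow$seq, po + 1L, po + vp), s,
                      substr(vrow$seq, so + 1L, so + vs))
          lab <- "vector_flanked_genic"
        }
        seqs[i] <- s
        rows[[i]] <- tibble::tibble(
          est_id = est_id, label = lab, gene_id = genes$gene_id[gi],
          orientation = orient, tx_start = off, tx_end = off + use,
          n_errors = n_err, vector_prefix = vp, vector_suffix = vs)
      } else {
        ref <- refs[ref_class == lab, ][1L, ]
        use <- min(len, ref$length)
        off <- sample.int(ref$length - use + 1L, 1L) - 1L
        chars <- mutate_bases(strsplit(substr(ref$seq, off + 1L, off + use), "")[[1]],
                              config$est_error_rate)
        seqs[i] <- paste(chars, collapse = "")
        rows[[i]] <- tibble::tibble(
          est_id = est_id, label = lab, gene_id = NA_character_,
          orientation = "+", tx_start = off, tx_end = off + use,
          n_errors = sum(chars != strsplit(substr(ref$seq, off + 1L, off + use),
                                           "")[[1]]),
          vector_prefix = 0L, vector_suffix = 0L)
      }
    }
    list(ests = sequence_records(
           id = sprintf("est%05d", seq_len(n)),
           seq = seqs,
           desc = paste0("label=", vapply(rows, function(r) r$label, character(1)))),
         labels = do.call(rbind, rows))
  })
  truth$est_labels <- rbind(truth$est_labels, out$labels)
  list(ests = out$ests, truth = truth)
}

apply_indels <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  if (!any(hit)) return(chars)
  res <- character(0)
  for (i in seq_along(chars)) {
    if (hit[i]) {
      if (stats::runif(1) < 0.5) next                      # deletion
      res <- c(res, chars[i], sample(c("A", "C", "G", "T"), 1L))  # insertion
    } else res <- c(res, chars[i])
  }
  res
}

#' Fraction of genic ESTs whose source gene survives assembly derivation
#'
#' An EST counts as matchable when its source gene's full span is
#' untouched by any dropped region. This is the planted expectation the
#' measured accuracy is compared against in parameter-recovery runs.
#'
#' @param truth truth ledger after [derive_assembly()] and [simulate_ests()]
#' @return fraction in [0, 1] over genic (non-contaminant) ESTs
#' @export
planted_matchable_fraction <- function(truth) {
  genic <- truth$est_labels[truth$est_labels$label %in%
                              c("genic", "vector_flanked_genic"), ]
  stopifnot(nrow(genic) > 0L)
  genes <- truth$gene_placements
  drop <- truth$dropped_regions
  untouched <- vapply(seq_len(nrow(genes)), function(gi) {
    g <- genes[gi, ]
    d <- drop[drop$target_id == g$chrom, ]
    !overlaps_any(g$span_start, g$span_end, d)
  }, logical(1))
  names(untouched) <- genes$gene_id
  mean(untouched[genic$gene_id])
}
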