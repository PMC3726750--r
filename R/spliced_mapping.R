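# Spliced EST-to-genome mapping: exhaustive DP on small targets, k-mer
# seeded windows plus the same DP on chromosome-scale assemblies, and the
# matched/unmatched decision that defines accuracy (mEST/sEST).

#' Alignment parameters
#'
#' Scoring follows the est2genome model: +1 match, -1 mismatch, linear
#' -2 per gap base, a flat intron penalty of 40 reduced to 20 when the
#' intron is flanked by canonical GT..AG dinucleotides on the aligned
#' strand. An EST counts as matched when identity >= `identity_min` and
#' EST coverage >= `coverage_min` on its best hit.
#'
#' @param match match score (> 0)
#' @param mismatch mismatch score
#' @param gap_per_base per-base gap penalty (positive number)
#' @param intron_open flat penalty for a non-canonical intron
#' @param spliced_intron_open penalty for a GT..AG intron
#' @param min_intron,max_intron intron length bounds (bases)
#' @param seed_k seeding k-mer length
#' @param min_seed_hits k-mer hits required to open a candidate window
#' @param seed_max_freq query k-mers occurring more often than this in
#'   one target are ignored during seeding (repetitive k-mers carry no
#'   placement information)
#' @param identity_min,coverage_min matched-EST thresholds
#' @return align_params object
#' @export
align_params <- function(match = 1L, mismatch = -1L, gap_per_base = 2L,
                         intron_open = 40L, spliced_intron_open = 20L,
                         min_intron = 30L, max_intron = 100000L,
                         seed_k = 12L, min_seed_hits = 2L,
                         seed_max_freq = 50L,
                         identity_min = 0.95, coverage_min = 0.50) {
  stopifnot(match > 0, mismatch <= 0, gap_per_base >= 0,
            intron_open >= 0, spliced_intron_open >= 0,
            min_intron >= 1, min_intron < max_intron,
            identity_min > 0, identity_min <= 1,
            coverage_min > 0, coverage_min <= 1,
            seed_k >= 4, seed_k <= 15)
  structure(as.list(environment()), class = "align_params")
}

# one-row hit tibble from the C++ result; blocks shifted by window offset
build_hit <- function(res, est_id, target_id, strand, est_len, offset,
                      params) {
  if (res$score <= 0) return(NULL)
  blocks <- res$blocks + offset
  n_aligned <- res$n_aligned
  identity <- res$n_match / n_aligned
  coverage <- n_aligned / est_len
  # est span reported on the original (input-orientation) EST
  es <- res$est_start; ee <- res$est_end
  if (strand == "-") { tmp <- es; es <- est_len - ee; ee <- est_len - tmp }
  tibble::tibble(
    est_id = est_id, target_id = target_id, strand = strand,
    score = res$score, identity = identity, coverage = coverage,
    matched = identity >= params$identity_min & coverage >= params$coverage_min,
    est_start = es, est_end = ee,
    target_start = blocks[1, 1], target_end = blocks[nrow(blocks), 2],
    n_blocks = nrow(blocks), blocks = list(blocks))
}

#' Exhaustive spliced alignment of an EST against one target
#'
#' Full dynamic program over the whole target, both strands; intended for
#' targets up to ~200 kb (a capacity error points larger jobs at
#' [map_est()]). Ties between strands resolve to "+".
#'
#' @param est EST sequence (string)
#' @param target target sequence (string)
#' @param params [align_params()]
#' @param est_id,target_id labels carried into the hit
#' @return one-row hit tibble (score, identity, coverage, matched, exon
#'   blocks as a 0-based half-open matrix in a list column), or NULL when
#'   nothing scores above zero
#' @export
spliced_align_exhaustive <- function(est, target, params = align_params(),
                                     est_id = "est", target_id = "target") {
  stopifnot(nzchar(est), nzchar(target))
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") est else reverse_complement(est)
    res <- .spliced_align_cpp(q, target,
                              params$match, params$mismatch, params$gap_per_base,
                              params$intron_open, params$spliced_intron_open,
                              params$min_intron, params$max_intron)
    h <- build_hit(res, est_id, target_id, strand, nchar(est), 0L, params)
    if (!is.null(h)) hits[[strand]] <- h
  }
  pick_best_hit(hits)
}

# deterministic best-hit selection: score desc, target_id asc,
# target_start asc, "+" strand first
pick_best_hit <- function(hits) {
  hits <- Filter(Negate(is.null), hits)
  if (!length(hits)) return(NULL)
  tab <- do.call(rbind, hits)
  o <- order(-tab$score, tab$target_id, tab$target_start,
             match(tab$strand, c("+", "-")))
  tab[o[1], ]
}

#' Map one EST onto an assembly
#'
#' Runs the exhaustive DP inside each k-mer-seeded candidate window and
#' returns the single best hit (deterministic tie-break), or NULL when no
#' window is found or nothing scores above zero.
#'
#' @param est EST sequence (string) or one-row record tibble
#' @param assembly assembly_set
#' @param params [align_params()]
#' @param index optional prebuilt [kmer_index()] over `assembly`
#' @param est_id hit label (default taken from the record)
#' @return one-row hit tibble or NULL
#' @export
map_est <- function(est, assembly, params = align_params(), index = NULL,
                    est_id = NULL) {
  if (is.data.frame(est)) {
    if (is.null(est_id)) est_id <- est$id
    est <- est$seq
  }
  if (is.null(est_id)) est_id <- "est"
  if (is.null(index)) index <- kmer_index(assembly, params$seed_k)
  win <- seed_candidates(est, index, params)
  if (nrow(win) == 0L) return(NULL)
  recs <- assembly$records
  hits <- vector("list", nrow(win))
  for (w in seq_len(nrow(win))) {
    ti <- match(win$target_id[w], recs$id)
    sub <- substr(recs$seq[ti], win$start[w] + 1L, win$end[w])
    q <- if (win$strand[w] == "+") est else reverse_complement(est)
    res <- .spliced_align_cpp(q, sub,
                              params$match, params$mismatch, params$gap_per_base,
                              params$intron_open, params$spliced_intron_open,
                              params$min_intron, params$max_intron)
    hits[[w]] <- build_hit(res, est_id, win$target_id[w], win$strand[w],
                           nchar(est), win$start[w], params)
  }
  pick_best_hit(hits)
}

#' Map an EST library and count matched ESTs
#'
#' One decision per EST (best hit only). `matched_count` over
#' `selected_count` is the accuracy ratio mEST/sEST.
#'
#' @param ests record tibble of ESTs
#' @param assembly assembly_set
#' @param params [align_params()]
#' @param keep_unmatched also return near-miss hits (default TRUE)
#' @return list(hits = tibble, matched_count, selected_count)
#' @export
map_all <- function(ests, assembly, params = align_params(),
                    keep_unmatched = TRUE) {
  stopifnot(nrow(ests) > 0L)
  if (nrow(assembly$records) == 0L)
    return(list(hits = NULL, matched_count = 0L,
                selected_count = nrow(ests)))
  index <- kmer_index(assembly, params$seed_k)
  hits <- vector("list", nrow(ests))
  for (i in seq_len(nrow(ests))) {
    h <- map_est(ests$seq[i], assembly, params, index = index,
                 est_id = ests$id[i])
    if (!is.null(h) && (h$matched || keep_unmatched)) hits[[i]] <- h
  }
  hits <- do.call(rbind, Filter(Negate(is.null), hits))
  list(hits = hits,
       matched_count = if (is.null(hits)) 0L else sum(hits$matched),
       selected_count = nrow(ests))
}

#' Write hits as BED12
#'
#' Exon blocks become BED blocks; score is scaled to 0-1000 from
#' identity.
#'
#' @param hits hit tibble from [map_all()]
#' @param path output path
#' @export
write_hits_bed12 <- function(hits, path) {
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    b <- hits$blocks[[i]]
    cs <- hits$target_start[i]
    sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            hits$target_id[i], hits$target_start[i], hits$target_end[i],
            hits$est_id[i], round(1000 * hits$identity[i]), hits$strand[i],
            hits$target_start[i], hits$target_end[i], nrow(b),
            paste0(b[, 2] - b[, 1], collapse = ","),
            paste0(b[, 1] - cs, collapse = ","))
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Write hits as a flat TSV (identity/coverage/matched columns)
#'
#' @param hits hit tibble
#' @param path output path
#' @export
write_hits_tsv <- function(hits, path) {
  flat <- hits[, c("est_id", "target_id", "strand", "score", "identity",
                   "coverage", "matched", "est_start", "est_end",
                   "target_start", "target_end", "n_blocks")]
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
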