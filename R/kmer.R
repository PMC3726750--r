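# 2-bit k-mer machinery shared by the mapping seeder and the cleaning
# screens. K-mers containing N are skipped.

# numeric k-mer codes for every window start (0-based positions returned
# alongside); windows containing N are dropped
kmer_values <- function(seq, k) {
  v <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) - 1L
  n <- length(v)
  if (n < k) return(list(value = numeric(0), pos = integer(0)))
  m <- n - k + 1L
  val <- numeric(m)
  bad <- logical(m)
  for (j in 0:(k - 1L)) {
    w <- v[(1L + j):(m + j)]
    bad <- bad | is.na(w)
    w[is.na(w)] <- 0L
    val <- val + w * 4^j
  }
  keep <- !bad
  list(value = val[keep], pos = (which(keep) - 1L))
}

# sorted lookup table of one sequence's k-mers
kmer_table <- function(seq, k) {
  kv <- kmer_values(seq, k)
  o <- order(kv$value)
  list(k = k, value = kv$value[o], pos = kv$pos[o])
}

# target positions (0-based) whose k-mer equals any query value; query
# values occurring more than max_freq times in the table are skipped
# (repetitive k-mers seed nothing useful and flood the window finder)
kmer_lookup <- function(table, query_values, max_freq = Inf) {
  if (length(query_values) == 0L || length(table$value) == 0L)
    return(integer(0))
  lo <- findInterval(query_values - 0.5, table$value)
  hi <- findInterval(query_values, table$value)
  take <- hi > lo & (hi - lo) <= max_freq
  if (!any(take)) return(integer(0))
  idx <- unlist(Map(function(a, b) (a + 1L):b, lo[take], hi[take]),
                use.names = FALSE)
  sort(table$pos[idx])
}

#' Build a k-mer index over an assembly
#'
#' One sorted k-mer table per record. Build once and pass to
#' [seed_candidates()] / [map_est()] when mapping many ESTs.
#'
#' @param assembly assembly_set (or record tibble)
#' @param k k-mer length
#' @return kmer_index object
#' @export
kmer_index <- function(assembly, k = 12L) {
  records <- if (inherits(assembly, "assembly_set")) assembly$records else assembly
  tables <- lapply(records$seq, kmer_table, k = k)
  structure(list(k = k, ids = records$id,
                 lengths = records$length, tables = tables),
            class = "kmer_index")
}

# cluster sorted positions: split where the gap exceeds max_gap, keep
# clusters with >= min_hits positions
cluster_positions <- function(pos, max_gap, min_hits) {
  if (length(pos) == 0L) return(list())
  grp <- cumsum(c(1L, diff(pos) > max_gap))
  cl <- split(pos, grp)
  cl[vapply(cl, length, integer(1)) >= min_hits]
}

merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(cbind(start = integer(0), end = integer(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out <- list()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out[[length(out) + 1L]] <- c(ms, me); ms <- start[i]; me <- end[i] }
  }
  out[[length(out) + 1L]] <- c(ms, me)
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

#' Candidate alignment windows for an EST
#'
#' Looks up the EST's k-mers (both strands) in the assembly index,
#' clusters shared k-mer positions, keeps clusters with at least
#' `min_seed_hits` hits, extends each by `max_intron` on both sides and
#' merges overlapping windows. An empty result is valid (no similarity).
#'
#' @param est EST sequence (string) or one-row record tibble
#' @param assembly assembly_set, record tibble, or prebuilt [kmer_index()]
#' @param params [align_params()]
#' @return tibble with target_id, start, end, strand
#' @export
seed_candidates <- function(est, assembly, params = align_params()) {
  seq <- if (is.data.frame(est)) est$seq else est
  idx <- if (inherits(assembly, "kmer_index")) assembly
         else kmer_index(assembly, params$seed_k)
  stopifnot(idx$k == params$seed_k)
  fw <- kmer_values(seq, idx$k)$value
  rc <- kmer_values(reverse_complement(seq), idx$k)$value
  out <- list()
  for (ti in seq_along(idx$ids)) {
    for (strand in c("+", "-")) {
      qv <- sort(unique(if (strand == "+") fw else rc))
      pos <- kmer_lookup(idx$tables[[ti]], qv, params$seed_max_freq)
      for (cl in cluster_positions(pos, params$max_intron, params$min_seed_hits)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          target_id = idx$ids[ti],
          start = max(0L, min(cl) - params$max_intron),
          end = min(idx$lengths[ti], max(cl) + idx$k + params$max_intron),
          strand = strand)
      }
    }
  }
  if (!length(out))
    return(tibble::tibble(target_id = character(), start = integer(),
                          end = integer(), strand = character()))
  res <- do.call(rbind, out)
  # merge overlapping windows per target+strand
  merged <- list()
  for (key in unique(paste(res$target_id, res$strand))) {
    sub <- res[paste(res$target_id, res$strand) == key, ]
    m <- merge_intervals(sub$start, sub$end)
    merged[[key]] <- tibble::tibble(target_id = sub$target_id[1],
                                    start = m[, "start"], end = m[, "end"],
                                    strand = sub$strand[1])
  }
  res <- do.call(rbind, merged)
  rownames(res) <- NULL
  res[order(res$target_id, res$start, res$strand), ]
}
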