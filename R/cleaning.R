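# EST cleaning: vector/adaptor clipping followed by rRNA / bacterial /
# organelle screening, producing "clean" ESTs. Local alignments against
# the references go through Biostrings::pairwiseAlignment, gated by a
# shared-k-mer prefilter so ESTs with no reference similarity never pay
# for a full alignment.

#' Cleaning parameters
#'
#' Threshold defaults follow conventional vector-screen / contaminant-
#' screen practice: a terminal vector hit needs >= 95% identity over
#' >= 20 bp starting within 50 bp of an EST end; a contaminant call needs
#' >= 90% identity covering >= 80% of the EST; anything shorter than
#' 100 bp after trimming is discarded.
#'
#' @param vector_identity_min minimum identity of a vector hit
#' @param vector_hit_min minimum vector hit length (bases)
#' @param terminal_window how far from an EST end a terminal hit may start
#' @param min_clean_length minimum kept length after trimming
#' @param screen_identity_min minimum identity of a contaminant hit
#' @param screen_coverage_min minimum EST coverage of a contaminant hit
#' @param seed_k prefilter k-mer length
#' @param min_seed_hits shared k-mers required to attempt an alignment
#' @return clean_params object
#' @export
clean_params <- function(vector_identity_min = 0.95, vector_hit_min = 20L,
                         terminal_window = 50L, min_clean_length = 100L,
                         screen_identity_min = 0.90,
                         screen_coverage_min = 0.80,
                         seed_k = 12L, min_seed_hits = 1L) {
  structure(as.list(environment()), class = "clean_params")
}

# contaminant class precedence on score ties (logged in reports)
CONTAMINANT_PRECEDENCE <- c("rRNA", "chloroplast", "mitochondrial", "bacterial")

.submat_cache <- new.env(parent = emptyenv())
screen_submat <- function() {
  if (is.null(.submat_cache$m))
    .submat_cache$m <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -3, baseOnly = FALSE)
  .submat_cache$m
}

# best local alignment of query against one reference, prefiltered by
# shared k-mers; returns NULL or list(q_start, q_end, identity, length)
best_local_hit <- function(query, ref_table, ref_seq, params) {
  qk <- kmer_values(query, params$seed_k)$value
  pos <- kmer_lookup(ref_table, sort(unique(qk)))
  if (length(pos) < params$min_seed_hits) return(NULL)
  qlen <- nchar(query)
  # densest cluster of hit positions within a query-length span
  cl <- cluster_positions(pos, qlen + 100L, 1L)
  sizes <- vapply(cl, length, integer(1))
  cl <- cl[[which.max(sizes)]]
  ws <- max(0L, min(cl) - qlen - 50L)
  we <- min(nchar(ref_seq), max(cl) + params$seed_k + qlen + 50L)
  sub <- substr(ref_seq, ws + 1L, we)
  # harsh mismatch cost keeps the local alignment from extending through
  # unrelated sequence, so the hit's identity reflects the real overlap
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(sub),
    type = "local",
    substitutionMatrix = screen_submat(),
    gapOpening = 0, gapExtension = 3)
  pr <- Biostrings::pattern(aln)
  q_start <- Biostrings::start(pr@range)
  q_end <- Biostrings::end(pr@range)
  span <- q_end - q_start + 1L
  if (span < 1L) return(NULL)
  list(q_start = q_start, q_end = q_end,
       identity = Biostrings::nmatch(aln) / span, length = span)
}

ref_kmer_tables <- function(refs, params) {
  lapply(refs$seq, kmer_table, k = params$seed_k)
}

#' Clip vector/adaptor sequence off an EST
#'
#' Terminal hits (identity >= `vector_identity_min`, length >=
#' `vector_hit_min`, starting within `terminal_window` of an end) are
#' trimmed; a record left shorter than `min_clean_length` is removed with
#' reason `too_short_after_trim`. A qualifying hit that is internal on
#' the EST (possible vector-insert chimera) removes the record with
#' reason `vector_internal`, logged distinctly.
#'
#' @param est one-row record tibble
#' @param vector_refs vector/adaptor reference records
#' @param params [clean_params()]
#' @param ref_tables optional precomputed [ref_kmer_tables] result
#' @return list(outcome = one-row tibble, record = trimmed record or NULL)
#' @export
clip_vector_adaptor <- function(est, vector_refs, params = clean_params(),
                                ref_tables = NULL) {
  stopifnot(nrow(vector_refs) > 0L)
  if (is.null(ref_tables)) ref_tables <- ref_kmer_tables(vector_refs, params)
  len <- est$length
  trim_prefix <- 0L
  trim_suffix <- 0L
  internal <- FALSE
  # iterate: each pass reports one best hit per reference, so an EST with
  # vector on both ends needs a second pass after the first trim
  repeat {
    cur <- substr(est$seq, trim_prefix + 1L, len - trim_suffix)
    cur_len <- nchar(cur)
    if (cur_len < 1L) break
    progressed <- FALSE
    for (r in seq_len(nrow(vector_refs))) {
      hit <- best_local_hit(cur, ref_tables[[r]], vector_refs$seq[r], params)
      if (is.null(hit)) next
      if (hit$identity < params$vector_identity_min ||
          hit$length < params$vector_hit_min) next
      at_start <- hit$q_start <= params$terminal_window
      at_end <- hit$q_end >= cur_len - params$terminal_window + 1L
      if (at_start && hit$q_end > 0L) {
        trim_prefix <- trim_prefix + hit$q_end
        progressed <- TRUE
        break
      }
      if (at_end) {
        trim_suffix <- trim_suffix + (cur_len - hit$q_start + 1L)
        progressed <- TRUE
        break
      }
      internal <- TRUE
    }
    if (!progressed || trim_prefix + trim_suffix >= len) break
  }
  outcome <- function(action, reason, fp, fs, flen) {
    tibble::tibble(est_id = est$id, action = action,
                   removal_reason = reason, trimmed_prefix = fp,
                   trimmed_suffix = fs, final_length = flen)
  }
  if (internal)
    return(list(outcome = outcome("removed", "vector_internal",
                                  trim_prefix, trim_suffix, 0L),
                record = NULL))
  final_len <- len - trim_prefix - trim_suffix
  if (final_len < params$min_clean_length)
    return(list(outcome = outcome("removed", "too_short_after_trim",
                                  trim_prefix, trim_suffix, max(0L, final_len)),
                record = NULL))
  if (trim_prefix + trim_suffix == 0L)
    return(list(outcome = outcome("kept", NA_character_, 0L, 0L, len),
                record = est))
  rec <- est
  rec$seq <- substr(est$seq, trim_prefix + 1L, len - trim_suffix)
  rec$length <- nchar(rec$seq)
  list(outcome = outcome("trimmed_kept", NA_character_, trim_prefix,
                         trim_suffix, rec$length),
       record = rec)
}

#' Screen an EST against contaminant references
#'
#' Removed with the class of the best hit when the best local alignment
#' reaches `screen_identity_min` identity and `screen_coverage_min` EST
#' coverage. Score ties between classes resolve by the fixed precedence
#' rRNA > chloroplast > mitochondrial > bacterial.
#'
#' @param est one-row record tibble
#' @param screen_refs contaminant references; `desc` carries `class=<label>`
#' @param params [clean_params()]
#' @param ref_tables optional precomputed [ref_kmer_tables] result
#' @return one-row outcome tibble (action kept or removed)
#' @export
screen_contaminants <- function(est, screen_refs, params = clean_params(),
                                ref_tables = NULL) {
  stopifnot(nrow(screen_refs) > 0L)
  if (is.null(ref_tables)) ref_tables <- ref_kmer_tables(screen_refs, params)
  classes <- sub("^class=", "", screen_refs$desc)
  best <- NULL
  for (r in seq_len(nrow(screen_refs))) {
    hit <- best_local_hit(est$seq, ref_tables[[r]], screen_refs$seq[r], params)
    if (is.null(hit)) next
    coverage <- hit$length / est$length
    if (hit$identity < params$screen_identity_min ||
        coverage < params$screen_coverage_min) next
    score <- hit$identity * hit$length
    cand <- list(class = classes[r], score = score)
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score &&
         match(cand$class, CONTAMINANT_PRECEDENCE) <
           match(best$class, CONTAMINANT_PRECEDENCE)))
      best <- cand
  }
  if (is.null(best))
    tibble::tibble(est_id = est$id, action = "kept",
                   removal_reason = NA_character_, trimmed_prefix = 0L,
                   trimmed_suffix = 0L, final_length = est$length)
  else
    tibble::tibble(est_id = est$id, action = "removed",
                   removal_reason = best$class, trimmed_prefix = 0L,
                   trimmed_suffix = 0L, final_length = est$length)
}

#' Run the full cleaning pipeline
#'
#' Fixed stage order: vector/adaptor clipping first, contaminant
#' screening second. Every input EST gets exactly one outcome row;
#' kept + removed counts always equal the input count, and residues are
#' never altered other than by terminal trimming.
#'
#' @param ests record tibble of ESTs
#' @param vector_refs vector/adaptor references
#' @param screen_refs labelled contaminant references
#' @param params [clean_params()]
#' @return list(clean = record tibble, outcomes = tibble)
#' @export
run_cleaning <- function(ests, vector_refs, screen_refs,
                         params = clean_params()) {
  if (nrow(ests) == 0L)
    return(list(clean = ests,
                outcomes = tibble::tibble(
                  est_id = character(), action = character(),
                  removal_reason = character(), trimmed_prefix = integer(),
                  trimmed_suffix = integer(), final_length = integer())))
  vt <- ref_kmer_tables(vector_refs, params)
  st <- ref_kmer_tables(screen_refs, params)
  outcomes <- vector("list", nrow(ests))
  kept <- vector("list", nrow(ests))
  for (i in seq_len(nrow(ests))) {
    clip <- clip_vector_adaptor(ests[i, ], vector_refs, params, vt)
    if (is.null(clip$record)) { outcomes[[i]] <- clip$outcome; next }
    scr <- screen_contaminants(clip$record, screen_refs, params, st)
    if (scr$action == "removed") {
      out <- clip$outcome
      out$action <- "removed"
      out$removal_reason <- scr$removal_reason
      outcomes[[i]] <- out
    } else {
      outcomes[[i]] <- clip$outcome
      kept[[i]] <- clip$record
    }
  }
  list(clean = do.call(rbind, Filter(Negate(is.null), kept)),
       outcomes = do.call(rbind, outcomes))
}

#' Write cleaning outcomes as TSV
#'
#' @param outcomes outcome tibble from [run_cleaning()]
#' @param path output path
#' @export
write_cleaning_tsv <- function(outcomes, path) {
  utils::write.table(outcomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
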