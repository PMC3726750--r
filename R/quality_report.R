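# Headline metrics: integrity (CS/GS or SS/GS), accuracy (mEST/sEST),
# segment-matching proportion, abundance bins, correlations, and the
# four-level classification of chromosome-level assemblies. Percentages
# round half up to 2 dp, and aggregate means are unweighted means of the
# rounded per-species values, matching how such tables are printed.

#' Integrity percentage (assembled size over genome size)
#'
#' @param assembled_size assembled bases (chromosome or scaffold total)
#' @param genome_size estimated genome size (> 0), NA allowed
#' @return percentage rounded half-up to 2 dp; NA when genome size is
#'   unavailable; values above 100 are kept but flagged with a warning
#' @export
#' @examples
#' integrity_ratio(526, 742)  # 70.89
integrity_ratio <- function(assembled_size, genome_size) {
  if (is.na(genome_size)) return(NA_real_)
  stopifnot(genome_size > 0, assembled_size >= 0)
  pct <- round_half_up(100 * assembled_size / genome_size, 2)
  if (pct > 100)
    warning(sprintf("integrity %.2f%% exceeds 100%%: assembled size larger than the genome-size estimate", pct))
  pct
}

#' Accuracy percentage (matched over selected ESTs)
#'
#' @param matched_count matched ESTs
#' @param selected_count randomly selected clean ESTs (> 0)
#' @return percentage rounded half-up to 2 dp
#' @export
#' @examples
#' accuracy_ratio(14020, 15297)  # 91.65
accuracy_ratio <- function(matched_count, selected_count) {
  stopifnot(selected_count > 0, matched_count <= selected_count,
            matched_count >= 0)
  round_half_up(100 * matched_count / selected_count, 2)
}

#' Per-segment EST match counts and the segment-matching proportion
#'
#' Every matched EST increments the match count of each 0.1 Mb segment
#' its exon blocks overlap, once per segment. The proportion of segments
#' with at least one match pools segments across all records (one
#' species-level number); per-record proportions are also returned.
#'
#' @param hits hit tibble (matched ESTs only are counted)
#' @param assembly assembly_set
#' @param width segment width
#' @return list(profiles = tibble(target_id, segment_index, start, end,
#'   est_match_count), pct_segments_matched, per_record = tibble)
#' @export
segment_match_profile <- function(hits, assembly, width = 100000L) {
  recs <- assembly$records
  profs <- lapply(seq_len(nrow(recs)), function(i) {
    w <- window_iter(recs$length[i], width)
    tibble::tibble(target_id = recs$id[i], segment_index = w$segment_index,
                   start = w$start, end = w$end,
                   est_match_count = 0L)
  })
  names(profs) <- recs$id
  if (!is.null(hits) && nrow(hits)) {
    mh <- hits[hits$matched, ]
    for (i in seq_len(nrow(mh))) {
      b <- mh$blocks[[i]]
      segs <- unique(unlist(lapply(seq_len(nrow(b)), function(r)
        (b[r, 1] %/% width):((b[r, 2] - 1L) %/% width))))
      tid <- mh$target_id[i]
      segs <- segs[segs + 1L <= nrow(profs[[tid]])]
      profs[[tid]]$est_match_count[segs + 1L] <-
        profs[[tid]]$est_match_count[segs + 1L] + 1L
    }
  }
  prof <- do.call(rbind, profs)
  rownames(prof) <- NULL
  pct <- round_half_up(100 * mean(prof$est_match_count >= 1L), 2)
  per_record <- do.call(rbind, lapply(profs, function(p)
    tibble::tibble(target_id = p$target_id[1],
                   n_segments = nrow(p),
                   pct_matched = round_half_up(
                     100 * mean(p$est_match_count >= 1L), 2))))
  rownames(per_record) <- NULL
  list(profiles = prof, pct_segments_matched = pct, per_record = per_record)
}

#' Bin segment match counts into abundance classes
#'
#' Six labels: "0" (always its own class), four half-open count ranges,
#' and an open top class. Breakpoints are per-species configurable, e.g.
#' c(10, 20, 30, 40) gives 0, 1-10, 11-20, 21-30, 31-40, >40.
#'
#' @param profiles segment profile tibble with est_match_count
#' @param breakpoints strictly increasing positive counts (length 4 for
#'   the six-class scheme, any length >= 1 accepted)
#' @return profiles with an abundance_bin factor column added
#' @export
abundance_bins <- function(profiles, breakpoints = c(10, 20, 30, 40)) {
  stopifnot(length(breakpoints) >= 1, all(diff(breakpoints) > 0),
            all(breakpoints > 0))
  b <- c(0, breakpoints)
  labels <- c("0",
              vapply(seq_along(breakpoints), function(i)
                if (b[i] + 1 == b[i + 1]) sprintf("%d", b[i + 1])
                else sprintf("%d-%d", b[i] + 1, b[i + 1]), character(1)),
              sprintf(">%d", b[length(b)]))
  cuts <- cut(profiles$est_match_count, breaks = c(-Inf, 0, breakpoints, Inf),
              labels = labels, right = TRUE)
  profiles$abundance_bin <- cuts
  profiles
}

#' Four-level quality classification of a chromosome assembly
#'
#' Evaluated in order, first match wins: level 1 when integrity > 85,
#' accuracy > 85 and segment-matching > 70; level 2 when integrity > 85,
#' accuracy > 85 and segment-matching > 30; level 3 when integrity > 80
#' and accuracy > 80; level 4 otherwise (either core ratio at or below
#' 80). The ordered evaluation resolves the overlaps the verbal group
#' definitions leave open and makes the function total.
#'
#' @param integrity_pct integrity percentage
#' @param accuracy_pct accuracy percentage
#' @param pct_segments_matched segment-matching percentage
#' @return integer level 1..4
#' @export
#' @examples
#' classify(95.20, 91.65, 93.40)  # 1
#' classify(98.09, 52.93, 12.88)  # 4
classify <- function(integrity_pct, accuracy_pct, pct_segments_matched) {
  if (any(is.na(c(integrity_pct, accuracy_pct, pct_segments_matched))))
    stop("classification refused: all three percentages are required")
  if (integrity_pct > 85 && accuracy_pct > 85 && pct_segments_matched > 70)
    return(1L)
  if (integrity_pct > 85 && accuracy_pct > 85 && pct_segments_matched > 30)
    return(2L)
  if (integrity_pct > 80 && accuracy_pct > 80) return(3L)
  4L
}

#' Pearson and Spearman correlation of two per-unit series
#'
#' Zero-variance input yields NA coefficients ("unavailable"), never 0.
#'
#' @param series_a,series_b equal-length numeric vectors (n >= 3)
#' @return list(pearson, spearman, n)
#' @export
correlate <- function(series_a, series_b) {
  stopifnot(length(series_a) == length(series_b), length(series_a) >= 3,
            all(is.finite(series_a)), all(is.finite(series_b)))
  n <- length(series_a)
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_, n = n))
  list(pearson = stats::cor(series_a, series_b, method = "pearson"),
       spearman = stats::cor(series_a, series_b, method = "spearman"),
       n = n)
}

#' Assemble a quality report for one assembly
#'
#' @param assembly assembly_set
#' @param map_result list from [map_all()]
#' @param segment_result list from [segment_match_profile()], or NULL for
#'   scaffold assemblies profiled without segments
#' @param gc_avg_pct whole-assembly average GC percentage (optional)
#' @param correlations named list of [correlate()] results (optional)
#' @return quality_report object
#' @export
summarize_quality <- function(assembly, map_result, segment_result = NULL,
                              gc_avg_pct = NA_real_, correlations = list()) {
  integrity <- integrity_ratio(assembly$assembled_size, assembly$genome_size)
  accuracy <- accuracy_ratio(map_result$matched_count,
                             map_result$selected_count)
  pct_seg <- if (is.null(segment_result)) NA_real_
             else segment_result$pct_segments_matched
  level <- if (assembly$kind == "chromosome" && !is.na(pct_seg) &&
               !is.na(integrity))
    classify(integrity, accuracy, pct_seg)
  else "unclassified (scaffold)"
  structure(list(
    assembly_kind = assembly$kind,
    integrity_pct = integrity,
    accuracy_pct = accuracy,
    selected_count = map_result$selected_count,
    matched_count = map_result$matched_count,
    pct_segments_matched = pct_seg,
    level = level,
    gc_avg_pct = gc_avg_pct,
    correlations = correlations
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %s-level assembly\n", x$assembly_kind))
  lab <- if (x$assembly_kind == "chromosome") "CS/GS" else "SS/GS"
  cat(sprintf("  integrity (%s): %s\n", lab,
              ifelse(is.na(x$integrity_pct), "unavailable",
                     sprintf("%.2f%%", x$integrity_pct))))
  cat(sprintf("  accuracy (mEST/sEST): %.2f%% (%d/%d)\n", x$accuracy_pct,
              x$matched_count, x$selected_count))
  if (!is.na(x$pct_segments_matched))
    cat(sprintf("  segments with matching ESTs: %.2f%%\n",
                x$pct_segments_matched))
  cat(sprintf("  quality level: %s\n", as.character(x$level)))
  invisible(x)
}

#' Unweighted mean of rounded per-species percentages
#'
#' Aggregate rows in comparative tables are means of the printed
#' (already rounded) per-species values, rounded half-up to 2 dp.
#'
#' @param pcts numeric vector of percentages
#' @return mean percentage, 2 dp
#' @export
mean_pct <- function(pcts) {
  round_half_up(mean(pcts), 2)
}

#' Write a quality report as JSON
#'
#' @param report quality_report
#' @param path output path
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
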