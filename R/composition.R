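# Repeat-landscape and GC profiling at 0.1 Mb resolution. Three
# self-contained detectors cover the three reported repeat classes:
# short-motif tandem arrays (simple), compositionally biased tracts
# (low complexity, DUST-style entropy) and dispersed multi-copy families
# (interspersed, k-mer frequency). N runs never count as repeat.

#' Find simple (short-motif tandem) repeats
#'
#' Reports maximal tandem runs of a unit of length `min_unit`..`max_unit`
#' with at least `min_copies` copies and total length >= `min_length`.
#' A run found at a longer unit whose interval is contained in a run
#' already found at a shorter unit is a rotation/multiple of the same
#' array and is dropped; runs of the same canonical motif that touch or
#' overlap are merged. The reported motif is the lexicographically
#' smallest rotation of the unit. Positions containing N never match.
#'
#' @param record one-row record tibble (or a plain sequence string)
#' @param min_unit,max_unit unit length bounds (1..6 by default)
#' @param min_length minimum run length in bases
#' @param min_copies minimum number of unit copies (fractional final copy
#'   counts pro rata)
#' @return tibble target_id, start, end, class, motif
#' @export
find_simple_repeats <- function(record, min_unit = 1L, max_unit = 6L,
                                min_length = 20L, min_copies = 4L) {
  seq <- if (is.data.frame(record)) record$seq else record
  id <- if (is.data.frame(record)) record$id else "seq"
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  runs <- list()
  accepted <- list()  # intervals from smaller units, for containment test
  for (u in min_unit:max_unit) {
    if (n < 2L * u) next
    eq <- chars[seq_len(n - u)] == chars[(u + 1L):n] &
      chars[seq_len(n - u)] != "N" & chars[(u + 1L):n] != "N"
    r <- rle(eq)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    hit <- which(r$values)
    for (h in hit) {
      a <- starts_idx[h] - 1L           # 0-based run start
      b <- ends_idx[h] + u              # 0-based half-open end
      len <- b - a
      if (len < min_length || len < min_copies * u) next
      contained <- any(vapply(accepted, function(iv)
        iv[1] <= a && iv[2] >= b, logical(1)))
      if (contained) next
      motif <- canonical_rotation(substr(seq, a + 1L, a + u))
      runs[[length(runs) + 1L]] <- c(a, b, u)
      names(runs)[length(runs)] <- motif
      accepted[[length(accepted) + 1L]] <- c(a, b)
    }
  }
  if (!length(runs))
    return(tibble::tibble(target_id = character(), start = integer(),
                          end = integer(), class = character(),
                          motif = character()))
  df <- tibble::tibble(
    motif = names(runs),
    start = vapply(runs, `[`, numeric(1), 1),
    end = vapply(runs, `[`, numeric(1), 2))
  out <- list()
  for (mo in unique(df$motif)) {
    sub <- df[df$motif == mo, ]
    m <- merge_touching(sub$start, sub$end)
    out[[mo]] <- tibble::tibble(target_id = id, start = as.integer(m[, 1]),
                                end = as.integer(m[, 2]), class = "simple",
                                motif = mo)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$end), ]
}

canonical_rotation <- function(motif) {
  k <- nchar(motif)
  rots <- vapply(seq_len(k) - 1L, function(i)
    paste0(substr(motif, i + 1L, k), substr(motif, 1L, i)), character(1))
  min(rots)
}

# merge intervals that overlap or touch
merge_touching <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]; out <- list()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out[[length(out) + 1L]] <- c(ms, me); ms <- start[i]; me <- end[i] }
  }
  out[[length(out) + 1L]] <- c(ms, me)
  do.call(rbind, out)
}

#' Find low-complexity tracts by windowed base-composition entropy
#'
#' Windows of `window` bases advancing by `window/4` whose Shannon
#' entropy over A/C/G/T (N excluded) is at most `entropy_max` bits are
#' flagged; flagged windows closer than `merge_gap` merge into one
#' interval (sampling noise inside a long biased tract leaves short
#' above-threshold holes that belong to the same tract). Windows that
#' are mostly N are not flagged.
#'
#' @param record one-row record tibble or sequence string
#' @param window window width in bases (>= 8)
#' @param entropy_max entropy threshold in bits (uniform random sequence
#'   sits near 2 bits)
#' @param merge_gap bridge distance between flagged windows
#' @return tibble target_id, start, end, class, motif (NA)
#' @export
find_low_complexity <- function(record, window = 64L, entropy_max = 1.0,
                                merge_gap = window %/% 2L) {
  stopifnot(window >= 8L)
  seq <- if (is.data.frame(record)) record$seq else record
  id <- if (is.data.frame(record)) record$id else "seq"
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < window)
    return(tibble::tibble(target_id = character(), start = integer(),
                          end = integer(), class = character(),
                          motif = character()))
  step <- max(1L, window %/% 4L)
  starts <- seq.int(0L, n - window, by = step)
  code <- match(chars, c("A", "C", "G", "T"))  # N -> NA
  onehot <- matrix(0L, nrow = n, ncol = 4)
  ok <- !is.na(code)
  onehot[cbind(which(ok), code[ok])] <- 1L
  cum <- apply(onehot, 2, cumsum)
  cum <- rbind(0L, cum)
  counts <- cum[starts + window + 1L, , drop = FALSE] -
    cum[starts + 1L, , drop = FALSE]
  tot <- rowSums(counts)
  p <- counts / pmax(tot, 1L)
  ent <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  flagged <- which(tot >= window / 2 & ent <= entropy_max)
  if (!length(flagged))
    return(tibble::tibble(target_id = character(), start = integer(),
                          end = integer(), class = character(),
                          motif = character()))
  m <- merge_touching(starts[flagged] - merge_gap %/% 2L,
                      starts[flagged] + window + merge_gap %/% 2L)
  m[, 1] <- pmax(m[, 1] + merge_gap %/% 2L, 0L)
  m[, 2] <- pmin(m[, 2] - merge_gap %/% 2L, n)
  tibble::tibble(target_id = id, start = as.integer(m[, 1]),
                 end = as.integer(m[, 2]), class = "low_complexity",
                 motif = NA_character_)
}

#' Find interspersed repeats by genome-wide k-mer frequency
#'
#' Positions covered by a k-mer occurring at least `copy_min` times
#' across the whole assembly are flagged; flagged runs separated by less
#' than `merge_gap` bases merge, and intervals shorter than k are
#' dropped. Library-free: multi-copy families announce themselves by
#' their own k-mer excess. K-mers containing N are ignored.
#'
#' @param assembly assembly_set or record tibble
#' @param k k-mer length (11..17)
#' @param copy_min genome-wide occurrence threshold
#' @param merge_gap merge distance in bases
#' @return tibble target_id, start, end, class, motif (NA)
#' @export
find_interspersed <- function(assembly, k = 13L, copy_min = 10L,
                              merge_gap = 50L) {
  stopifnot(k >= 11L, k <= 17L)
  records <- if (inherits(assembly, "assembly_set")) assembly$records else assembly
  kv <- lapply(records$seq, kmer_values, k = k)
  allv <- unlist(lapply(kv, `[[`, "value"))
  if (!length(allv))
    return(tibble::tibble(target_id = character(), start = integer(),
                          end = integer(), class = character(),
                          motif = character()))
  uv <- unique(allv)
  cnt <- tabulate(match(allv, uv))
  frequent <- uv[cnt >= copy_min]
  out <- list()
  for (ri in seq_len(nrow(records))) {
    hot <- kv[[ri]]$pos[kv[[ri]]$value %in% frequent]
    if (!length(hot)) next
    # covered bases: union of [pos, pos+k)
    iv <- merge_touching(hot, hot + k)
    # bridge gaps below merge_gap
    if (nrow(iv) > 1L) {
      keep_s <- iv[1, 1]; res <- list(); cur_e <- iv[1, 2]
      for (i in 2:nrow(iv)) {
        if (iv[i, 1] - cur_e < merge_gap) cur_e <- iv[i, 2]
        else { res[[length(res) + 1L]] <- c(keep_s, cur_e)
               keep_s <- iv[i, 1]; cur_e <- iv[i, 2] }
      }
      res[[length(res) + 1L]] <- c(keep_s, cur_e)
      iv <- do.call(rbind, res)
    }
    iv <- iv[iv[, 2] - iv[, 1] >= k, , drop = FALSE]
    if (nrow(iv))
      out[[length(out) + 1L]] <- tibble::tibble(
        target_id = records$id[ri], start = as.integer(iv[, 1]),
        end = as.integer(iv[, 2]), class = "interspersed",
        motif = NA_character_)
  }
  if (!length(out))
    return(tibble::tibble(target_id = character(), start = integer(),
                          end = integer(), class = character(),
                          motif = character()))
  do.call(rbind, out)
}

#' Per-segment repeat count and masked length
#'
#' Counts, per 0.1 Mb segment, the number of repeat intervals overlapping
#' the segment and the overlap length summed. An interval spanning a
#' segment boundary counts in every segment it touches and contributes
#' its per-segment overlap to each.
#'
#' @param record one-row record tibble
#' @param intervals repeat intervals on this record
#' @param width segment width (default 0.1 Mb)
#' @return tibble segment_index, start, end, repeat_count, repeat_length
#' @export
repeat_profile <- function(record, intervals, width = 100000L) {
  segs <- window_iter(record, width)
  iv <- intervals[intervals$target_id %in%
                    c(if (is.data.frame(record)) record$id else "seq"), ]
  counts <- integer(nrow(segs))
  lens <- integer(nrow(segs))
  if (nrow(iv)) {
    for (i in seq_len(nrow(iv))) {
      first <- iv$start[i] %/% width
      last <- (iv$end[i] - 1L) %/% width
      for (s in first:last) {
        if (s + 1L > nrow(segs)) break
        ov <- min(iv$end[i], segs$end[s + 1L]) - max(iv$start[i], segs$start[s + 1L])
        counts[s + 1L] <- counts[s + 1L] + 1L
        lens[s + 1L] <- lens[s + 1L] + ov
      }
    }
  }
  tibble::tibble(segment_index = segs$segment_index, start = segs$start,
                 end = segs$end, repeat_count = counts, repeat_length = lens)
}

#' Per-segment GC profile
#'
#' GC fraction of every 0.1 Mb segment (default n_inclusive mode, i.e. N
#' counts in the denominator) plus the whole-record average, which equals
#' the length-weighted mean of the segment values.
#'
#' @param record one-row record tibble
#' @param width segment width
#' @param mode see [gc_fraction()]
#' @return list(segments = tibble(segment_index, start, end, gc),
#'   overall = whole-record GC fraction)
#' @export
gc_profile <- function(record, width = 100000L, mode = "n_inclusive") {
  segs <- window_iter(record, width)
  gc <- vapply(seq_len(nrow(segs)), function(i)
    gc_fraction(substr(record$seq, segs$start[i] + 1L, segs$end[i]), mode),
    numeric(1))
  list(segments = tibble::tibble(segment_index = segs$segment_index,
                                 start = segs$start, end = segs$end, gc = gc),
       overall = gc_fraction(record$seq, mode))
}

#' Write repeat intervals as BED6
#'
#' name = class, score = 0, strand = "."
#'
#' @param intervals repeat interval tibble
#' @param path output path
#' @export
write_repeats_bed6 <- function(intervals, path) {
  rows <- sprintf("%s\t%d\t%d\t%s\t0\t.",
                  intervals$target_id, intervals$start, intervals$end,
                  intervals$class)
  writeLines(rows, path)
  invisible(path)
}
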