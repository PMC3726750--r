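#' Sequence records
#'
#' Sequences move through the pipeline as plain tibbles with one row per
#' record and columns `id` (unique token), `desc` (free text, may be ""),
#' `seq` (uppercase DNA over A/C/G/T/N) and `length`. Constructing through
#' [sequence_records()] normalizes residues and checks the invariants.
#'
#' @param id character vector of unique identifiers
#' @param seq character vector of DNA strings
#' @param desc character vector of descriptions (recycled "" by default)
#' @return tibble with columns id, desc, seq, length
#' @export
sequence_records <- function(id, seq, desc = "") {
  stopifnot(length(id) == length(seq))
  if (length(id)) {
    if (anyNA(id) || any(!nzchar(id))) stop("sequence ids must be non-empty")
    dup <- unique(id[duplicated(id)])
    if (length(dup))
      stop("duplicate sequence id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  seq <- normalize_dna(seq)
  if (any(!nzchar(seq))) {
    bad <- id[!nzchar(seq)]
    stop("record(s) with zero residues: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  tibble::tibble(
    id = as.character(id),
    desc = rep_len(as.character(desc), length(id)),
    seq = seq,
    length = nchar(seq)
  )
}

# Uppercase, U -> T, anything outside {A,C,G,T} -> N.
normalize_dna <- function(seq) {
  seq <- toupper(as.character(seq))
  seq <- chartr("U", "T", seq)
  gsub("[^ACGTN]", "N", seq)
}

#' Read a FASTA file into sequence records
#'
#' Lowercase residues and U are accepted on input; residues are uppercased,
#' U mapped to T, and any other symbol (IUPAC ambiguity codes included)
#' collapsed to N. Record order is preserved. The id is the first
#' whitespace-delimited token of the header; the remainder is the
#' description.
#'
#' @param path FASTA file path
#' @return tibble of sequence records (see [sequence_records()])
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  sequence_records(id, as.character(set), desc)
}

#' Write sequence records to FASTA
#'
#' Round-trip faithful: re-reading reproduces ids and residues exactly.
#'
#' @param records tibble of sequence records
#' @param path output path
#' @param line_width wrap width for sequence lines (positive integer)
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  stopifnot(line_width >= 1L)
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc),
                       records$id)
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width))
  invisible(path)
}

#' GC fraction of a DNA string
#'
#' `n_inclusive` divides G+C by the full length (N counts in the
#' denominator); `n_exclusive` divides by the number of unambiguous bases.
#' The default is n_inclusive: assemblies with long N-rich tracts then show
#' diluted GC, which is how chromosome-wide averages are reported here.
#'
#' @param seq DNA string (single character value)
#' @param mode "n_inclusive" or "n_exclusive"
#' @return fraction in [0, 1]
#' @export
#' @examples
#' gc_fraction("ACGTNNNN")                  # 0.25
#' gc_fraction("ACGTNNNN", "n_exclusive")   # 0.5
gc_fraction <- function(seq, mode = c("n_inclusive", "n_exclusive")) {
  mode <- match.arg(mode)
  stopifnot(length(seq) == 1L, nzchar(seq))
  counts <- base_counts(seq)
  gc <- counts[["G"]] + counts[["C"]]
  if (mode == "n_inclusive") return(gc / nchar(seq))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0L) stop("gc_fraction undefined: sequence has no unambiguous bases")
  gc / acgt
}

base_counts <- function(seq) {
  x <- Biostrings::BString(seq)
  vapply(c("A", "C", "G", "T", "N"),
         function(b) Biostrings::countPattern(b, x), integer(1))
}

#' Tile a sequence into fixed-width segments
#'
#' Segments are 0-based half-open, tile `[0, length)` in order, and the
#' final partial segment is kept. The default width is the 0.1 Mb segment
#' used for all per-segment profiling.
#'
#' @param length_or_record sequence length in bases, or a one-row record tibble
#' @param width segment width in bases (>= 1)
#' @return tibble with columns segment_index (0-based), start, end
#' @export
window_iter <- function(length_or_record, width = 100000L) {
  stopifnot(width >= 1L)
  len <- if (is.data.frame(length_or_record)) {
    stopifnot(nrow(length_or_record) == 1L)
    length_or_record$length
  } else length_or_record
  stopifnot(len >= 1L)
  starts <- seq.int(0L, len - 1L, by = width)
  tibble::tibble(
    segment_index = seq_along(starts) - 1L,
    start = starts,
    end = pmin(starts + width, len)
  )
}

#' Reverse complement
#'
#' N maps to N; applying twice is the identity.
#'
#' @param seq DNA string(s) over A/C/G/T/N
#' @return reverse-complemented string(s)
#' @export
reverse_complement <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) stop("reverse_complement: alphabet must be A/C/G/T/N")
  vapply(seq, function(s) {
    rc <- rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]])
    paste(rc, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Bundle assembly records with a genome-size estimate
#'
#' @param records tibble of sequence records (chromosomes or scaffolds)
#' @param kind "chromosome" or "scaffold"; decides whether integrity is
#'   reported as CS/GS or SS/GS
#' @param genome_size externally estimated genome size in bases, or NA
#' @return assembly_set object (list with records, kind, genome_size,
#'   assembled_size)
#' @export
assembly_set <- function(records, kind = c("chromosome", "scaffold"),
                         genome_size = NA_real_) {
  kind <- match.arg(kind)
  if (!is.na(genome_size)) stopifnot(genome_size > 0)
  structure(
    list(kind = kind, records = records,
         genome_size = genome_size,
         assembled_size = sum(records$length)),
    class = "assembly_set"
  )
}

#' @export
print.assembly_set <- function(x, ...) {
  cat(sprintf("<assembly_set> %s-level, %d record(s), %s bases assembled",
              x$kind, nrow(x$records), format(x$assembled_size, big.mark = ",")))
  if (!is.na(x$genome_size))
    cat(sprintf(", genome size %s", format(x$genome_size, big.mark = ",")))
  cat("\n")
  invisible(x)
}

#' Write segment definitions as BED3
#'
#' @param assembly assembly_set
#' @param path output path
#' @param width segment width
#' @export
write_segments_bed3 <- function(assembly, path, width = 100000L) {
  rows <- do.call(rbind, lapply(seq_len(nrow(assembly$records)), function(i) {
    w <- window_iter(assembly$records$length[i], width)
    data.frame(chrom = assembly$records$id[i], start = w$start, end = w$end)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
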