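#' Simulation configuration
#'
#' Bundles every knob of the synthetic genome / assembly / EST generator.
#' Defaults describe the desk-scale study condition exercised throughout
#' the tests: a 5-chromosome, 2 Mb genome with spliced genes concentrated
#' toward chromosome ends, three repeat classes, regional GC variation
#' with N gaps, a derived assembly missing 20% of the sequence, and an
#' EST library with ~1% single-pass sequencing error plus vector flanks
#' and organelle/rRNA/bacterial contaminants.
#'
#' @param n_chromosomes number of chromosomes
#' @param chrom_length length of each chromosome (bases)
#' @param n_genes genes planted across the genome
#' @param exons_per_gene integer range c(min, max)
#' @param exon_length exon length range in bases
#' @param intron_length intron length range in bases
#' @param gene_end_bias share of genes whose midpoints are drawn from
#'   edge-concentrated triangular distributions over the outer quarters
#'   of a chromosome; the rest are uniform
#' @param gc_levels per-region GC targets, cycled along each chromosome
#' @param gc_region_length length of each constant-GC region
#' @param n_gap_fraction fraction of each chromosome replaced by N runs
#' @param n_gap_mean mean N-run length (bases)
#' @param repeat_config list with `simple`, `low_complexity` and
#'   `interspersed` sub-lists (see Details)
#' @param drop_fraction fraction of the genome excised from a derived
#'   chromosome-level assembly
#' @param drop_chunk_mean mean size of an excised chunk (bases)
#' @param fragmentation mean scaffold length for scaffold-kind assemblies
#' @param unplaced_fraction share of scaffolds left out ("unplaced")
#' @param est_count number of ESTs to simulate
#' @param est_length EST length range (bases)
#' @param est_error_rate per-base substitution probability
#' @param est_indel_rate per-base indel probability (0 by default so the
#'   planted identity stays analytic; used only for aligner stress tests)
#' @param contaminant_mix named fractions for vector_flanked, rRNA,
#'   bacterial, chloroplast, mitochondrial; remainder is plain genic
#' @param seed root RNG seed; each stage derives its own stream by name
#'
#' @details `repeat_config$simple` takes `n_arrays`, `motifs`,
#'   `array_length` (range); `$low_complexity` takes `n_tracts`,
#'   `tract_length` (range), `major_base`, `major_prob`;
#'   `$interspersed` takes `n_families`, `unit_length`, `copies`,
#'   `divergence` (per-base substitution between copies).
#'
#' @return sim_config object
#' @export
sim_config <- function(n_chromosomes = 5L,
                       chrom_length = 400000L,
                       n_genes = 300L,
                       exons_per_gene = c(2L, 6L),
                       exon_length = c(80L, 300L),
                       intron_length = c(60L, 400L),
                       gene_end_bias = 0.7,
                       gc_levels = c(0.35, 0.45, 0.25),
                       gc_region_length = 100000L,
                       n_gap_fraction = 0.02,
                       n_gap_mean = 5000L,
                       repeat_config = list(
                         simple = list(n_arrays = 60L,
                                       motifs = c("AG", "AC", "AT", "AAG"),
                                       array_length = c(60L, 240L)),
                         low_complexity = list(n_tracts = 30L,
                                               tract_length = c(300L, 600L),
                                               major_base = "A",
                                               major_prob = 0.85),
                         interspersed = list(n_families = 2L,
                                             unit_length = 500L,
                                             copies = 20L,
                                             divergence = 0.02)
                       ),
                       drop_fraction = 0.2,
                       drop_chunk_mean = 50000L,
                       fragmentation = 50000L,
                       unplaced_fraction = 0.05,
                       est_count = 2000L,
                       est_length = c(300L, 600L),
                       est_error_rate = 0.01,
                       est_indel_rate = 0,
                       contaminant_mix = c(vector_flanked = 0.05,
                                           rRNA = 0.01,
                                           bacterial = 0.01,
                                           chloroplast = 0.02,
                                           mitochondrial = 0.01),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_chromosomes >= 1, chrom_length >= 1000, n_genes >= 0,
    exons_per_gene[1] <= exons_per_gene[2], exons_per_gene[1] >= 1,
    exon_length[1] <= exon_length[2],
    intron_length[1] <= intron_length[2],
    gene_end_bias >= 0, gene_end_bias <= 1,
    all(gc_levels > 0 & gc_levels < 1),
    n_gap_fraction >= 0, n_gap_fraction < 1,
    drop_fraction >= 0, drop_fraction < 1,
    unplaced_fraction >= 0, unplaced_fraction < 1,
    est_length[1] <= est_length[2],
    est_error_rate >= 0, est_error_rate < 1,
    all(contaminant_mix >= 0), sum(contaminant_mix) <= 1
  )
  mix_names <- c("vector_flanked", "rRNA", "bacterial", "chloroplast",
                 "mitochondrial")
  stopifnot(all(names(cfg$contaminant_mix) %in% mix_names))
  full <- stats::setNames(numeric(5), mix_names)
  full[names(cfg$contaminant_mix)] <- cfg$contaminant_mix
  cfg$contaminant_mix <- full
  structure(cfg, class = "sim_config")
}

# Empty truth ledger; stages append to its components.
empty_truth <- function() {
  list(
    gene_placements = tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      exon_starts = list(), exon_ends = list(),
      span_start = integer(), span_end = integer()),
    repeat_intervals = tibble::tibble(
      target_id = character(), start = integer(), end = integer(),
      class = character(), motif = character(), family = character()),
    gc_regions = tibble::tibble(
      target_id = character(), start = integer(), end = integer(),
      gc_target = numeric()),
    n_gaps = tibble::tibble(
      target_id = character(), start = integer(), end = integer()),
    dropped_regions = tibble::tibble(
      target_id = character(), start = integer(), end = integer()),
    est_labels = tibble::tibble(
      est_id = character(), label = character(), gene_id = character(),
      orientation = character(), tx_start = integer(), tx_end = integer(),
      n_errors = integer(), vector_prefix = integer(),
      vector_suffix = integer())
  )
}
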