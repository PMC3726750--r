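# Published summary statistics for 32 public plant genome sequencing
# projects, shipped as plain TSV under inst/extdata. These printed
# size/count pairs are inputs: the ratio arithmetic, aggregate means and
# the four-level classification are recomputed from them.

#' Load the published genome-project summary table
#'
#' Columns: group (chromosome/scaffold), species, genome_size_mb (NA when
#' unpublished), assembled_size_mb, printed_pct (the percentage as
#' printed, NA when unavailable), n_units.
#'
#' @return tibble of 32 species
#' @export
genome_project_table <- function() {
  path <- system.file("extdata", "plant_genome_projects.tsv",
                      package = "estqc", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Load the published EST alignment results table
#'
#' Columns: group, species, dbest_total, selected, printed_est_pct,
#' matched, printed_accuracy_pct.
#'
#' @return tibble of 32 species
#' @export
est_alignment_table <- function() {
  path <- system.file("extdata", "est_alignment_results.tsv",
                      package = "estqc", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Load the published per-species quality summary for the 13
#' chromosome-level assemblies
#'
#' Columns: species, gc_pct, integrity_pct, accuracy_pct, segment_pct,
#' level (the published four-level grouping).
#'
#' @return tibble of 13 species
#' @export
csg_quality_table <- function() {
  path <- system.file("extdata", "csg_quality_summary.tsv",
                      package = "estqc", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
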