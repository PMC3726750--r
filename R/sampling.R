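# Two-round stratified random EST selection. Tier rules are keyed to the
# dbEST total N for the species, with strict ">" boundaries (N exactly at
# a boundary falls to the lower tier) and sample sizes rounded half up.

#' First-round EST sampling rule
#'
#' N > 10,000: select 50% of N accessions uniformly without replacement;
#' otherwise all accessions. Deterministic given seed. If the rule asks
#' for more ids than are available the count is capped with a warning.
#'
#' @param accessions character vector of EST accession ids
#' @param total_in_dbest dbEST total N for the species
#' @param seed RNG seed
#' @return selected accession ids
#' @export
first_round_sample <- function(accessions, total_in_dbest, seed = 1L) {
  stopifnot(length(accessions) > 0L, total_in_dbest >= length(accessions))
  n <- first_round_size(total_in_dbest)
  draw_sample(accessions, n, seed, "first_round")
}

#' @rdname first_round_sample
#' @export
first_round_size <- function(total_in_dbest) {
  if (total_in_dbest > 10000) tier_size(total_in_dbest, 50, Inf)
  else as.numeric(total_in_dbest)
}

#' Second-round EST sampling rule
#'
#' The percentage is keyed to the dbEST total N (not the clean-pool
#' size): N > 100,000 takes 1%, 10,000 < N <= 100,000 takes 10%,
#' N <= 10,000 takes 100%. The resulting count is capped at the clean
#' pool; sizes round half up. Deterministic given seed.
#'
#' @param clean_ids ids surviving the cleaning stage
#' @param total_in_dbest dbEST total N for the species
#' @param seed RNG seed
#' @return selected clean ids
#' @export
#' @examples
#' second_round_size(1529700)  # 15297
#' second_round_size(10855)    # 1086
second_round_sample <- function(clean_ids, total_in_dbest, seed = 1L) {
  stopifnot(length(clean_ids) > 0L)
  n <- second_round_size(total_in_dbest)
  draw_sample(clean_ids, n, seed, "second_round")
}

#' @rdname second_round_sample
#' @export
second_round_size <- function(total_in_dbest) {
  if (total_in_dbest > 100000) tier_size(total_in_dbest, 1, Inf)
  else if (total_in_dbest > 10000) tier_size(total_in_dbest, 10, Inf)
  else as.numeric(total_in_dbest)
}

draw_sample <- function(ids, n, seed, stage) {
  if (n >= length(ids)) {
    if (n > length(ids))
      warning(sprintf("%s: rule asks for %d ids but only %d available; capped",
                      stage, n, length(ids)))
    return(ids)
  }
  with_stream(seed, stage, sample(ids, n))
}

#' Record of a sampling decision
#'
#' @param total_in_dbest dbEST total N
#' @param round 1 or 2
#' @param n_selected selected count
#' @param population available pool size
#' @param seed seed used
#' @return sampling_decision list (fraction is the applied percentage)
#' @export
sampling_decision <- function(total_in_dbest, round, n_selected, population,
                              seed) {
  fraction <- if (round == 1L) {
    if (total_in_dbest > 10000) 50 else 100
  } else {
    if (total_in_dbest > 100000) 1
    else if (total_in_dbest > 10000) 10
    else 100
  }
  structure(list(total_in_dbest = total_in_dbest, round = round,
                 fraction = fraction, n_selected = n_selected,
                 population = population, seed = seed),
            class = "sampling_decision")
}
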