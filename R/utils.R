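#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.5 -> 1), the
#' convention used throughout the reports here, as opposed to [round()]'s
#' round-half-even. A tiny guard absorbs binary representation error so that
#' quantities that are exact in decimal (e.g. 1085.5) round as written.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return numeric vector rounded half-up
#' @export
#' @examples
#' round_half_up(1085.5, 0)  # 1086
#' round_half_up(70.889, 2)  # 70.89
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Derive a named RNG stream seed from a root seed
#'
#' Every stochastic stage draws from its own stream derived from the root
#' seed and a stable stage name, so adding or reordering stages never
#' perturbs another stage's draws.
#'
#' @param root integer root seed
#' @param name character stream name
#' @return integer seed below 2^31
#' @export
derive_seed <- function(root, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483647
  as.integer((as.numeric(root) %% 2147483647 * 7919 + h) %% 2147483647)
}

# Run code under a derived, locally-scoped RNG seed; restores caller RNG.
with_stream <- function(root, name, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(root, name))
  force(code)
}

# Sample size for a percentage tier, integer percent, round half up,
# capped at the population size.
tier_size <- function(n_total, percent, available) {
  n <- floor(n_total * percent / 100 + 0.5 + 1e-9)
  min(n, available)
}
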