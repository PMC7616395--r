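#' Seed size distribution
#'
#' Seed sizes are drawn from a Normal distribution (defaults: mean 0.5 g,
#' sd 0.05 g), truncated below at a small positive floor by resampling so
#' that no zero- or negative-mass individuals can arise. The cost of a
#' seed to its parent equals the seed size.
#'
#' @param mean mean seed size (g).
#' @param sd standard deviation of seed size (g); `0` gives degenerate
#'   (fixed-size) seeds.
#' @param floor smallest admissible seed size (g); draws at or below it
#'   are redrawn.
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(mean = 0.5, sd = 0.05, floor = 0.05) {
  if (!(mean > 0) || sd < 0 || floor < 0)
    stop("seed spec requires mean > 0, sd >= 0, floor >= 0")
  if (mean <= floor)
    stop("seed size mean must exceed the truncation floor")
  structure(list(mean = mean, sd = sd, floor = floor), class = "seed_spec")
}

#' Draw truncated seed sizes
#'
#' @param n number of sizes to draw.
#' @param spec a [seed_spec()].
#' @return Numeric vector of `n` seed sizes, all `> spec$floor`.
#' @export
draw_seed_size <- function(n, spec = seed_spec()) {
  x <- stats::rnorm(n, spec$mean, spec$sd)
  bad <- x <= spec$floor
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), spec$mean, spec$sd)
    bad <- x <= spec$floor
  }
  x
}

#' Polyploid formation parameters
#'
#' Each reproducing diploid converts each of its seeds to a tetraploid
#' independently with a parent-specific probability drawn once per
#' reproduction event from a Beta distribution (defaults: shape 2 and 40,
#' mean 2/42 = 0.0476 — zero-inflated, occasionally large). The `regime`
#' controls when formation operates: at every season (`recurrent`,
#' default), only in the first season (`single_season`), in the first ten
#' seasons (`burst_10_seasons`), or never (`off`). `rate_scale` thins every
#' drawn probability multiplicatively (e.g. `0.5` halves the mean
#' formation rate from 4.76% to 2.38%).
#'
#' @param alpha,beta Beta shape parameters, both positive.
#' @param regime one of `"recurrent"`, `"single_season"`,
#'   `"burst_10_seasons"`, `"off"`.
#' @param rate_scale multiplicative thinning of drawn probabilities, in
#'   \code{[0, 1]}.
#' @return An object of class `formation_spec`.
#' @export
formation_spec <- function(alpha = 2, beta = 40,
                           regime = c("recurrent", "single_season",
                                      "burst_10_seasons", "off"),
                           rate_scale = 1) {
  regime <- match.arg(regime)
  if (!(alpha > 0 && beta > 0))
    stop("Beta shape parameters must be positive")
  if (rate_scale < 0 || rate_scale > 1)
    stop("`rate_scale` must lie in [0, 1]")
  structure(list(alpha = alpha, beta = beta, regime = regime,
                 rate_scale = rate_scale),
            class = "formation_spec")
}

#' Is polyploid formation active in a given season?
#'
#' @param formation a [formation_spec()].
#' @param season 1-based season index.
#' @return Logical.
#' @export
formation_active <- function(formation, season) {
  switch(formation$regime,
         recurrent = TRUE,
         single_season = season == 1L,
         burst_10_seasons = season <= 10L,
         off = FALSE)
}

#' Draw per-parent polyploid formation probabilities
#'
#' Returns `n` draws from `Beta(alpha, beta)` scaled by `rate_scale`, or
#' zeros when the regime is inactive for `season`.
#'
#' @param formation a [formation_spec()].
#' @param season 1-based season index (determines regime activity).
#' @param n number of draws (one per reproducing diploid parent).
#' @return Numeric vector of probabilities in \code{[0, 1]}.
#' @export
draw_formation_probability <- function(formation, season = 1L, n = 1L) {
  if (!formation_active(formation, season)) return(rep(0, n))
  pmin(1, formation$rate_scale * stats::rbeta(n, formation$alpha, formation$beta))
}

#' End-of-season seed production
#'
#' Converts a parent's accumulated reproductive energy budget (REB) into
#' seeds. Candidate seed sizes are drawn sequentially from the seed-size
#' distribution; each affordable draw (REB >= size) becomes a seed and its
#' cost is deducted, and production stops at the first unaffordable draw.
#' A diploid parent that produced at least one seed draws its formation
#' probability `p` once (see [draw_formation_probability()]) and each of
#' its seeds is tetraploid independently with probability `p`; tetraploid
#' parents produce only tetraploid seeds.
#'
#' @param individual a list or one-row data frame with numeric `reb` and
#'   integer `ploidy` (2 or 4).
#' @param spec a [seed_spec()].
#' @param formation a [formation_spec()].
#' @param season 1-based season index.
#' @return A list: `seeds` (data frame with columns `mass`, `ploidy`),
#'   `reb` (residual REB after production), `reproduced` (`TRUE` iff at
#'   least one seed), `p_formation` (the parent's drawn probability, `NA`
#'   for tetraploids or non-reproducers).
#' @export
produce_seeds <- function(individual, spec = seed_spec(),
                          formation = formation_spec(), season = 1L) {
  reb <- individual$reb
  ploidy <- as.integer(individual$ploidy)
  stopifnot(length(reb) == 1L, reb >= 0, ploidy %in% c(2L, 4L))
  sizes <- numeric(0L)
  repeat {
    s <- draw_seed_size(1L, spec)
    if (reb < s) break
    reb <- reb - s
    sizes <- c(sizes, s)
  }
  k <- length(sizes)
  p <- NA_real_
  if (ploidy == 2L && k > 0L) {
    p <- draw_formation_probability(formation, season, 1L)
    tet <- stats::runif(k) < p
  } else {
    tet <- rep(ploidy == 4L, k)
  }
  list(seeds = data.frame(mass = sizes, ploidy = ifelse(tet, 4L, 2L)),
       reb = reb,
       reproduced = k > 0L,
       p_formation = p)
}

#' Nearest-neighbor seed dispersal
#'
#' Places each seed uniformly at random in one of the parent cell's
#' adjacent cells (no dispersal cost: seed mass is unchanged). Vectorized
#' over seeds; `parent_cell` is recycled against `n`.
#'
#' @param env a [lattice_env()] object.
#' @param parent_cell cell index (or vector of indices) of the parents.
#' @param n number of seeds to place (default: `length(parent_cell)`).
#' @return Integer vector of destination cell indices.
#' @export
disperse_seed <- function(env, parent_cell, n = length(parent_cell)) {
  stopifnot(inherits(env, "nutrient_lattice"))
  parent_cell <- rep_len(as.integer(parent_cell), n)
  if (any(parent_cell < 1L) || any(parent_cell > env$L^2))
    stop("parent cell index out of grid")
  nn <- env$n_nbr[parent_cell]
  j <- 1L + as.integer(floor(stats::runif(n) * nn))
  env$nbr[cbind(parent_cell, j)]
}

#' End-of-season mortality
#'
#' Annuals die at the end of every growing season regardless of
#' reproductive success. The species is semelparous, so any individual
#' that reproduced dies as well; only perennials that failed to reproduce
#' survive into the next season.
#'
#' @param strategy character vector, `"annual"` or `"perennial"`.
#' @param reproduced logical vector: produced at least one seed this
#'   season.
#' @return Logical vector: `TRUE` for individuals alive next season.
#' @export
end_of_season_mortality <- function(strategy, reproduced) {
  stopifnot(all(strategy %in% c("annual", "perennial")),
            length(strategy) == length(reproduced))
  strategy == "perennial" & !reproduced
}

#' Life-history strategy of a cytotype under a scenario
#'
#' Deterministic mapping from ploidy to life history: `all_annual` and
#' `all_perennial` assign the same strategy to both cytotypes;
#' `tetraploid_perennial` makes diploids annual and tetraploids perennial
#' (whole-genome duplication coinciding with a shift to perenniality).
#'
#' @param ploidy integer vector of 2s and 4s.
#' @param scenario one of `"all_annual"`, `"all_perennial"`,
#'   `"tetraploid_perennial"`.
#' @return Character vector, `"annual"` or `"perennial"`.
#' @export
assign_strategy <- function(ploidy,
                            scenario = c("all_annual", "all_perennial",
                                         "tetraploid_perennial")) {
  scenario <- match.arg(scenario)
  stopifnot(all(ploidy %in% c(2L, 4L)))
  switch(scenario,
         all_annual = rep("annual", length(ploidy)),
         all_perennial = rep("perennial", length(ploidy)),
         tetraploid_perennial = ifelse(ploidy == 4L, "perennial", "annual"))
}
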