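#' Simulation configuration
#'
#' Collects every free parameter of a run, with the study defaults. All
#' parameters are validated together; violations are reported as one
#' aggregated error.
#'
#' Nutrient parameters `r` and `Rmax` set the emergent carrying capacity.
#' Their defaults were fixed once by the documented calibration procedure
#' (tune so the all-annual, diploid-only equilibrium population on the
#' 40 x 40 lattice is of order 800 individuals; see the package vignette)
#' and are exposed here, never hard-coded.
#'
#' @param L lattice side length (cells).
#' @param r daily nutrient replenishment (g/day/cell).
#' @param Rmax nutrient cap (g/cell).
#' @param boundary `"torus"` or `"clipped"` (see [lattice_env()]).
#' @param neighborhood `"moore"` or `"von_neumann"`.
#' @param QM,kQM,theta photosynthesis parameters (see [photo_params()]).
#' @param base_allocation reference BMR:SOMA:REB fractions (diploid).
#' @param reduction tetraploid metabolic-efficiency reduction, in
#'   \code{[0, 1]} (0.10 = the 37:54:9 profile; the study sweeps 0-0.10).
#' @param seed_mean,seed_sd,seed_floor seed-size distribution (g), see
#'   [seed_spec()].
#' @param formation_alpha,formation_beta Beta shapes of the polyploid
#'   formation probability.
#' @param formation_regime `"recurrent"`, `"single_season"`,
#'   `"burst_10_seasons"` or `"off"`.
#' @param formation_scale multiplicative thinning of formation draws.
#' @param scenario life-history scenario: `"all_annual"`,
#'   `"all_perennial"` or `"tetraploid_perennial"`.
#' @param season_length growing-season length in days.
#' @param run_length total run length in days; must be a whole number of
#'   seasons.
#' @param initial_seeds number of founding diploid seeds (default 1600,
#'   an average density of one per cell at `L = 40`).
#' @param replicates default replicate count for [run_replicates()].
#' @param seed master RNG seed.
#' @param germination_delay days after birth during which a seed is
#'   metabolically dormant (consumes nothing, loses nothing); the study
#'   default is 0 (seeds are active from their first day).
#' @param service_order within-cell consumption order: a fresh uniform
#'   random permutation per cell per day (`"random"`, default) or largest
#'   plants first (`"size_desc"`, for sensitivity analysis).
#' @param reset_reb_on_season if `TRUE`, perennials that failed to
#'   reproduce forfeit their residual REB at the season boundary; the
#'   default (`FALSE`) carries it over (energy reserves accumulate over
#'   seasons).
#' @param invasion_threshold,extinction_threshold tetraploid-proportion
#'   cutoffs used by [classify_outcome()].
#' @param classify_window,capacity_window window lengths (seasons) for
#'   outcome classification and carrying-capacity estimation.
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(L = 40L,
                       r = 9,
                       Rmax = 30,
                       boundary = c("torus", "clipped"),
                       neighborhood = c("moore", "von_neumann"),
                       QM = 32.8, kQM = 1.06, theta = 0.94,
                       base_allocation = c(bmr = 0.36, soma = 0.54, reb = 0.10),
                       reduction = 0,
                       seed_mean = 0.5, seed_sd = 0.05, seed_floor = 0.05,
                       formation_alpha = 2, formation_beta = 40,
                       formation_regime = c("recurrent", "single_season",
                                            "burst_10_seasons", "off"),
                       formation_scale = 1,
                       scenario = c("all_annual", "all_perennial",
                                    "tetraploid_perennial"),
                       season_length = 100L,
                       run_length = 10000L,
                       initial_seeds = 1600L,
                       replicates = 10L,
                       seed = 1L,
                       germination_delay = 0L,
                       service_order = c("random", "size_desc"),
                       allocation_rule = c("priority", "bmr_first_shared"),
                       reset_reb_on_season = FALSE,
                       invasion_threshold = 0.95,
                       extinction_threshold = 0.05,
                       classify_window = 10L,
                       capacity_window = 20L) {
  cfg <- list(
    L = as.integer(L), r = r, Rmax = Rmax,
    boundary = match.arg(boundary),
    neighborhood = match.arg(neighborhood),
    QM = QM, kQM = kQM, theta = theta,
    base_allocation = if (length(base_allocation) == 3L)
      stats::setNames(as.numeric(base_allocation), c("bmr", "soma", "reb"))
    else base_allocation,
    reduction = reduction,
    seed_mean = seed_mean, seed_sd = seed_sd, seed_floor = seed_floor,
    formation_alpha = formation_alpha, formation_beta = formation_beta,
    formation_regime = match.arg(formation_regime),
    formation_scale = formation_scale,
    scenario = match.arg(scenario),
    season_length = as.integer(season_length),
    run_length = as.integer(run_length),
    initial_seeds = as.integer(initial_seeds),
    replicates = as.integer(replicates),
    seed = as.integer(seed),
    germination_delay = as.integer(germination_delay),
    service_order = match.arg(service_order),
    allocation_rule = match.arg(allocation_rule),
    reset_reb_on_season = isTRUE(reset_reb_on_season),
    invasion_threshold = invasion_threshold,
    extinction_threshold = extinction_threshold,
    classify_window = as.integer(classify_window),
    capacity_window = as.integer(capacity_window)
  )
  class(cfg) <- "sim_config"
  errs <- validate_config(cfg)
  if (length(errs))
    stop("invalid simulation configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every constraint and returns all violations at once (an empty
#' character vector means the configuration is valid).
#'
#' @param cfg a `sim_config`-like list.
#' @return Character vector of violation messages.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs[[length(errs) + 1L]] <<- msg
  chk(is.numeric(cfg$L) && length(cfg$L) == 1L && cfg$L >= 1,
      "L must be a single integer >= 1")
  chk(is.numeric(cfg$r) && cfg$r >= 0, "replenishment rate r must be >= 0")
  chk(is.numeric(cfg$Rmax) && cfg$Rmax > 0, "nutrient cap Rmax must be > 0")
  chk(cfg$boundary %in% c("torus", "clipped"), "unknown boundary mode")
  chk(cfg$neighborhood %in% c("moore", "von_neumann"), "unknown neighborhood")
  chk(cfg$QM > 0 && cfg$kQM > 0 && cfg$theta > 0,
      "photosynthesis parameters QM, kQM, theta must be positive")
  chk(length(cfg$base_allocation) == 3L &&
        all(cfg$base_allocation >= 0) && all(cfg$base_allocation <= 1) &&
        abs(sum(cfg$base_allocation) - 1) <= 1e-12,
      "base_allocation must be three fractions in [0, 1] summing to 1")
  chk(is.numeric(cfg$reduction) && cfg$reduction >= 0 && cfg$reduction <= 1,
      "reduction must lie in [0, 1] (REB fraction cannot go negative)")
  chk(cfg$seed_sd >= 0, "seed_sd must be >= 0")
  chk(cfg$seed_floor >= 0, "seed_floor must be >= 0")
  chk(cfg$seed_mean > cfg$seed_floor, "seed_mean must exceed seed_floor")
  chk(cfg$formation_alpha > 0 && cfg$formation_beta > 0,
      "formation Beta shapes must be positive")
  chk(cfg$formation_scale >= 0 && cfg$formation_scale <= 1,
      "formation_scale must lie in [0, 1]")
  chk(cfg$scenario %in% c("all_annual", "all_perennial",
                          "tetraploid_perennial"),
      "unknown life-history scenario")
  chk(cfg$season_length >= 1, "season_length must be >= 1 day")
  chk(cfg$run_length >= 0, "run_length must be >= 0 days")
  chk(cfg$run_length %% cfg$season_length == 0,
      "run_length must be a whole number of seasons")
  chk(cfg$initial_seeds >= 1, "initial_seeds must be >= 1")
  chk(cfg$replicates >= 1, "replicates must be >= 1")
  chk(!is.na(cfg$seed), "rng seed must be an integer")
  chk(cfg$germination_delay >= 0, "germination_delay must be >= 0")
  chk(cfg$service_order %in% c("random", "size_desc"),
      "unknown service_order")
  chk(cfg$allocation_rule %in% c("priority", "bmr_first_shared"),
      "unknown allocation_rule")
  chk(cfg$invasion_threshold > 0 && cfg$invasion_threshold <= 1,
      "invasion_threshold must lie in (0, 1]")
  chk(cfg$extinction_threshold >= 0 &&
        cfg$extinction_threshold < cfg$invasion_threshold,
      "extinction_threshold must be >= 0 and below invasion_threshold")
  chk(cfg$classify_window >= 1, "classify_window must be >= 1 season")
  chk(cfg$capacity_window >= 1, "capacity_window must be >= 1 season")
  errs
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  lattice: %d x %d, r = %g g/day, Rmax = %g g/cell (%s, %s)\n",
              x$L, x$L, x$r, x$Rmax, x$boundary, x$neighborhood))
  cat(sprintf("  photosynthesis: QM = %g, kQM = %g, theta = %g\n",
              x$QM, x$kQM, x$theta))
  cat(sprintf("  allocation: %g:%g:%g, tetraploid reduction = %g%%\n",
              100 * x$base_allocation[[1]], 100 * x$base_allocation[[2]],
              100 * x$base_allocation[[3]], 100 * x$reduction))
  cat(sprintf("  formation: Beta(%g, %g) x %g, regime %s\n",
              x$formation_alpha, x$formation_beta, x$formation_scale,
              x$formation_regime))
  cat(sprintf("  scenario: %s; %d-day seasons, %d days, %d founder seeds\n",
              x$scenario, x$season_length, x$run_length, x$initial_seeds))
  cat(sprintf("  seed: %d, replicates: %d\n", x$seed, x$replicates))
  invisible(x)
}

# columns of the per-day trajectory record
DAY_COLS <- c("day", "season", "n", "n_diploid", "n_tetraploid",
              "n_tetraploid_from_diploid", "mean_mass_diploid",
              "mean_mass_tetraploid", "mean_reb_diploid",
              "mean_reb_tetraploid", "nutrients", "nutrients_post_replenish",
              "consumed", "starved", "recruits")

day_record <- function(day, season, pop, env, post_replenish, consumed,
                       starved, recruits) {
  tet <- pop$ploidy == 4L
  ntet <- sum(tet)
  ndip <- nrow(pop) - ntet
  c(day = day, season = season,
    n = nrow(pop), n_diploid = ndip, n_tetraploid = ntet,
    n_tetraploid_from_diploid = sum(tet & pop$from_dip),
    mean_mass_diploid = if (ndip) mean(pop$mass[!tet]) else NA_real_,
    mean_mass_tetraploid = if (ntet) mean(pop$mass[tet]) else NA_real_,
    mean_reb_diploid = if (ndip) mean(pop$reb[!tet]) else NA_real_,
    mean_reb_tetraploid = if (ntet) mean(pop$reb[tet]) else NA_real_,
    nutrients = sum(env$stock),
    nutrients_post_replenish = post_replenish,
    consumed = consumed, starved = starved, recruits = recruits)
}

#' Initialize a simulation state
#'
#' Creates the founding population: `initial_seeds` diploid seeds with
#' masses drawn from the seed-size distribution, placed uniformly at
#' random over the lattice (multiple occupants per cell allowed — an
#' average density of one per cell at the defaults), on a lattice whose
#' cells all start at the nutrient cap. Uses the current RNG state; seed
#' the RNG first (as [sim_run()] does) for reproducibility.
#'
#' @param config a [sim_config()].
#' @return A `sim_state` list: `day`, `env`, `pop` (individual table with
#'   columns `id`, `ploidy`, `mass`, `reb`, `age`, `perennial`, `cell`,
#'   `from_dip`), `next_id`, plus precomputed parameter objects.
#' @export
sim_init <- function(config) {
  errs <- validate_config(config)
  if (length(errs))
    stop("invalid simulation configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  env <- lattice_env(config$L, config$r, config$Rmax,
                     config$boundary, config$neighborhood)
  sspec <- seed_spec(config$seed_mean, config$seed_sd, config$seed_floor)
  n0 <- config$initial_seeds
  pop <- data.frame(
    id = seq_len(n0),
    ploidy = rep(2L, n0),
    mass = draw_seed_size(n0, sspec),
    reb = rep(0, n0),
    age = rep(0L, n0),
    perennial = assign_strategy(rep(2L, n0), config$scenario) == "perennial",
    cell = sample.int(env$L^2, n0, replace = TRUE),
    from_dip = rep(FALSE, n0)
  )
  state <- list(
    day = 0L,
    env = env,
    pop = pop,
    next_id = n0 + 1L,
    config = config,
    photo = photo_params(config$QM, config$kQM, config$theta),
    seedspec = sspec,
    formation = formation_spec(config$formation_alpha, config$formation_beta,
                               config$formation_regime,
                               config$formation_scale),
    prof_dip = allocation_profile(0, config$base_allocation),
    prof_tet = allocation_profile(config$reduction, config$base_allocation),
    last_day = day_record(0L, 0L, pop, env, NA_real_, 0, 0L, n0),
    last_season = NULL
  )
  class(state) <- "sim_state"
  state
}

#' Advance the simulation by one day
#'
#' The daily schedule: (1) replenish every cell; (2) serve each cell's
#' occupants in a fresh random order under contest competition, then
#' allocate the granted energy by BMR > SOMA > REB priority and update
#' mass/REB; (3) remove starvation deaths; (4) increment ages; (5) at a
#' season boundary, run the season phase (seed production, dispersal,
#' end-of-season mortality, recruitment — newborns first metabolize the
#' following day); (6) record the day's summary in `state$last_day` (and
#' `state$last_season` at boundaries).
#'
#' @param state a `sim_state` from [sim_init()].
#' @return The advanced state.
#' @export
sim_step_day <- function(state) {
  cfg <- state$config
  env <- state$env
  pop <- state$pop
  env$stock <- pmin(env$stock + env$r, env$Rmax)
  post_replenish <- sum(env$stock)
  n <- nrow(pop)
  consumed <- 0
  starved <- 0L
  if (n > 0L) {
    Q <- photosynthetic_demand(pop$mass, state$photo)
    demand <- if (cfg$germination_delay > 0L)
      ifelse(pop$age >= cfg$germination_delay, Q, 0) else Q
    # within-cell service order
    perm <- sample.int(n)  # random tie-breaking in either order
    o <- if (cfg$service_order == "random") {
      perm[order(pop$cell[perm], method = "radix")]
    } else {
      perm[order(pop$cell[perm], -pop$mass[perm], method = "radix")]
    }
    cells_o <- pop$cell[o]
    d_o <- demand[o]
    # contest competition: granted_i = min(d_i, max(0, stock - demand before))
    cs <- cumsum(d_o)
    first <- !duplicated(cells_o)
    grp <- cumsum(first)
    start_cs <- (cs - d_o)[first]
    before <- cs - d_o - start_cs[grp]
    stock_g <- env$stock[cells_o[first]]
    g_o <- pmin(d_o, pmax(0, stock_g[grp] - before))
    env$stock[cells_o[first]] <- stock_g - rowsum(g_o, grp, reorder = FALSE)[, 1L]
    granted <- numeric(n)
    granted[o] <- g_o
    consumed <- sum(g_o)
    # priority allocation, vectorized over both cytotype profiles
    tet <- pop$ploidy == 4L
    bmrF <- ifelse(tet, state$prof_tet[["bmr"]], state$prof_dip[["bmr"]])
    somaF <- ifelse(tet, state$prof_tet[["soma"]], state$prof_dip[["soma"]])
    rebF <- ifelse(tet, state$prof_tet[["reb"]], state$prof_dip[["reb"]])
    B <- bmrF * demand
    bmr_spent <- pmin(granted, B)
    rem <- granted - bmr_spent
    if (cfg$allocation_rule == "priority") {
      soma_gain <- pmin(rem, somaF * demand)
      reb_gain <- pmin(rem - soma_gain, rebF * demand)
    } else {  # bmr_first_shared: SOMA and REB funded pro-rata after BMR
      rest <- (somaF + rebF) * demand
      frac <- ifelse(rest > 0, pmin(rem / rest, 1), 0)
      soma_gain <- frac * somaF * demand
      reb_gain <- rem - soma_gain
    }
    pop$mass <- pop$mass + soma_gain - (B - bmr_spent)
    pop$reb <- pop$reb + reb_gain
    dead <- pop$mass <= 0
    if (any(dead)) {
      starved <- sum(dead)
      pop <- pop[!dead, , drop = FALSE]
    }
  }
  if (nrow(pop) > 0L) pop$age <- pop$age + 1L
  day <- state$day + 1L
  recruits <- 0L
  state$last_season <- NULL
  if (day %% cfg$season_length == 0L) {
    sp <- season_phase(pop, env, state, day %/% cfg$season_length)
    pop <- sp$pop
    state$next_id <- sp$next_id
    state$last_season <- sp$record
    recruits <- sp$recruits
  }
  state$env <- env
  state$pop <- pop
  state$day <- day
  state$last_day <- day_record(day, (day - 1L) %/% cfg$season_length + 1L,
                               pop, env, post_replenish, consumed, starved,
                               recruits)
  state
}

# End-of-season phase: reproduction -> dispersal -> mortality ->
# recruitment. Returns the surviving + recruited population and a season
# record (summary fields plus per-individual detail used by observers).
season_phase <- function(pop, env, state, season) {
  cfg <- state$config
  n <- nrow(pop)
  n_end <- n
  active <- formation_active(state$formation, season)
  seed_mass <- vector("list", n)
  seed_tet <- vector("list", n)
  nseeds <- integer(n)
  reb_res <- pop$reb
  sspec <- state$seedspec
  for (i in seq_len(n)) {
    reb <- pop$reb[i]
    sizes <- numeric(0L)
    repeat {
      s <- draw_seed_size(1L, sspec)
      if (reb < s) break
      reb <- reb - s
      sizes <- c(sizes, s)
    }
    k <- length(sizes)
    if (k > 0L) {
      if (pop$ploidy[i] == 2L) {
        p <- if (active)
          min(1, state$formation$rate_scale *
                stats::rbeta(1L, state$formation$alpha, state$formation$beta))
        else 0
        tetflag <- stats::runif(k) < p
      } else {
        tetflag <- rep(TRUE, k)
      }
      seed_mass[[i]] <- sizes
      seed_tet[[i]] <- tetflag
      nseeds[i] <- k
      reb_res[i] <- reb
    }
  }
  reproduced <- nseeds > 0L
  strategy <- ifelse(pop$perennial, "perennial", "annual")
  survives <- end_of_season_mortality(strategy, reproduced)
  # season detail snapshot (pre-mortality), used by age/mass observers
  detail <- data.frame(
    id = pop$id, ploidy = pop$ploidy,
    age_seasons = pop$age %/% cfg$season_length,
    mass = pop$mass, reb = pop$reb,
    perennial = pop$perennial,
    from_dip = pop$from_dip,
    reproduced = reproduced, n_seeds = nseeds,
    n_tet_seeds = vapply(seed_tet, sum, 0L)
  )
  survivors <- pop[survives, , drop = FALSE]
  if (nrow(survivors) > 0L) {
    survivors$reb <- if (cfg$reset_reb_on_season) 0 else reb_res[survives]
  }
  # recruitment with nearest-neighbor dispersal
  m <- sum(nseeds)
  if (m > 0L) {
    parent_idx <- rep.int(seq_len(n), nseeds)
    smass <- unlist(seed_mass[nseeds > 0L], use.names = FALSE)
    stet <- unlist(seed_tet[nseeds > 0L], use.names = FALSE)
    ploidy <- ifelse(stet, 4L, 2L)
    dest <- disperse_seed(env, pop$cell[parent_idx], m)
    recruits_df <- data.frame(
      id = seq.int(state$next_id, length.out = m),
      ploidy = ploidy,
      mass = smass,
      reb = rep(0, m),
      age = rep(0L, m),
      perennial = assign_strategy(ploidy, cfg$scenario) == "perennial",
      cell = dest,
      from_dip = pop$ploidy[parent_idx] == 2L
    )
    pop2 <- rbind(survivors, recruits_df)
  } else {
    pop2 <- survivors
  }
  tet_end <- detail$ploidy == 4L
  record <- list(
    season = season,
    n_start = nrow(pop2),
    n_end = n_end,
    n_diploid_end = sum(!tet_end),
    n_tetraploid_end = sum(tet_end),
    n_repro = sum(reproduced),
    n_repro_diploid = sum(reproduced & !tet_end),
    n_repro_tetraploid = sum(reproduced & tet_end),
    seeds = m,
    seeds_tetraploid = sum(detail$n_tet_seeds),
    mean_age_end = if (n_end) mean(detail$age_seasons) else NA_real_,
    max_age_end = if (n_end) max(detail$age_seasons) else NA_real_,
    mean_age_repro = if (any(reproduced))
      mean(detail$age_seasons[reproduced]) else NA_real_,
    self_sufficiency = if (any(tet_end))
      mean(!detail$from_dip[tet_end]) else NA_real_,
    detail = detail
  )
  list(pop = pop2, next_id = state$next_id + m, recruits = m,
       record = record)
}

empty_seasons_df <- function() {
  data.frame(season = integer(0), n_start = integer(0), n_end = integer(0),
             n_diploid_end = integer(0), n_tetraploid_end = integer(0),
             n_repro = integer(0), n_repro_diploid = integer(0),
             n_repro_tetraploid = integer(0), seeds = integer(0),
             seeds_tetraploid = integer(0), mean_age_end = numeric(0),
             max_age_end = numeric(0), mean_age_repro = numeric(0),
             self_sufficiency = numeric(0))
}

#' Run a full simulation
#'
#' Seeds the RNG from `config$seed`, initializes the state and advances it
#' `run_length` days. The result is a pure function of the configuration:
#' the same config yields bit-identical trajectories.
#'
#' @param config a [sim_config()].
#' @return An object of class `ploidy_trajectory`: a list with `config`,
#'   `daily` (one data-frame row per day, including day 0), `seasons`
#'   (per-season summary data frame), `season_details` (list of
#'   per-season individual snapshots taken just before reproduction), and
#'   `final` (the final population table).
#' @export
sim_run <- function(config) {
  set.seed(config$seed)
  state <- sim_init(config)
  ndays <- config$run_length
  nseasons <- ndays %/% config$season_length
  daily <- matrix(NA_real_, ndays + 1L, length(DAY_COLS),
                  dimnames = list(NULL, DAY_COLS))
  daily[1L, ] <- state$last_day
  seasons <- vector("list", nseasons)
  details <- vector("list", nseasons)
  for (t in seq_len(ndays)) {
    state <- sim_step_day(state)
    daily[t + 1L, ] <- state$last_day
    if (!is.null(state$last_season)) {
      rec <- state$last_season
      details[[rec$season]] <- rec$detail
      rec$detail <- NULL
      seasons[[rec$season]] <- as.data.frame(rec)
    }
  }
  seasons_df <- if (nseasons > 0L) do.call(rbind, seasons) else
    empty_seasons_df()
  structure(
    list(config = config,
         daily = as.data.frame(daily),
         seasons = seasons_df,
         season_details = details,
         final = state$pop,
         final_env = state$env),
    class = "ploidy_trajectory"
  )
}

#' @export
print.ploidy_trajectory <- function(x, ...) {
  nd <- nrow(x$daily) - 1L
  last <- x$daily[nrow(x$daily), ]
  cat(sprintf("<ploidy_trajectory> %d days (%d seasons), scenario %s\n",
              nd, nrow(x$seasons), x$config$scenario))
  cat(sprintf("  final population: %d (%d diploid, %d tetraploid)\n",
              last$n, last$n_diploid, last$n_tetraploid))
  cat(sprintf("  tetraploid efficiency reduction: %g%%; formation: %s\n",
              100 * x$config$reduction, x$config$formation_regime))
  invisible(x)
}

#' Derive a replicate's child seed from the master seed
#'
#' A small multiplicative-congruential hash keeping seeds in the 32-bit
#' integer range; distinct replicate indices give distinct, reproducible
#' streams.
#'
#' @param master master seed (integer).
#' @param k replicate index (>= 1).
#' @return An integer seed.
#' @export
child_seed <- function(master, k) {
  m <- 2147483647
  a <- (as.numeric(master) %% m) * 48271 %% m
  s <- (a + as.numeric(k) * 69621 + 12345) %% m
  as.integer(if (s == 0) 1 else s)
}

#' Run independent replicates
#'
#' Replicate `k` runs with the deterministically derived seed
#' `child_seed(config$seed, k)`, so any replicate can be reproduced alone.
#'
#' @param config a [sim_config()].
#' @param n_replicates number of replicates (default `config$replicates`).
#' @return A list of `ploidy_trajectory` objects.
#' @export
run_replicates <- function(config, n_replicates = config$replicates) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates), function(k) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, k)
    sim_run(cfg)
  })
}
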