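#' Tetraploid proportion
#'
#' Fraction of tetraploids in the population, defined as 0 when the
#' population is empty.
#'
#' @param n_tetraploid tetraploid count(s).
#' @param n_total total count(s).
#' @return Numeric proportion(s) in \code{[0, 1]}.
#' @export
tetraploid_proportion <- function(n_tetraploid, n_total) {
  ifelse(n_total > 0, n_tetraploid / n_total, 0)
}

# mean daily tetraploid proportion over the final `window_seasons` seasons
final_window_proportion <- function(trajectory, window_seasons) {
  cfg <- trajectory$config
  ndays <- nrow(trajectory$daily) - 1L
  wdays <- window_seasons * cfg$season_length
  if (wdays > ndays)
    stop("trajectory shorter than the classification window")
  d <- trajectory$daily[(ndays - wdays + 2L):(ndays + 1L), ]
  mean(tetraploid_proportion(d$n_tetraploid, d$n))
}

#' Classify the outcome of a run
#'
#' Uses the mean daily tetraploid proportion over the final
#' `window_seasons` seasons: at or above the invasion threshold (default
#' 0.95) the tetraploids have taken over (`invasion`); at or below the
#' extinction threshold (default 0.05) they are absent or nearly so
#' (`extinction_of_tetraploids`); anything in between is `coexistence`.
#' An empty final population is `extinction_of_all`. The thresholds
#' operationalize the visual grey-zone classification of the study and
#' are exposed in the configuration.
#'
#' @param trajectory a `ploidy_trajectory` from [sim_run()].
#' @param window_seasons classification window (seasons); defaults to the
#'   run's `classify_window`.
#' @param invasion_threshold,extinction_threshold proportion cutoffs;
#'   default to the run's configuration.
#' @return An object of class `ploidy_outcome`: a list with `label`,
#'   `final_proportion`, and `season` (first season at/above the invasion
#'   threshold, or last season with tetraploids present, where
#'   applicable; otherwise `NA`).
#' @export
classify_outcome <- function(trajectory,
                             window_seasons = trajectory$config$classify_window,
                             invasion_threshold =
                               trajectory$config$invasion_threshold,
                             extinction_threshold =
                               trajectory$config$extinction_threshold) {
  prop <- final_window_proportion(trajectory, window_seasons)
  last <- trajectory$daily[nrow(trajectory$daily), ]
  sprop <- tetraploid_proportion(trajectory$seasons$n_tetraploid_end,
                                 trajectory$seasons$n_end)
  if (last$n == 0) {
    label <- "extinction_of_all"
    season <- trajectory$seasons$season[match(TRUE, trajectory$seasons$n_start == 0)]
  } else if (prop >= invasion_threshold) {
    label <- "invasion"
    season <- trajectory$seasons$season[match(TRUE, sprop >= invasion_threshold)]
  } else if (prop <= extinction_threshold) {
    label <- "extinction_of_tetraploids"
    w <- which(trajectory$seasons$n_tetraploid_end > 0)
    season <- if (length(w)) trajectory$seasons$season[max(w)] else NA_integer_
  } else {
    label <- "coexistence"
    season <- NA_integer_
  }
  structure(list(label = label, final_proportion = prop,
                 season = if (length(season)) season else NA_integer_),
            class = "ploidy_outcome")
}

#' @export
print.ploidy_outcome <- function(x, ...) {
  cat(sprintf("<ploidy_outcome> %s (final-window tetraploid proportion %.3f)\n",
              x$label, x$final_proportion))
  invisible(x)
}

#' Estimate the carrying capacity of a run
#'
#' The equilibrium population size: the mean daily population over the
#' final `window_seasons` seasons (the flat level visible in population
#' time series), with the between-season standard deviation of the
#' per-season daily means. The mean season-start count (survivors plus
#' the freshly recruited seed cohort) is returned as `season_start`; it
#' is dominated by the seed rain and therefore not used as the capacity
#' itself.
#'
#' @param trajectory a `ploidy_trajectory`.
#' @param window_seasons averaging window (seasons); defaults to the
#'   run's `capacity_window`.
#' @return A list with `capacity`, `sd`, `season_start`,
#'   `window_seasons`.
#' @export
estimate_carrying_capacity <- function(trajectory,
                                       window_seasons =
                                         trajectory$config$capacity_window) {
  s <- trajectory$seasons
  if (window_seasons > nrow(s))
    stop("capacity window longer than the trajectory")
  tail_s <- s$n_start[(nrow(s) - window_seasons + 1L):nrow(s)]
  cfg <- trajectory$config
  ndays <- nrow(trajectory$daily) - 1L
  wdays <- window_seasons * cfg$season_length
  d <- trajectory$daily[(ndays - wdays + 2L):(ndays + 1L), ]
  season_of <- rep(seq_len(window_seasons), each = cfg$season_length)
  per_season <- tapply(d$n, season_of, mean)
  list(capacity = mean(d$n),
       sd = stats::sd(per_season),
       season_start = mean(tail_s),
       window_seasons = window_seasons)
}

#' Mass distribution of a population
#'
#' Histogram of individual masses, filtered by ploidy and/or restricted to
#' the season's successful reproducers. Masses beyond the last break are
#' collected in an overflow bin so the histogram always accounts for every
#' individual.
#'
#' @param trajectory a `ploidy_trajectory`; masses are taken from the last
#'   recorded season snapshot (just before reproduction), or from the
#'   final population if no season completed.
#' @param ploidy `NULL` (all), 2 or 4.
#' @param reproducers_only restrict to individuals that produced seeds in
#'   that season.
#' @param breaks bin edges in grams (default 0-20 g in 0.25 g bins).
#' @return A list with `counts`, `mids`, `breaks`, `n`, and `n_modes`
#'   (number of local maxima whose height exceeds `prominence` times the
#'   tallest bin).
#' @param prominence fraction of the tallest bin a local maximum must
#'   reach to count as a mode.
#' @export
mass_distribution <- function(trajectory, ploidy = NULL,
                              reproducers_only = FALSE,
                              breaks = seq(0, 20, by = 0.25),
                              prominence = 0.1) {
  details <- Filter(Negate(is.null), trajectory$season_details)
  if (length(details)) {
    snap <- details[[length(details)]]
    mass <- snap$mass
    keep <- rep(TRUE, nrow(snap))
    if (!is.null(ploidy)) keep <- keep & snap$ploidy == ploidy
    if (reproducers_only) keep <- keep & snap$reproduced
    mass <- mass[keep]
  } else {
    mass <- trajectory$final$mass
    if (!is.null(ploidy)) mass <- mass[trajectory$final$ploidy == ploidy]
    if (reproducers_only) mass <- numeric(0)
  }
  mass <- as.numeric(mass)
  br <- unique(c(breaks, max(breaks, mass + 1)))
  if (length(mass)) {
    h <- graphics::hist(mass, breaks = br, plot = FALSE)
    counts <- h$counts
    mids <- h$mids
  } else {
    counts <- integer(length(br) - 1L)
    mids <- (br[-1L] + br[-length(br)]) / 2
  }
  n_modes <- 0L
  if (length(counts) && any(counts > 0)) {
    thr <- prominence * max(counts)
    padded <- c(-Inf, counts, -Inf)
    for (i in seq_along(counts)) {
      if (counts[i] > thr && counts[i] >= padded[i] && counts[i] >= padded[i + 2L] &&
          (counts[i] > padded[i] || counts[i] > padded[i + 2L]))
        n_modes <- n_modes + 1L
    }
  }
  list(counts = counts, mids = mids, breaks = br,
       n = length(mass), n_modes = n_modes)
}

#' Mean age, in seasons
#'
#' Average age (whole seasons lived, `floor(age_days / season_length)`)
#' over the final `window_seasons` season snapshots, optionally filtered
#' by ploidy and/or restricted to that season's successful reproducers.
#'
#' @param trajectory a `ploidy_trajectory`.
#' @param ploidy `NULL` (all), 2 or 4.
#' @param reproducers_only average over successful reproducers only.
#' @param window_seasons number of final seasons to pool.
#' @return Mean age in seasons (`NaN` if no matching individuals).
#' @export
age_summary <- function(trajectory, ploidy = NULL, reproducers_only = FALSE,
                        window_seasons = trajectory$config$classify_window) {
  details <- trajectory$season_details
  if (window_seasons > length(details))
    stop("age window longer than the trajectory")
  idx <- (length(details) - window_seasons + 1L):length(details)
  ages <- unlist(lapply(details[idx], function(snap) {
    if (is.null(snap) || nrow(snap) == 0L) return(numeric(0))
    keep <- rep(TRUE, nrow(snap))
    if (!is.null(ploidy)) keep <- keep & snap$ploidy == ploidy
    if (reproducers_only) keep <- keep & snap$reproduced
    snap$age_seasons[keep]
  }), use.names = FALSE)
  mean(ages)
}

#' Metabolic-efficiency sweep
#'
#' The study's central experiment: a full factorial over tetraploid
#' efficiency reductions, life-history scenarios, and replicates. Each
#' run is classified by its final-window tetraploid proportion; the
#' largest reduction whose replicate-mean proportion reaches the invasion
#' threshold is the invasion threshold of the sweep (see
#' [invasion_threshold()]).
#'
#' @param config template [sim_config()]; its `seed` acts as the sweep's
#'   master seed and each run gets a deterministic child seed.
#' @param reductions numeric vector of efficiency reductions (e.g.
#'   `seq(0, 0.10, by = 0.01)`).
#' @param scenarios character vector of life-history scenarios.
#' @param replicates replicates per (reduction, scenario) combination.
#' @return A data frame with one row per run: `scenario`, `reduction`,
#'   `replicate`, `seed`, `final_proportion` (the tetraploid proportion as
#'   the last season closes, just before its reproduction phase — the
#'   proportion after the full run's growing seasons), `outcome` (the
#'   [classify_outcome()] label, which uses the trailing-window mean),
#'   `capacity`, `n_final`.
#' @export
sweep_efficiency <- function(config,
                             reductions = seq(0, 0.10, by = 0.01),
                             scenarios = "all_annual",
                             replicates = 3L) {
  if (length(reductions) == 0L)
    return(data.frame(scenario = character(0), reduction = numeric(0),
                      replicate = integer(0), seed = integer(0),
                      final_proportion = numeric(0), outcome = character(0),
                      capacity = numeric(0), n_final = integer(0)))
  grid <- expand.grid(replicate = seq_len(replicates),
                      reduction = reductions,
                      scenario = scenarios,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$reduction <- grid$reduction[i]
    cfg$scenario <- grid$scenario[i]
    cfg$seed <- child_seed(config$seed, i)
    traj <- sim_run(cfg)
    out <- classify_outcome(traj)
    cap <- tryCatch(estimate_carrying_capacity(traj)$capacity,
                    error = function(e) NA_real_)
    last <- traj$seasons[nrow(traj$seasons), ]
    data.frame(scenario = cfg$scenario,
               reduction = cfg$reduction,
               replicate = grid$replicate[i],
               seed = cfg$seed,
               final_proportion = tetraploid_proportion(
                 last$n_tetraploid_end, last$n_end),
               outcome = out$label,
               capacity = cap,
               n_final = traj$daily$n[nrow(traj$daily)])
  })
  do.call(rbind, rows)
}

#' Invasion threshold of a sweep
#'
#' For each scenario, the boundary of the contiguous invasion region: the
#' largest efficiency reduction such that it and every smaller tested
#' reduction have a replicate-mean final-window tetraploid proportion at
#' or above the invasion threshold ("tetraploids take over at reductions
#' of at most X"). `NA` if the smallest tested reduction does not invade.
#'
#' @param sweep a [sweep_efficiency()] result.
#' @param threshold invasion proportion cutoff (default 0.95).
#' @return Named numeric vector (one entry per scenario), in reduction
#'   units (multiply by 100 for percent).
#' @export
invasion_threshold <- function(sweep, threshold = 0.95) {
  vapply(split(sweep, sweep$scenario), function(d) {
    means <- tapply(d$final_proportion, d$reduction, mean)
    means <- means[order(as.numeric(names(means)))]
    below <- which(means < threshold)
    if (length(below) == 0L) return(as.numeric(names(means)[length(means)]))
    if (below[1L] == 1L) return(NA_real_)
    as.numeric(names(means)[below[1L] - 1L])
  }, numeric(1))
}
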