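#' Load a simulation configuration from a YAML file
#'
#' Reads a flat key-value YAML file whose keys are the arguments of
#' [sim_config()]. Omitted keys take the study defaults; unknown keys are
#' an error (to catch typos); constraint violations are reported all at
#' once. An empty file yields the default configuration.
#'
#' @param path path to a YAML file.
#' @return A validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must be a YAML mapping")
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$base_allocation))
    raw$base_allocation <- unlist(raw$base_allocation)
  do.call(sim_config, raw)
}

#' Write a configuration to a YAML file
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config a [sim_config()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$base_allocation <- as.list(as.numeric(x$base_allocation))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write trajectory outputs
#'
#' Writes the per-day trajectory CSV, the per-season summary CSV, the
#' per-season reproduction log CSV (one row per reproducing parent), and
#' a JSON run manifest (full configuration echo, master seed, package
#' version, file listing). Output is deterministic: re-running the same
#' configuration produces byte-identical files.
#'
#' @param trajectory a `ploidy_trajectory` from [sim_run()].
#' @param out_dir output directory (created if absent).
#' @param prefix file-name prefix (default `"run"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(trajectory, out_dir, prefix = "run") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(daily = file.path(out_dir, paste0(prefix, "_daily.csv")),
             seasons = file.path(out_dir, paste0(prefix, "_seasons.csv")),
             reproduction = file.path(out_dir,
                                      paste0(prefix, "_reproduction.csv")),
             manifest = file.path(out_dir, paste0(prefix, "_manifest.json")))
  utils::write.csv(trajectory$daily, paths[["daily"]], row.names = FALSE)
  utils::write.csv(trajectory$seasons, paths[["seasons"]], row.names = FALSE)
  repro <- do.call(rbind, lapply(trajectory$season_details, function(snap) {
    if (is.null(snap)) return(NULL)
    r <- snap[snap$reproduced, c("id", "ploidy", "perennial", "age_seasons",
                                 "mass", "reb", "n_seeds", "n_tet_seeds"),
              drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    r
  }))
  if (is.null(repro))
    repro <- data.frame(id = integer(0), ploidy = integer(0),
                        perennial = logical(0), age_seasons = integer(0),
                        mass = numeric(0), reb = numeric(0),
                        n_seeds = integer(0), n_tet_seeds = integer(0))
  utils::write.csv(repro, paths[["reproduction"]], row.names = FALSE)
  manifest <- list(config = unclass(trajectory$config),
                   master_seed = trajectory$config$seed,
                   package_version = as.character(
                     utils::packageVersion("ploidysim")),
                   files = as.list(basename(paths[-4L])))
  jsonlite::write_json(manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Deterministic micro-scenarios for testing and exploration
#'
#' Returns a tiny configuration plus analytically derived expectations:
#' \describe{
#'   \item{`single_plant_unlimited`}{a 1 x 1 lattice with a nutrient
#'     stock no single plant can exhaust within a season, one diploid of
#'     fixed 1 g seed mass, 100 days. Expected first-day mass gain is
#'     `0.54 * Q(1)` and REB gain `0.10 * Q(1)`.}
#'   \item{`starvation`}{a 1 x 1 lattice with a small initial stock and
#'     zero replenishment; the plant booms briefly, then pays its basal
#'     demand from body mass and dies.}
#'   \item{`two_cell_competition`}{a 2 x 2 lattice, two seeds, limited
#'     daily income: contest competition decides which one booms.}
#'   \item{`formation_off`}{a small lattice with polyploid formation
#'     disabled: the tetraploid count must stay 0 forever.}
#'   \item{`tiny_invasion`}{a small lattice with recurrent formation and
#'     equal efficiencies over 10 seasons; tetraploids should appear and
#'     grow in frequency.}
#' }
#'
#' @param name one of the fixture names above.
#' @return A list with `config` and `expected` (named list; contents vary
#'   per fixture).
#' @export
fixture <- function(name = c("single_plant_unlimited", "starvation",
                             "two_cell_competition", "formation_off",
                             "tiny_invasion")) {
  name <- match.arg(name)
  pp <- photo_params()
  q1 <- photosynthetic_demand(1, pp)
  switch(
    name,
    single_plant_unlimited = list(
      config = sim_config(L = 1, r = 40, Rmax = 1e6,
                          seed_mean = 1, seed_sd = 0, seed_floor = 0.05,
                          formation_regime = "off",
                          season_length = 100, run_length = 100,
                          initial_seeds = 1, seed = 11),
      expected = list(day1_mass = 1 + 0.54 * q1,
                      day1_reb = 0.10 * q1)
    ),
    starvation = list(
      config = sim_config(L = 1, r = 0, Rmax = 40,
                          seed_mean = 1, seed_sd = 0, seed_floor = 0.05,
                          formation_regime = "off",
                          season_length = 100, run_length = 100,
                          initial_seeds = 1, seed = 11),
      expected = list(dies = TRUE)
    ),
    two_cell_competition = list(
      config = sim_config(L = 2, r = 9, Rmax = 30,
                          formation_regime = "off",
                          season_length = 100, run_length = 100,
                          initial_seeds = 2, seed = 11),
      expected = list(max_granted_per_cell_per_day = 30)
    ),
    formation_off = list(
      config = sim_config(L = 8, r = 9, Rmax = 30,
                          formation_regime = "off",
                          season_length = 100, run_length = 1000,
                          initial_seeds = 64, seed = 11),
      expected = list(n_tetraploid = 0)
    ),
    tiny_invasion = list(
      config = sim_config(L = 8, r = 9, Rmax = 30,
                          formation_regime = "recurrent", reduction = 0,
                          season_length = 100, run_length = 1000,
                          initial_seeds = 64, seed = 11),
      expected = list(tetraploids_appear = TRUE)
    )
  )
}
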