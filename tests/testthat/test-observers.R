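# minimal synthetic trajectory: constant daily counts chosen per test
synthetic_traj <- function(n_tet, n_total, seasons = 30, season_len = 10,
                           n_start = NULL) {
  days <- seasons * season_len
  cfg <- sim_config(season_length = season_len, run_length = days,
                    classify_window = 10, capacity_window = 20)
  n_tet <- rep_len(n_tet, days + 1)
  n_total <- rep_len(n_total, days + 1)
  daily <- data.frame(day = 0:days, n = n_total, n_tetraploid = n_tet,
                      n_diploid = n_total - n_tet)
  if (is.null(n_start)) n_start <- n_total[seq_len(seasons) * season_len + 1]
  seasons_df <- data.frame(season = seq_len(seasons),
                           n_start = n_start,
                           n_end = n_total[seq_len(seasons) * season_len],
                           n_tetraploid_end =
                             n_tet[seq_len(seasons) * season_len])
  structure(list(config = cfg, daily = daily, seasons = seasons_df,
                 season_details = vector("list", seasons)),
            class = "ploidy_trajectory")
}

test_that("tetraploid proportion handles the empty population", {
  expect_equal(tetraploid_proportion(0, 800), 0)
  expect_equal(tetraploid_proportion(1200, 1200), 1)
  expect_equal(tetraploid_proportion(300, 1000), 0.3)
  expect_equal(tetraploid_proportion(0, 0), 0)
})

test_that("outcome classification uses the final-window proportion", {
  expect_equal(classify_outcome(synthetic_traj(100, 100))$label, "invasion")
  expect_equal(classify_outcome(synthetic_traj(0, 100))$label,
               "extinction_of_tetraploids")
  mid <- classify_outcome(synthetic_traj(50, 100))
  expect_equal(mid$label, "coexistence")
  expect_equal(mid$final_proportion, 0.5)
  expect_equal(classify_outcome(synthetic_traj(0, 0))$label,
               "extinction_of_all")
  expect_error(classify_outcome(synthetic_traj(1, 10), window_seasons = 99),
               "shorter")
  # prefix-invariance: early history outside the window cannot matter
  tr <- synthetic_traj(c(rep(0, 150), rep(90, 151)), 100)
  expect_equal(classify_outcome(tr)$final_proportion, 0.9)
})

test_that("carrying capacity averages the final window", {
  tr <- synthetic_traj(0, 800)
  cap <- estimate_carrying_capacity(tr)
  expect_equal(cap$capacity, 800)
  expect_equal(cap$sd, 0)
  expect_equal(cap$season_start, 800)
  # alternating seasons average out
  alt <- synthetic_traj(0, 800, n_start = rep(c(700, 900), 15))
  expect_equal(estimate_carrying_capacity(alt)$season_start, 800)
  expect_error(estimate_carrying_capacity(tr, window_seasons = 99), "window")
})

test_that("mass distributions cover every individual and find modes", {
  cfg <- sim_config(L = 6, initial_seeds = 36, run_length = 0)
  tr <- sim_run(cfg)
  md <- mass_distribution(tr)   # founding seeds only: one mode near 0.5 g
  expect_equal(md$n, 36)
  expect_equal(sum(md$counts), 36)
  expect_equal(md$n_modes, 1)
  expect_equal(md$mids[which.max(md$counts)], 0.625, tolerance = 0.25)
  empty <- mass_distribution(synthetic_traj(0, 0))
  expect_equal(empty$n, 0)
  expect_true(all(empty$counts == 0))
})

test_that("age summaries track newborn cohorts and filters", {
  cfg <- sim_config(L = 8, initial_seeds = 64, season_length = 50,
                    run_length = 500, seed = 10)
  tr <- sim_run(cfg)
  a_all <- age_summary(tr, window_seasons = 5)
  expect_gte(a_all, 0)
  a_rep <- age_summary(tr, reproducers_only = TRUE, window_seasons = 5)
  expect_true(is.nan(a_rep) || a_rep >= 1)
  # annuals never exceed one season of age
  expect_true(all(vapply(tr$season_details,
                         function(s) max(s$age_seasons), 0) <= 1))
})

test_that("an empty sweep yields an empty table", {
  sw <- sweep_efficiency(sim_config(), reductions = numeric(0))
  expect_equal(nrow(sw), 0)
  expect_true(all(c("scenario", "reduction", "final_proportion", "outcome")
                  %in% names(sw)))
})

test_that("invasion threshold picks the largest invading reduction", {
  sw <- data.frame(scenario = "all_annual",
                   reduction = rep(c(0, 0.01, 0.02), each = 2),
                   final_proportion = c(1, 1, 0.97, 0.95, 0.5, 0.2))
  expect_equal(unname(invasion_threshold(sw)), 0.01)
  sw$final_proportion <- 0.1
  expect_true(is.na(invasion_threshold(sw)))
})
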