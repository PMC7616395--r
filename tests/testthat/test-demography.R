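test_that("seed production stops at the first unaffordable draw", {
  set.seed(3)
  # empty budget: no seeds, no reproduced flag
  out <- produce_seeds(list(reb = 0, ploidy = 2L))
  expect_equal(nrow(out$seeds), 0)
  expect_false(out$reproduced)
  # degenerate spec (sd = 0): integer-division oracle, 5.0 / 0.5 = 10 seeds
  out10 <- produce_seeds(list(reb = 5, ploidy = 2L),
                         spec = seed_spec(0.5, 0, 0.05),
                         formation = formation_spec(regime = "off"))
  expect_equal(nrow(out10$seeds), 10)
  expect_equal(out10$reb, 0)
  expect_true(out10$reproduced)
})

test_that("seed accounting: REB decrement equals the summed seed masses", {
  set.seed(4)
  for (i in 1:20) {
    reb0 <- runif(1, 0, 6)
    out <- produce_seeds(list(reb = reb0, ploidy = sample(c(2L, 4L), 1)))
    expect_equal(reb0 - out$reb, sum(out$seeds$mass), tolerance = 1e-9)
    expect_true(all(out$seeds$mass > 0.05))
  }
})

test_that("tetraploid parents beget only tetraploid seeds", {
  set.seed(5)
  out <- produce_seeds(list(reb = 10, ploidy = 4L))
  expect_gt(nrow(out$seeds), 0)
  expect_true(all(out$seeds$ploidy == 4L))
  expect_true(is.na(out$p_formation))
})

test_that("formation probability respects regime activity windows", {
  f_rec <- formation_spec(regime = "recurrent")
  f_one <- formation_spec(regime = "single_season")
  f_burst <- formation_spec(regime = "burst_10_seasons")
  f_off <- formation_spec(regime = "off")
  expect_true(formation_active(f_rec, 57))
  expect_true(formation_active(f_one, 1))
  expect_false(formation_active(f_one, 2))
  expect_true(formation_active(f_burst, 10))
  expect_false(formation_active(f_burst, 11))
  expect_equal(draw_formation_probability(f_off, 1, 5), rep(0, 5))
  expect_equal(draw_formation_probability(f_one, 3, 5), rep(0, 5))
  set.seed(6)
  p <- draw_formation_probability(f_rec, 1, 1000)
  expect_true(all(p > 0 & p < 1))            # Beta support
  # halved-rate thinning scales the mean
  f_half <- formation_spec(rate_scale = 0.5)
  set.seed(6)
  p2 <- draw_formation_probability(f_half, 1, 1000)
  expect_equal(p2, p / 2)
})

test_that("expected tetraploid seed fraction matches alpha/(alpha+beta)", {
  set.seed(7)
  tet <- 0L
  tot <- 0L
  for (i in 1:4000) {
    out <- produce_seeds(list(reb = 3, ploidy = 2L))
    tet <- tet + sum(out$seeds$ploidy == 4L)
    tot <- tot + nrow(out$seeds)
  }
  expect_gt(tot, 1e4)
  expect_equal(tet / tot, 2 / 42, tolerance = 0.15)
})

test_that("nearest-neighbor dispersal is uniform over the neighborhood", {
  set.seed(8)
  env <- lattice_env(L = 10, r = 1, Rmax = 10)
  parent <- cell_index(env, 5, 5)
  dest <- disperse_seed(env, parent, 1e4)
  expect_false(any(dest == parent))          # never on the parent cell
  nb <- env$nbr[parent, 1:8]
  expect_true(all(dest %in% nb))
  p <- suppressWarnings(chisq.test(table(factor(dest, levels = nb))))$p.value
  expect_gt(p, 1e-4)                         # consistent with uniform 1/8
  # clipped corner parent: only its 3 in-grid neighbors
  envc <- lattice_env(L = 10, r = 1, Rmax = 10, boundary = "clipped")
  corner <- cell_index(envc, 1, 1)
  destc <- disperse_seed(envc, corner, 500)
  expect_setequal(unique(destc), envc$nbr[corner, 1:3])
})

test_that("end-of-season mortality encodes annuality and semelparity", {
  expect_false(end_of_season_mortality("annual", TRUE))    # die after repro
  expect_false(end_of_season_mortality("annual", FALSE))   # die regardless
  expect_false(end_of_season_mortality("perennial", TRUE)) # semelparous
  expect_true(end_of_season_mortality("perennial", FALSE)) # survives
})

test_that("life-history scenarios map ploidy to strategy deterministically", {
  expect_equal(assign_strategy(4L, "all_annual"), "annual")
  expect_equal(assign_strategy(2L, "all_perennial"), "perennial")
  expect_equal(assign_strategy(2L, "tetraploid_perennial"), "annual")
  expect_equal(assign_strategy(4L, "tetraploid_perennial"), "perennial")
  expect_equal(assign_strategy(c(2L, 4L, 2L), "tetraploid_perennial"),
               c("annual", "perennial", "annual"))
  expect_error(assign_strategy(2L, "mixed_up"))
})

test_that("seed sizes are truncated above the floor by resampling", {
  set.seed(9)
  x <- draw_seed_size(1e4, seed_spec(0.5, 0.05, floor = 0.45))
  expect_true(all(x > 0.45))
  expect_error(seed_spec(0.1, 0.01, floor = 0.2), "exceed")
})
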