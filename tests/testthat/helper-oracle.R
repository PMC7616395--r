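# Independent scalar oracle: one plant in one cell, stepped day by day
# with plain arithmetic (Michaelis-Menten demand, contest grant, strict
# BMR > SOMA > REB priority). Deliberately uses no package internals.
oracle_plant <- function(mass0, days, r, Rmax, stock0 = Rmax,
                         frac = c(0.36, 0.54, 0.10),
                         QM = 32.8, kQM = 1.06, theta = 0.94) {
  m <- mass0
  reb <- 0
  S <- stock0
  rows <- vector("list", days)
  for (d in seq_len(days)) {
    S <- min(S + r, Rmax)
    Q <- QM * m / (kQM + theta * m)
    g <- min(Q, S)
    S <- S - g
    B <- frac[1] * Q
    bs <- min(g, B)
    sg <- min(g - bs, frac[2] * Q)
    rg <- min(g - bs - sg, frac[3] * Q)
    m <- m + sg - (B - bs)
    reb <- reb + rg
    alive <- m > 0
    rows[[d]] <- data.frame(day = d, mass = max(m, 0), reb = reb,
                            alive = alive)
    if (!alive) break
  }
  do.call(rbind, rows)
}

# shared expensive runs, computed once per test session
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- expr
  .sim_cache[[key]]
}

baseline_runs <- function(scenario) {
  cached(paste0("baseline_", scenario), {
    cfg <- sim_config(scenario = scenario, formation_regime = "off",
                      run_length = 4000L, seed = 1L)
    run_replicates(cfg, 3L)
  })
}
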