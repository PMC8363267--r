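test_that("stochastic runs are seed-deterministic and trial machinery enforces seeds", {
  net <- fixture()
  p <- single_pulse_protocol("cAMP", 200, 10, onset_s = 5)
  cfg <- solver_config("tau_leap_adaptive", t_end = 60, seed = 42)
  t1 <- simulate_network(net, p, cfg)
  t2 <- simulate_network(net, p, cfg)
  expect_identical(t1$counts, t2$counts)

  trials <- run_trials(net, p, cfg, seeds = 1:5)
  expect_length(trials, 5)
  pairs <- combn(5, 2)
  distinct <- apply(pairs, 2, function(ij)
    !identical(trials[[ij[1]]]$counts, trials[[ij[2]]]$counts))
  expect_true(all(distinct))
  rerun <- run_trials(net, p, cfg, seeds = 1:5)
  for (i in 1:5) expect_identical(trials[[i]]$counts, rerun[[i]]$counts)
  expect_error(run_trials(net, p, cfg, seeds = c(1, 1, 2)), "distinct")
})

test_that("injections appear on schedule and counts never go negative", {
  net <- fixture()
  p <- single_pulse_protocol("cAMP", 300, 10, onset_s = 20)
  for (m in c("ssa_exact", "tau_leap_adaptive")) {
    tr <- simulate_network(net, p, solver_config(m, t_end = 60, seed = 3))
    camp <- species_conc(tr, "cAMP")
    expect_lt(max(camp[tr$times < 20]), 10)
    expect_gt(max(camp[tr$times >= 21 & tr$times <= 30]), 250)
    expect_true(all(tr$counts >= 0L))
    expect_true(all(tr$counts == floor(tr$counts)))
  }
})

test_that("unstimulated pre-equilibrated fixture stays at its steady state", {
  net <- fixture()
  cfg <- solver_config("tau_leap_adaptive", t_end = 3600,
                       output_interval = 10, seed = 8)
  ss <- run_to_steady_state(net, cfg)
  expect_lt(max(ss$drift), 0.01)
  # fixture basal fixed point: all inputs and effectors off, ppERK at zero
  expect_equal(unname(ss$conc["ppERK"]), 0, tolerance = 1e-9)
  # conserved moieties constant over a further unstimulated run
  tr <- simulate_network(net, NULL, solver_config("ssa_exact", t_end = 500, seed = 2))
  W <- conserved_moieties(net)
  tot <- tr$counts %*% W
  expect_true(all(apply(tot, 2, function(z) diff(range(z))) == 0))
})

test_that("ODE steady state under a sustained cAMP clamp matches the closed-form fixed point", {
  # with cAMP clamped at c, GEFa* = G_tot k_on c / (k_on c + k_off) and
  # ppERK* = E_tot v/(v + k_mkp) with v = k_cat GEFa*
  net <- fixture()
  p <- single_pulse_protocol("cAMP", 500, 600)
  tr <- simulate_network(net, p, solver_config("ode", t_end = 600))
  gefa_star <- 100 * (0.001 * 500) / (0.001 * 500 + 0.1)
  v <- 0.001 * gefa_star
  pperk_star <- 200 * v / (v + 0.1)
  expect_equal(tail(species_conc(tr, "GEFa"), 1), gefa_star, tolerance = 0.05)
  expect_equal(tail(species_conc(tr, "ppERK"), 1), pperk_star, tolerance = 0.05)
})

test_that("ultrasensitive switch turns on with saturating calcium and persists", {
  net <- fixture()
  dur <- 10
  p <- single_pulse_protocol("calcium", 1000, dur, onset_s = 10)
  tr <- simulate_network(net, p, solver_config("ode", t_end = 10 + 11 * dur))
  pc <- species_conc(tr, "pCaMKII")
  after <- tr$times >= 10 + dur
  expect_gt(min(pc[after]), 50)  # above half phosphorylation, 10x beyond input
  # and without input the switch stays off
  tr0 <- simulate_network(net, NULL, solver_config("ode", t_end = 1000))
  expect_lt(max(species_conc(tr0, "pCaMKII")), 1e-6)
  expect_lt(max(species_conc(tr0, "ppERK")), 1e-6)
})

test_that("tau-leap agrees with exact SSA in distribution on the fixture", {
  net <- fixture()
  p <- single_pulse_protocol("cAMP", 200, 5, onset_s = 5)
  endpoint <- function(method, seeds) {
    sapply(seeds, function(s) {
      tr <- simulate_network(net, p, solver_config(method, t_end = 40, seed = s))
      tr$counts[nrow(tr$counts), ]
    })
  }
  ssa <- endpoint("ssa_exact", 1:50)
  tau <- endpoint("tau_leap_adaptive", 101:150)
  for (sp in c("cAMP", "GEFa", "ppERK", "ERK")) {
    i <- match(sp, fixture()$species$name)
    se <- sqrt(var(ssa[i, ]) / 50 + var(tau[i, ]) / 50)
    expect_lt(abs(mean(ssa[i, ]) - mean(tau[i, ])), 3 * se + 1e-9)
  }
})

test_that("steady-state drift failure reports the worst species", {
  # a pure-production network never settles: A -> A + B
  net <- reaction_network(
    data.frame(name = c("A", "B"), initial_nM = c(100, 0)),
    data.frame(label = "K_make", reactants = "A", products = "A + B", kf = 1),
    volume = 4)
  expect_error(run_to_steady_state(net, solver_config("ode", t_end = 3600,
                                                      output_interval = 10)),
               "worst species 'B'")
})
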