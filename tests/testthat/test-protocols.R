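test_that("single pulses encode peak and duration; zero duration is empty", {
  p <- single_pulse_protocol("calcium", 500, 30)
  expect_equal(nrow(p$injections), 1)
  expect_equal(p$injections$target_nM, 500)
  expect_equal(p$injections$duration_s, 30)

  p0 <- single_pulse_protocol("calcium", 500, 0)
  expect_equal(nrow(p0$injections), 0)
  # and an empty protocol simulates identically to no protocol
  net <- fixture()
  cfg <- solver_config("ssa_exact", t_end = 50, seed = 4)
  expect_identical(simulate_network(net, p0, cfg)$counts,
                   simulate_network(net, NULL, cfg)$counts)

  expect_error(single_pulse_protocol("glutamate", 1, 1), "unknown input")
  expect_error(single_pulse_protocol("cAMP", -5, 1), "> 0")
})

test_that("total injected exposure scales with pulse duration and count", {
  p4 <- single_pulse_protocol("cAMP", 100, 4)
  p1 <- single_pulse_protocol("cAMP", 100, 1)
  exposure <- function(p) sum(p$injections$duration_s * p$injections$target_nM)
  expect_equal(exposure(p4) / exposure(p1), 4)
  # train exposure is linear in the number of trains
  l2 <- lltp_protocol(20, c(cAMP = 500), n_trains = 2)
  l4 <- lltp_protocol(20, c(cAMP = 500), n_trains = 4)
  expect_equal(exposure(l4) / exposure(l2), 2)
})

test_that("L-LTP train schedule arithmetic matches the protocol definition", {
  p <- lltp_protocol(3, c(calcium = 1000))
  inj <- p$injections
  expect_equal(nrow(inj), 400)  # 4 trains x 100 pulses
  expect_equal(max(inj$onset_s), 3 * (1 + 3) + 0.99)
  expect_true(all(diff(inj$onset_s) >= 0))

  p300 <- lltp_protocol(300, c(calcium = 1000))
  span <- max(p300$injections$onset_s + p300$injections$duration_s)
  expect_equal(span, 3 * 301 + 1)

  expect_error(lltp_protocol(50, c(calcium = 1000)), "3, 20, 40, 80, 300")

  # co-scheduled inputs share identical pulse timing
  pc <- lltp_protocol(80, c(calcium = 1000, cAMP = 500, Gibg = 100))
  byspecies <- split(pc$injections$onset_s, pc$injections$species)
  expect_length(byspecies, 3)
  expect_equal(byspecies$cAMP, byspecies$calcium)
  expect_equal(byspecies$Gibg, byspecies$calcium)
})

test_that("validation protocols are exactly the two stated stimulations", {
  vp <- validation_protocols()
  expect_named(vp, c("rasgtp_uncaging", "llp_2x100Hz"))
  u <- vp$rasgtp_uncaging$injections
  expect_equal(nrow(u), 1)
  expect_equal(u$target_nM, 500)
  expect_equal(u$duration_s, 60)
  l <- vp$llp_2x100Hz$injections
  expect_setequal(unique(l$species), c("calcium", "cAMP", "Gibg"))
  peaks <- tapply(l$target_nM, l$species, unique)
  expect_equal(peaks[["calcium"]], 5000)
  expect_equal(peaks[["cAMP"]], 1000)
  expect_equal(peaks[["Gibg"]], 100)
  # two trains separated by 20 s: second train starts at 21 s
  ca <- sort(l$onset_s[l$species == "calcium"])
  expect_equal(min(ca), 0)
  expect_equal(ca[101], 21)
  # protocol invariants hold
  expect_true(all(diff(l$onset_s) >= 0))
  expect_true(all(l$target_nM > 0))
})

test_that("file-based time series load, validate, and drive the model", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 10, 20), species = "cAMP",
                       value_nM = c(0, 200, 0)), f, row.names = FALSE)
  p <- load_timeseries_protocol(f)
  expect_s3_class(p, "protocol")
  expect_identical(p$source, "file")
  tr <- simulate_network(fixture(), p, solver_config("ode", t_end = 40))
  camp <- species_conc(tr, "cAMP")
  expect_gt(max(camp[tr$times >= 10 & tr$times < 20]), 150)
  expect_lt(camp[tr$times == 5], 1)

  # constant-zero series equals the unstimulated control
  f0 <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 100), species = "calcium",
                       value_nM = 0), f0, row.names = FALSE)
  p0 <- load_timeseries_protocol(f0)
  cfg <- solver_config("ssa_exact", t_end = 100, seed = 9)
  expect_identical(simulate_network(fixture(), p0, cfg)$counts,
                   simulate_network(fixture(), NULL, cfg)$counts)

  fbad <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 10, 5), species = "cAMP",
                       value_nM = c(0, 1, 2)), fbad, row.names = FALSE)
  expect_error(load_timeseries_protocol(fbad), "non-monotone")
})
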