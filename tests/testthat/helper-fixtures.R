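# shared helpers for the suite

fixture <- function(volume = 4) build_fixture_network(volume = volume)

# hand-built trajectory object for analysis-stage tests
make_traj <- function(times, conc_list) {
  conc <- do.call(cbind, conc_list)
  colnames(conc) <- names(conc_list)
  structure(list(times = times, counts = NULL, conc = conc,
                 species = names(conc_list), volume = 4, method = "ode",
                 seed = NA_integer_, protocol_id = "synthetic"),
            class = "trajectory")
}

# a tiny two-reaction toy network: A + B <-> C, C -> D
toy_network <- function() {
  reaction_network(
    species = data.frame(name = c("A", "B", "C", "D"),
                         initial_nM = c(100, 50, 0, 0)),
    reactions = data.frame(label = c("K_bind", "K_conv"),
                           reactants = c("A + B", "C"),
                           products = c("C", "D"),
                           kf = c(0.01, 0.1), kr = c(0.1, NA)),
    volume = 4)
}

# mean relative RMS deviation of a stochastic mean trajectory from the ODE
rel_rms <- function(mean_conc, ode_conc) {
  vapply(colnames(ode_conc), function(s) {
    o <- ode_conc[, s]
    m <- max(abs(o))
    if (m == 0) {
      if (max(abs(mean_conc[, s])) > 0) Inf else 0
    } else sqrt(mean((mean_conc[, s] - o)^2)) / m
  }, numeric(1))
}
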