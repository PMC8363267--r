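#' Solver configuration
#'
#' @param method `"tau_leap_adaptive"` (default; adaptive tau-leaping with a
#'   bounded relative propensity change per leap and exact stepping for
#'   small-population species), `"ssa_exact"` (Gillespie direct method), or
#'   `"ode"` (deterministic mass-action, stiff integrator, the large-volume
#'   oracle).
#' @param leap_tolerance bound on the relative propensity change per leap
#'   (default 0.1).
#' @param seed integer RNG seed; with the same network, protocol, config and
#'   seed a stochastic trajectory is bit-identical.
#' @param output_interval output grid spacing in s (default 1).
#' @param t_end end time in s.
#' @param rtol relative tolerance of the ODE integrator (default 1e-8).
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(method = c("tau_leap_adaptive", "ssa_exact", "ode"),
                          leap_tolerance = 0.1, seed = 1L,
                          output_interval = 1, t_end = 600, rtol = 1e-8) {
  method <- match.arg(method)
  if (leap_tolerance <= 0) stop("leap_tolerance must be > 0")
  if (output_interval <= 0) stop("output_interval must be > 0")
  if (t_end <= 0) stop("t_end must be > 0")
  structure(list(method = method, leap_tolerance = leap_tolerance,
                 seed = as.integer(seed), output_interval = output_interval,
                 t_end = t_end, rtol = rtol),
            class = "solver_config")
}

# compile network + protocol into the arrays the engines consume
.compile_sim <- function(net, prot, cfg, x0_counts = NULL, x0_nM = NULL) {
  st <- .stoich(net)
  seg <- .protocol_segments(prot, cfg$t_end)
  nseg <- length(seg$breaks) - 1
  sp <- st$species
  RS <- st$RS; NS <- st$NS
  kdet <- matrix(rep(st$k, nseg), ncol = nseg)  # nM/s-consistent constants
  labels <- st$labels
  if (!is.null(seg$clamp)) {
    for (spn in names(seg$clamp)) {
      i <- match(spn, sp)
      if (is.na(i)) stop("protocol references species '", spn,
                         "' not in the network")
      src <- rep(0L, length(sp)); src[i] <- 1L
      RS <- rbind(RS, 0L, deparse.level = 0)      # source: no reactants
      NS <- rbind(NS, src, deparse.level = 0)
      RS <- rbind(RS, src, deparse.level = 0)     # sink: first order in sp
      NS <- rbind(NS, -src, deparse.level = 0)
      kdet <- rbind(kdet, seg$clamp[[spn]]$source_nM_s,
                    seg$clamp[[spn]]$sink_per_s, deparse.level = 0)
      labels <- c(labels, paste0("clamp_src_", spn), paste0("clamp_snk_", spn))
    }
  }
  order_tot <- rowSums(RS)
  homodimer <- apply(RS, 1, function(r) any(r == 2))
  om <- .omega(net$volume)
  # deterministic k -> stochastic propensity constant c
  cconv <- ifelse(order_tot == 0, om,
                  ifelse(order_tot == 1, 1,
                         ifelse(homodimer, 2 / om, 1 / om)))
  cstoch <- kdet * cconv
  if (is.null(x0_nM)) x0_nM <- setNames(net$species$initial_nM, sp)
  if (is.null(x0_counts)) x0_counts <- concentration_to_count(x0_nM, net$volume)
  list(species = sp, RS = RS, NS = NS, kdet = kdet, cstoch = cstoch,
       breaks = seg$breaks, labels = labels, omega = om,
       x0_counts = as.integer(x0_counts), x0_nM = as.numeric(x0_nM))
}

.ode_run <- function(comp, out_times, rtol) {
  RS <- comp$RS; NS <- comp$NS
  nseg <- length(comp$breaks) - 1
  deriv <- function(t, y, parms) {
    k <- parms
    r <- k
    for (j in seq_len(nrow(RS))) {
      idx <- which(RS[j, ] > 0)
      for (i in idx) r[j] <- r[j] * y[i]^RS[j, i]
    }
    list(as.numeric(crossprod(NS, r)))
  }
  y <- comp$x0_nM
  res <- matrix(NA_real_, length(out_times), length(y))
  for (s in seq_len(nseg)) {
    t0 <- comp$breaks[s]; t1 <- comp$breaks[s + 1]
    sel <- which(out_times > t0 + 1e-12 & out_times <= t1 + 1e-12)
    tt <- unique(c(t0, out_times[sel], t1))
    sol <- deSolve::lsoda(y, tt, deriv, parms = comp$kdet[, s],
                          rtol = rtol, atol = 1e-10)
    if (length(sel))
      res[sel, ] <- sol[match(out_times[sel], sol[, 1]), -1, drop = FALSE]
    y <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
  }
  if (length(out_times) && out_times[1] <= 1e-12) res[1, ] <- comp$x0_nM
  res
}

#' Simulate a reaction network under a stimulation protocol
#'
#' Propagates the network from its initial amounts with the exact stochastic
#' simulation algorithm, the adaptive tau-leap accelerator, or the
#' deterministic mass-action ODE oracle. Stimulation enters as fast clamp
#' windows on the free input species (see [protocol()]).
#'
#' @param net a `reaction_network`.
#' @param protocol a [protocol()] or `NULL` for an unstimulated run.
#' @param config a [solver_config()].
#' @param x0 optional named vector of initial amounts in nM overriding the
#'   network's initial concentrations (e.g. a pre-equilibrated steady state).
#' @return an object of class `trajectory` with fields `times` (s), `counts`
#'   (integer matrix, stochastic methods only), `conc` (nM matrix), `species`,
#'   and metadata (`method`, `seed`, `protocol_id`, `volume`).
#' @export
simulate_network <- function(net, protocol = NULL, config = solver_config(),
                             x0 = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  if (!is.null(protocol)) stopifnot(inherits(protocol, "protocol"))
  cfg <- config
  comp <- .compile_sim(net, protocol, cfg, x0_nM = x0)
  out_times <- seq(0, cfg$t_end, by = cfg$output_interval)
  if (cfg$method == "ode") {
    conc <- .ode_run(comp, out_times, cfg$rtol)
    counts <- NULL
  } else {
    set.seed(cfg$seed)
    counts <- if (cfg$method == "ssa_exact")
      sim_ssa_cpp(comp$x0_counts, comp$RS, comp$NS, comp$cstoch,
                  comp$breaks, out_times)
    else
      sim_tau_cpp(comp$x0_counts, comp$RS, comp$NS, comp$cstoch,
                  comp$breaks, out_times, cfg$leap_tolerance, 10L)
    conc <- counts / comp$omega
  }
  colnames(conc) <- comp$species
  if (!is.null(counts)) colnames(counts) <- comp$species
  structure(list(times = out_times, counts = counts, conc = conc,
                 species = comp$species, volume = net$volume,
                 method = cfg$method, seed = cfg$seed,
                 protocol_id = if (is.null(protocol)) "none" else protocol$id),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points over [0, ",
      max(x$times), "] s, ", length(x$species), " species, method ",
      x$method, ", protocol ", x$protocol_id, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_s = rep(x$times, length(x$species)),
             species = rep(x$species, each = length(x$times)),
             value_nM = as.numeric(x$conc),
             stringsAsFactors = FALSE)
}

#' @export
plot.trajectory <- function(x, species = NULL, ...) {
  sel <- if (is.null(species)) x$species else species
  graphics::matplot(x$times, x$conc[, sel, drop = FALSE], type = "l", lty = 1,
                    xlab = "time (s)", ylab = "concentration (nM)", ...)
  graphics::legend("topright", legend = sel, lty = 1,
                   col = seq_along(sel), bty = "n", cex = 0.8)
  invisible(x)
}

#' Extract one species' time course
#'
#' @param traj a `trajectory`.
#' @param species species name.
#' @return numeric vector of concentrations (nM) on the trajectory grid.
#' @export
species_conc <- function(traj, species) {
  if (!species %in% traj$species) stop("no species '", species, "' in trajectory")
  traj$conc[, species]
}

#' Relax a network to its unstimulated steady state
#'
#' Simulates without stimulation for at least an hour of model time and
#' checks that the per-species mean over the final 600 s window differs from
#' the preceding 600 s window by less than a relative drift threshold.
#'
#' @param net a `reaction_network`.
#' @param config a [solver_config()]; `t_end` is raised to 3600 s if lower.
#' @param drift_threshold maximum relative change between the two final 600 s
#'   windows (default 0.01).
#' @return an object of class `steady_state` with fields `conc` (named nM
#'   vector), `counts` (stochastic methods), `drift`, and the final-window
#'   trajectory.
#' @export
run_to_steady_state <- function(net, config = solver_config(t_end = 3600),
                                drift_threshold = 0.01) {
  cfg <- config
  if (cfg$t_end < 3600) cfg$t_end <- 3600
  traj <- simulate_network(net, NULL, cfg)
  w2 <- traj$times > cfg$t_end - 600
  w1 <- traj$times > cfg$t_end - 1200 & !w2
  m1 <- colMeans(traj$conc[w1, , drop = FALSE])
  m2 <- colMeans(traj$conc[w2, , drop = FALSE])
  # denominator floored at one molecule to keep near-empty species from
  # dominating the relative drift
  floor_nM <- 1 / .omega(net$volume)
  drift <- abs(m2 - m1) / pmax(abs(m1), floor_nM)
  if (max(drift) >= drift_threshold)
    stop("steady state not reached: worst species '",
         names(which.max(drift)), "' drift ", signif(max(drift), 3))
  conc <- m2
  structure(list(conc = conc,
                 counts = concentration_to_count(conc, net$volume),
                 drift = drift, method = cfg$method),
            class = "steady_state")
}

#' Run repeated stochastic trials
#'
#' Repeats a simulation with different seeds (default five, matching the
#' study's trial count); trials are otherwise identical.
#'
#' @param net a `reaction_network`.
#' @param protocol a [protocol()] or `NULL`.
#' @param config a [solver_config()]; its seed is replaced per trial.
#' @param seeds integer seeds, one per trial (must be distinct).
#' @param x0 optional initial amounts (nM) passed to [simulate_network()].
#' @return list of `trajectory` objects.
#' @export
run_trials <- function(net, protocol, config = solver_config(),
                       seeds = 2021:2025, x0 = NULL) {
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    simulate_network(net, protocol, cfg, x0 = x0)
  })
}

#' Export a trajectory as flat CSV
#'
#' Long format, one row per (time, species): columns `time_s`, `species`,
#' `value_nM`, plus metadata columns `method`, `seed`, `protocol`.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  d <- as.data.frame(traj)
  d$method <- traj$method; d$seed <- traj$seed; d$protocol <- traj$protocol_id
  write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
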