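#' Single-pathway stimulation grids
#'
#' The duration and amplitude scan grids for each input: amplitude scans use
#' 1 s pulses of varying peak; duration scans hold a fixed peak (0.5 uM
#' calcium, 0.1/0.5 uM cAMP, 0.03/0.1 uM Gibg) for varying durations.
#'
#' @param input `"calcium"`, `"cAMP"`, or `"Gibg"`.
#' @param type `"duration"` or `"amplitude"`.
#' @return list with `values` (the grid), `fixed` (the held quantity in nM or
#'   s) and `type`.
#' @export
table_grid <- function(input = c("calcium", "cAMP", "Gibg"),
                       type = c("duration", "amplitude")) {
  input <- match.arg(input); type <- match.arg(type)
  grids <- list(
    calcium = list(amplitude = c(200, 300, 500, 1000, 1500, 2000, 5000),
                   duration = c(1, 2, 4, 5, 6, 8, 10, 30, 100),
                   duration_peak = 500),
    cAMP = list(amplitude = c(100, 200, 500, 1000, 1500, 2000),
                duration = c(1, 4, 10, 30, 100), duration_peak = 500),
    Gibg = list(amplitude = c(5, 30, 100, 500),
                duration = c(1, 4, 10, 30, 100), duration_peak = 100))
  g <- grids[[input]]
  if (type == "duration")
    list(values = g$duration, fixed = g$duration_peak, type = "duration")
  else
    list(values = g$amplitude, fixed = 1, type = "amplitude")
}

.default_seeds <- c(2021L, 2022L, 2023L, 2024L, 2025L)

# run one protocol for several seeds and summarize a readout
.auc_trials <- function(net, prot, cfg, seeds, species, stim_onset) {
  trials <- run_trials(net, prot, cfg, seeds = seeds)
  vapply(trials, function(tr)
    auc_above_basal(tr, species, stim_onset = stim_onset)$auc, numeric(1))
}

#' Model validation runs against published experiments
#'
#' Replays the two validation protocols (60 s 0.5 uM calcium uncaging
#' surrogate; two 100 Hz trains with calcium + cAMP + Gibg) and reports the
#' RasGTP time course and the ppERK peak timing and return to basal. These
#' comparisons are defined against the published parameterization only, so
#' fixture networks are refused.
#'
#' @param net a `reaction_network` with published parameterization.
#' @param config a [solver_config()].
#' @param stim_onset pre-stimulus equilibration offset in s (default 300).
#' @return an `experiment_result` list with per-protocol summaries.
#' @export
run_validation_suite <- function(net, config = solver_config(t_end = 3600),
                                 stim_onset = 300) {
  if (identical(attr(net, "parameterization"), "fixture"))
    stop("validation suite compares against published quantities and ",
         "refuses fixture networks")
  prots <- validation_protocols()
  out <- lapply(prots, function(p) {
    p$injections$onset_s <- p$injections$onset_s + stim_onset
    traj <- simulate_network(net, p, config)
    res <- list(trajectory = traj)
    if ("ppERK" %in% traj$species)
      res$ppERK <- auc_above_basal(traj, "ppERK", stim_onset = stim_onset)
    if ("RasGTP" %in% traj$species)
      res$RasGTP <- auc_above_basal(traj, "RasGTP", stim_onset = stim_onset)
    res
  })
  structure(list(name = "validation", results = out),
            class = "experiment_result")
}

#' Single-pathway dose-response scan
#'
#' Runs the duration or amplitude grid for one input (optionally under a
#' knockout), summarizes ppERK AUC over repeated trials, and fits/classifies
#' the dose-response per the linear/log/Hill selection rule.
#'
#' @param net a `reaction_network`.
#' @param input input species name.
#' @param type `"duration"` or `"amplitude"`.
#' @param grid optional override of the scan grid values.
#' @param fixed optional override of the held peak (nM, duration scans) or
#'   pulse duration (s, amplitude scans).
#' @param ko optional [knockout_config()].
#' @param config a [solver_config()]; `t_end` is extended to cover the window.
#' @param seeds trial seeds (default 5 trials).
#' @param species readout species (default ppERK).
#' @param stim_onset pre-stimulus equilibration in s (default 300).
#' @param post_window analysis window after stimulation end in s.
#' @return an `experiment_result` with the tidy AUC table (`x`, `seed`,
#'   `auc`) and the `dose_response_fit`.
#' @export
run_single_pathway_scan <- function(net, input, type = "duration",
                                    grid = NULL, fixed = NULL, ko = NULL,
                                    config = solver_config(),
                                    seeds = .default_seeds,
                                    species = "ppERK", stim_onset = 300,
                                    post_window = 600) {
  g <- table_grid(input, type)
  if (!is.null(grid)) g$values <- grid
  if (!is.null(fixed)) g$fixed <- fixed
  if (!is.null(ko)) net <- apply_knockout(net, ko)
  rows <- list()
  for (v in g$values) {
    if (g$type == "duration") { amp <- g$fixed; dur <- v } else { amp <- v; dur <- g$fixed }
    prot <- single_pulse_protocol(input, amp, dur, onset_s = stim_onset)
    cfg <- config
    cfg$t_end <- stim_onset + dur + post_window
    aucs <- .auc_trials(net, prot, cfg, seeds, species, stim_onset)
    rows[[length(rows) + 1L]] <- data.frame(x = v, seed = seeds, auc = aucs)
  }
  tab <- do.call(rbind, rows)
  fit <- fit_dose_response(tab$x, tab$auc)
  structure(list(name = paste0(input, "_", g$type, "_scan"), auc = tab,
                 fit = fit, classification = fit$classification,
                 grid = g, seeds = seeds),
            class = "experiment_result")
}

#' Combination versus summation experiment
#'
#' For each grid point, runs each of two inputs singly and both together with
#' shared seeds, then tests whether the combined ppERK response equals the
#' sum of the single responses by two-way ANCOVA (covariate: the scanned
#' value; factor: combination vs summation).
#'
#' @param net a `reaction_network`.
#' @param input_a,input_b lists `list(species =, amplitude_nM =)`.
#' @param durations numeric vector of shared pulse durations (s).
#' @param config a [solver_config()].
#' @param seeds trial seeds.
#' @param species readout (default ppERK).
#' @param stim_onset pre-stimulus equilibration (s).
#' @param post_window analysis window after stimulation end (s).
#' @return an `experiment_result` with per-condition AUC table, the
#'   `ancova_result` and its verdict.
#' @export
run_combination_suite <- function(net, input_a, input_b, durations,
                                  config = solver_config(),
                                  seeds = .default_seeds, species = "ppERK",
                                  stim_onset = 300, post_window = 600) {
  rows <- list()
  for (dur in durations) {
    cfg <- config
    cfg$t_end <- stim_onset + dur + post_window
    pa <- single_pulse_protocol(input_a$species, input_a$amplitude_nM, dur,
                                onset_s = stim_onset)
    pb <- single_pulse_protocol(input_b$species, input_b$amplitude_nM, dur,
                                onset_s = stim_onset)
    pc <- protocol(rbind(pa$injections, pb$injections),
                   id = paste0("combo_", dur, "s"))
    a <- .auc_trials(net, pa, cfg, seeds, species, stim_onset)
    b <- .auc_trials(net, pb, cfg, seeds, species, stim_onset)
    cc <- .auc_trials(net, pc, cfg, seeds, species, stim_onset)
    rows[[length(rows) + 1L]] <-
      data.frame(x = dur, seed = seeds, auc_a = a, auc_b = b,
                 auc_sum = a + b, auc_combo = cc)
  }
  tab <- do.call(rbind, rows)
  anc <- summation_test(tab$auc_combo, tab$auc_sum, tab$x)
  structure(list(name = paste0(input_a$species, "+", input_b$species,
                               "_combination"),
                 auc = tab, ancova = anc, verdict = anc$verdict,
                 seeds = seeds),
            class = "experiment_result")
}

#' L-LTP intertrain-interval scan
#'
#' Runs the four-train 100 Hz induction protocol across intertrain intervals,
#' summarizes per-ITI AUC of the requested readouts over trials, and reports
#' the temporal sensitivity (max minus min across ITIs) and best ITI of the
#' primary readout. Optional knockout variants are run on the same grid and
#' expressed as percent pathway contributions relative to the intact model.
#'
#' @param net a `reaction_network`.
#' @param inputs named per-pulse peak vector passed to [lltp_protocol()].
#' @param iti_set subset of 3, 20, 40, 80, 300 (all five for the sensitivity
#'   summary).
#' @param variants optional named list of [knockout_config()]s.
#' @param config a [solver_config()].
#' @param seeds trial seeds.
#' @param readouts species to summarize (those present in the network).
#' @param stim_onset pre-stimulus equilibration (s).
#' @param post_window analysis window after the last train (s).
#' @return an `experiment_result` with per-ITI AUC tables, `sensitivity`
#'   (when all five ITIs are present), and per-variant contributions.
#' @export
run_lltp_scan <- function(net, inputs, iti_set = c(3, 20, 40, 80, 300),
                          variants = NULL, config = solver_config(),
                          seeds = .default_seeds,
                          readouts = c("ppERK", "pCaMKII"),
                          stim_onset = 300, post_window = 600) {
  readouts <- intersect(readouts, net$species$name)
  run_one <- function(network) {
    rows <- list()
    for (iti in iti_set) {
      prot <- lltp_protocol(iti, inputs, onset_s = stim_onset)
      span <- 3 * (1 + iti) + 1
      cfg <- config
      cfg$t_end <- stim_onset + span + post_window
      trials <- run_trials(network, prot, cfg, seeds = seeds)
      for (sp in readouts) {
        res <- lapply(trials, auc_above_basal, species = sp,
                      stim_onset = stim_onset)
        rows[[length(rows) + 1L]] <- data.frame(
          iti = iti, species = sp, seed = seeds,
          auc = vapply(res, `[[`, numeric(1), "auc"),
          peak = vapply(res, `[[`, numeric(1), "peak"))
      }
    }
    do.call(rbind, rows)
  }
  tab <- run_one(net)
  sens <- NULL
  if (setequal(iti_set, c(3, 20, 40, 80, 300))) {
    sens <- lapply(readouts, function(sp) {
      m <- with(tab[tab$species == sp, ], tapply(auc, iti, mean))
      temporal_sensitivity(m)
    })
    names(sens) <- readouts
  }
  contributions <- NULL
  if (!is.null(variants)) {
    all_mean <- with(tab[tab$species == "ppERK", ], tapply(auc, iti, mean))
    contributions <- lapply(variants, function(ko) {
      vt <- run_one(apply_knockout(net, ko))
      vm <- with(vt[vt$species == "ppERK", ], tapply(auc, iti, mean))
      100 * vm / all_mean
    })
  }
  structure(list(name = "lltp_scan", auc = tab, sensitivity = sens,
                 contributions = contributions, inputs = inputs,
                 iti_set = iti_set, seeds = seeds),
            class = "experiment_result")
}

#' Parameter-perturbation robustness suite
#'
#' Perturbs molecule initial concentrations by up to a fractional delta
#' (random draws across all molecules, or single-molecule +/- delta), reruns
#' the L-LTP ITI scan per perturbation, and summarizes per-perturbation mean
#' ppERK AUC, temporal sensitivity, and best ITI. The unperturbed control is
#' always row one and is the reference for percent changes. Random mode
#' additionally fits the random-forest importance ranking of the molecule
#' changes.
#'
#' @param net a `reaction_network`.
#' @param inputs named per-pulse peak vector for [lltp_protocol()].
#' @param mode `"random"` (collective uniform draws) or `"single"`
#'   (one molecule at a time, +delta and -delta).
#' @param n_random number of random draws (>= 30 for forest fitting).
#' @param delta maximum fractional change (default 0.1, i.e. +/-10%).
#' @param config a [solver_config()].
#' @param seed seed for the perturbation draws and the simulations.
#' @param molecules species to perturb (default: all non-input species with
#'   non-zero initial amounts).
#' @param stim_onset,post_window analysis window, as in [run_lltp_scan()].
#' @return an object of class `robustness_suite`: the per-perturbation table
#'   (`mean_ppERK`, `sensitivity`, `best_iti`, percent changes), best-ITI
#'   counts, and in random mode the `robustness_result` forest ranking.
#' @export
run_robustness_suite <- function(net, inputs, mode = c("random", "single"),
                                 n_random = 100, delta = 0.1,
                                 config = solver_config(), seed = 2021L,
                                 molecules = NULL,
                                 stim_onset = 300, post_window = 600) {
  mode <- match.arg(mode)
  if (is.null(molecules))
    molecules <- net$species$name[net$species$role != "input" &
                                    net$species$initial_nM > 0]
  set.seed(seed)
  if (mode == "random") {
    if (n_random < 30) stop("need n_random >= 30 for forest fitting")
    P <- matrix(runif(n_random * length(molecules), -delta, delta),
                n_random, length(molecules), dimnames = list(NULL, molecules))
  } else {
    P <- do.call(rbind, lapply(seq_along(molecules), function(i) {
      up <- rep(0, length(molecules)); up[i] <- delta
      rbind(up, -up)
    }))
    colnames(P) <- molecules
  }
  P <- rbind(control = rep(0, length(molecules)), P)
  itis <- c(3, 20, 40, 300, 80)  # order irrelevant; all five required
  run_row <- function(frac) {
    ko <- knockout_config(scale_quantities = setNames(1 + frac, molecules))
    network <- apply_knockout(net, ko)
    m <- numeric(0)
    for (iti in sort(itis)) {
      prot <- lltp_protocol(iti, inputs, onset_s = stim_onset)
      cfg <- config
      cfg$t_end <- stim_onset + 3 * (1 + iti) + 1 + post_window
      cfg$seed <- seed
      traj <- simulate_network(network, prot, cfg)
      m[as.character(iti)] <-
        auc_above_basal(traj, "ppERK", stim_onset = stim_onset)$auc
    }
    ts <- temporal_sensitivity(m)
    c(mean_ppERK = ts$mean, sensitivity = ts$sensitivity,
      best_iti = ts$best_iti)
  }
  res <- t(apply(P, 1, run_row))
  tab <- data.frame(P, res, check.names = FALSE)
  ctrl <- res[1, ]
  tab$pct_change_mean <- 100 * (res[, "mean_ppERK"] - ctrl["mean_ppERK"]) /
    ctrl["mean_ppERK"]
  tab$pct_change_sensitivity <- 100 * (res[, "sensitivity"] -
                                         ctrl["sensitivity"]) / ctrl["sensitivity"]
  counts <- table(factor(res[, "best_iti"], levels = c(3, 20, 40, 80, 300)))
  forest <- NULL
  if (mode == "random")
    forest <- robustness_importance(P[-1, , drop = FALSE],
                                    res[-1, "sensitivity"])
  structure(list(mode = mode, table = tab, best_iti_counts = counts,
                 forest = forest, molecules = molecules, delta = delta,
                 seed = seed),
            class = "robustness_suite")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result '", x$name, "'>\n", sep = "")
  if (!is.null(x$classification)) cat("  classification:", x$classification, "\n")
  if (!is.null(x$verdict)) cat("  verdict:", x$verdict, "\n")
  if (!is.null(x$sensitivity) && !is.null(x$sensitivity$ppERK))
    cat("  ppERK temporal sensitivity:",
        signif(x$sensitivity$ppERK$sensitivity, 4),
        "nM s; best ITI:", x$sensitivity$ppERK$best_iti, "s\n")
  invisible(x)
}

#' @export
print.robustness_suite <- function(x, ...) {
  cat("<robustness_suite> mode:", x$mode, ";",
      nrow(x$table) - 1, "perturbations of", length(x$molecules),
      "molecules\n  best-ITI counts:\n")
  print(x$best_iti_counts)
  if (!is.null(x$forest)) print(x$forest)
  invisible(x)
}

#' Export an experiment's tidy AUC table
#'
#' @param result an `experiment_result`.
#' @param path CSV output path.
#' @export
write_experiment_csv <- function(result, path) {
  write.table(result$auc, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
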