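# default duration grid for dose-response generators (s): the standard
# calcium duration scan at 0.5 uM
.DURATION_GRID <- c(1, 2, 4, 5, 6, 8, 10, 30, 100)

#' Specify a synthetic dataset
#'
#' Declares a seeded generator for pseudo-data with the statistical structure
#' the analysis stage assumes, together with its ground truth, so every
#' statistic is testable without simulation. Noise is multiplicative
#' Gaussian (`sd` expressed as a fraction of the mean), reflecting how
#' trial-to-trial spread of stochastic AUCs scales with signal.
#'
#' Generators:
#' * `hill_dose_response`: `params = list(max, h, n)`, optional `x` grid.
#' * `linear_dose_response`: `params = list(intercept, slope)`, optional `x`.
#' * `ancova_groups`: `params = list(intercept, slope, offset)`; the
#'   combination group mean is the summation mean plus `offset`.
#' * `iti_profile`: `params = list(means)` named by ITI.
#' * `forest_planted`: `params = list(n_obs, features, planted, coef)`;
#'   response depends on the planted feature only.
#'
#' @param generator generator name (see above).
#' @param params list of ground-truth parameters.
#' @param noise_sd fractional noise SD (>= 0).
#' @param n_trials trials per design point (default 5).
#' @param seed integer seed; regeneration with the same spec is bit-identical.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(generator, params = list(), noise_sd = 0,
                           n_trials = 5, seed = 1L) {
  gens <- c("hill_dose_response", "linear_dose_response", "ancova_groups",
            "iti_profile", "forest_planted")
  if (!generator %in% gens)
    stop("unknown generator '", generator, "'; available: ",
         paste(gens, collapse = ", "))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(generator = generator, params = params, noise_sd = noise_sd,
                 n_trials = n_trials, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.mult_noise <- function(mu, frac) mu * (1 + rnorm(length(mu), 0, frac))

#' Generate a synthetic dataset with known ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `data` (schema matching the consuming analysis
#'   operation) and `ground_truth` (the spec's parameters).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  p <- spec$params
  out <- switch(
    spec$generator,
    hill_dose_response = {
      x <- if (!is.null(p$x)) p$x else .DURATION_GRID
      xx <- rep(x, each = spec$n_trials)
      mu <- p$max * xx^p$n / (xx^p$n + p$h^p$n)
      data.frame(x = xx, trial = rep(seq_len(spec$n_trials), length(x)),
                 y = .mult_noise(mu, spec$noise_sd))
    },
    linear_dose_response = {
      x <- if (!is.null(p$x)) p$x else .DURATION_GRID
      xx <- rep(x, each = spec$n_trials)
      mu <- p$intercept + p$slope * xx
      data.frame(x = xx, trial = rep(seq_len(spec$n_trials), length(x)),
                 y = .mult_noise(mu, spec$noise_sd))
    },
    ancova_groups = {
      x <- if (!is.null(p$x)) p$x else .DURATION_GRID
      xx <- rep(x, each = spec$n_trials)
      mu_sum <- p$intercept + p$slope * xx
      mu_combo <- mu_sum + (if (is.null(p$offset)) 0 else p$offset)
      rbind(
        data.frame(x = xx, trial = rep(seq_len(spec$n_trials), length(x)),
                   type = "summation", y = .mult_noise(mu_sum, spec$noise_sd)),
        data.frame(x = xx, trial = rep(seq_len(spec$n_trials), length(x)),
                   type = "combination", y = .mult_noise(mu_combo, spec$noise_sd)))
    },
    iti_profile = {
      means <- unlist(p$means)
      d <- data.frame(iti = rep(as.numeric(names(means)), each = spec$n_trials),
                      trial = rep(seq_len(spec$n_trials), length(means)),
                      y = .mult_noise(rep(means, each = spec$n_trials),
                                      spec$noise_sd))
      d
    },
    forest_planted = {
      n <- if (is.null(p$n_obs)) 50 else p$n_obs
      nf <- if (is.null(p$features)) 8 else p$features
      X <- matrix(runif(n * nf, -0.1, 0.1), n, nf,
                  dimnames = list(NULL, paste0("mol", seq_len(nf))))
      coefp <- if (is.null(p$coef)) 1 else p$coef
      mu <- coefp * X[, p$planted]
      list(X = X, y = mu + rnorm(n, 0, spec$noise_sd * max(abs(mu), 1e-12)))
    })
  list(data = out, ground_truth = p, spec = spec)
}

#' Write synthetic ISO-style input time series
#'
#' Emits CSV time-series files (columns `time_s`, `species`, `value_nM`)
#' qualitatively matching five bath/train stimulation conditions: `ISO`
#' (slow 600 s cAMP bath elevation), `100Hz` (one 1 s high calcium train),
#' `5Hz` (180 s of moderate calcium), and the two combinations. These are
#' synthetic stand-ins constructed by this package, not recordings of any
#' published input; file names carry a `synthetic_` prefix accordingly. Each
#' file loads with [load_timeseries_protocol()].
#'
#' @param dir output directory (created if needed).
#' @param seed seed for the small jitter on the bath ramp.
#' @return named character vector of the five file paths.
#' @export
generate_iso_like_inputs <- function(dir = tempdir(), seed = 1L) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tgrid <- seq(0, 900, by = 5)
  # slow bath: rise over ~120 s, hold ~600 s, decay
  bath <- 400 * pmin(tgrid / 120, 1) * ifelse(tgrid < 720, 1,
                                              exp(-(tgrid - 720) / 60))
  bath <- pmax(bath * (1 + rnorm(length(bath), 0, 0.02)), 0)
  iso_cAMP <- data.frame(time_s = tgrid, species = "cAMP", value_nM = bath)
  zero_ca <- data.frame(time_s = c(0, 900), species = "calcium", value_nM = 0)
  hz100 <- data.frame(time_s = c(0, 300, 301, 900), species = "calcium",
                      value_nM = c(0, 1000, 0, 0))
  hz5 <- data.frame(time_s = c(0, 300, 480, 900), species = "calcium",
                    value_nM = c(0, 300, 0, 0))
  zero_cAMP <- data.frame(time_s = c(0, 900), species = "cAMP", value_nM = 0)
  conds <- list(
    ISO = rbind(iso_cAMP, zero_ca),
    `100Hz` = rbind(zero_cAMP, hz100),
    `5Hz` = rbind(zero_cAMP, hz5),
    `ISO+100Hz` = rbind(iso_cAMP, hz100),
    `ISO+5Hz` = rbind(iso_cAMP, hz5))
  paths <- vapply(names(conds), function(nm) {
    path <- file.path(dir, paste0("synthetic_iso_",
                                  gsub("[^A-Za-z0-9]", "", nm), ".csv"))
    write.table(conds[[nm]], path, sep = ",", quote = FALSE, row.names = FALSE)
    path
  }, "")
  paths
}
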