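test_that("AUC above basal matches closed forms and a quadrature oracle", {
  tt <- seq(0, 1000, by = 1)
  basal <- 5
  # rectangle: +10 nM for 100 s starting at 400
  rect <- ifelse(tt >= 400 & tt < 500, basal + 10, basal)
  tr <- make_traj(tt, list(ppERK = rect))
  res <- auc_above_basal(tr, "ppERK", stim_onset = 400)
  expect_equal(res$basal, basal)
  expect_equal(res$auc, 1000, tolerance = 0.02)  # 10 nM x 100 s
  expect_equal(res$peak, 10)

  # alpha-function transient vs high-resolution quadrature
  t0 <- 400; A <- 40; tau <- 30
  alpha <- function(t) ifelse(t > t0, A * (t - t0) / tau * exp(1 - (t - t0) / tau), 0)
  tr2 <- make_traj(tt, list(ppERK = basal + alpha(tt)))
  res2 <- auc_above_basal(tr2, "ppERK", stim_onset = t0)
  oracle <- integrate(alpha, t0, max(tt), rel.tol = 1e-10)$value
  expect_equal(res2$auc, oracle, tolerance = 1e-3)
  expect_equal(res2$time_to_peak, tau, tolerance = 0.05)

  # unstimulated noise integrates to ~zero
  set.seed(1)
  noise <- basal + rnorm(length(tt), 0, 0.5)
  res3 <- auc_above_basal(make_traj(tt, list(ppERK = noise)), "ppERK",
                          stim_onset = 400)
  # positive-part integral of zero-mean noise ~ sd/sqrt(2*pi)*span
  expect_lt(res3$auc, 0.5 * 600)
  expect_error(auc_above_basal(make_traj(tt, list(ppERK = rect)), "ppERK",
                               stim_onset = 100), "pre-stimulus")
})

test_that("AUC is additive over windows and stable under grid refinement", {
  t0 <- 400; A <- 40; tau <- 30
  alpha <- function(t) ifelse(t > t0, A * (t - t0) / tau * exp(1 - (t - t0) / tau), 0)
  coarse <- seq(0, 1000, by = 2)
  fine <- seq(0, 1000, by = 0.25)
  a_c <- auc_above_basal(make_traj(coarse, list(ppERK = 2 + alpha(coarse))),
                         "ppERK", stim_onset = t0)$auc
  a_f <- auc_above_basal(make_traj(fine, list(ppERK = 2 + alpha(fine))),
                         "ppERK", stim_onset = t0)$auc
  expect_lt(abs(a_c - a_f) / a_f, 0.005)

  tt <- seq(0, 1000, by = 1)
  trj <- make_traj(tt, list(ppERK = 2 + alpha(tt)))
  whole <- auc_above_basal(trj, "ppERK", stim_onset = t0, basal = 2)$auc
  part1 <- auc_above_basal(trj, "ppERK", stim_onset = t0, window_end = 600,
                           basal = 2)$auc
  part2 <- auc_above_basal(trj, "ppERK", stim_onset = 600, basal = 2)$auc
  expect_equal(part1 + part2, whole, tolerance = 1e-9)
})

test_that("dose-response selection recovers exact generating models", {
  x <- rep(c(1, 2, 4, 5, 6, 8, 10, 30, 100), each = 3)
  # exactly linear data
  fit_lin <- fit_dose_response(x, 2 + 3 * x)
  expect_identical(fit_lin$classification, "linear")
  expect_equal(fit_lin$fits$linear$adjusted_r2, 1)
  # noiseless Hill data: parameters back to 4 significant digits
  hill <- function(x, m, h, n) m * x^n / (x^n + h^n)
  fit_h <- fit_dose_response(x, hill(x, 100, 6.7, 2.5))
  expect_identical(fit_h$classification, "non-linear")
  expect_identical(fit_h$best_model, "hill")
  p <- coef(fit_h, "hill")
  expect_equal(unname(p["max"]), 100, tolerance = 1e-4)
  expect_equal(unname(p["half_point"]), 6.7, tolerance = 1e-4)
  expect_equal(unname(p["n"]), 2.5, tolerance = 1e-4)
  # predict() reproduces fitted curve
  expect_equal(predict(fit_h, newdata = c(5, 10)),
               hill(c(5, 10), 100, 6.7, 2.5), tolerance = 1e-3)
})

test_that("linear adjusted R2 >= 0.9 short-circuits the AIC comparison", {
  set.seed(7)
  x <- rep(c(1, 2, 4, 6, 8, 10, 30, 100), each = 5)
  # nearly linear data with slight saturation: hill AIC may win, but the rule
  # classifies linear because the linear adjusted R2 clears 0.9
  y <- hill <- 100 * x^1 / (x^1 + 300) + rnorm(length(x), 0, 0.05)
  fit <- fit_dose_response(x, y)
  expect_gte(fit$fits$linear$adjusted_r2, 0.9)
  expect_identical(fit$classification, "linear")
  expect_identical(fit$best_model, "linear")
  expect_error(fit_dose_response(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
})

test_that("summation ANCOVA returns calibrated verdicts on constructed effects", {
  x <- rep(c(1, 4, 10, 30, 100), each = 5)
  set.seed(11)
  base <- 50 + 2 * x + rnorm(length(x), 0, 5)
  # identical draws: no type effect
  same <- summation_test(base, base, x)
  expect_gt(same$p_type, 0.99)
  expect_identical(same$verdict, "linear")
  # sublinear: combination falls a large constant below the sum
  sub <- summation_test(base - 40, base, x)
  expect_lt(sub$p_type, 0.05)
  expect_identical(sub$verdict, "sublinear")
  # supralinear
  sup <- summation_test(base + 40, base, x)
  expect_identical(sup$verdict, "supralinear")
  expect_error(summation_test(base[-1], base, x), "equal trial counts")
})

test_that("pathway contributions are ratios without renormalization", {
  expect_equal(pathway_contribution(c(a = 100, b = 0), 100),
               c(a = 100, b = 0))
  got <- pathway_contribution(c(a = 60, b = 60), 100)
  expect_equal(unname(got), c(60, 60))
  expect_gt(sum(got), 100)  # documented: sums may exceed 100%
  expect_error(pathway_contribution(c(a = 1), 0), "positive")

  # two fixture branches balanced to equal single responses: ~50% each
  net <- fixture()
  auc_of <- function(prot) {
    tr <- simulate_network(net, prot, solver_config("ode", t_end = 300))
    auc_above_basal(tr, "ppERK", stim_onset = 10, basal = 0)$auc
  }
  pa <- single_pulse_protocol("cAMP", 50, 20, onset_s = 10)
  pb <- single_pulse_protocol("Gibg", 0.73, 20, onset_s = 10)
  a <- auc_of(pa); b <- auc_of(pb)
  ab <- auc_of(protocol(rbind(pa$injections, pb$injections), id = "combo"))
  contrib <- pathway_contribution(c(cAMP = a, Gibg = b), ab)
  expect_equal(unname(contrib), c(50, 50), tolerance = 0.1)
})

test_that("temporal sensitivity summarizes the ITI profile with larger-ITI ties", {
  flat <- setNames(rep(7, 5), c(3, 20, 40, 80, 300))
  expect_equal(temporal_sensitivity(flat)$sensitivity, 0)
  prof <- c(`3` = 10, `20` = 12, `40` = 15, `80` = 30, `300` = 28)
  ts <- temporal_sensitivity(prof)
  expect_equal(ts$sensitivity, 20)
  expect_equal(ts$best_iti, 80)
  tie <- c(`3` = 10, `20` = 30, `40` = 15, `80` = 30, `300` = 20)
  expect_equal(temporal_sensitivity(tie)$best_iti, 80)  # tie -> larger ITI
  tie2 <- c(`3` = 10, `20` = 30, `40` = 15, `80` = 30, `300` = 30)
  expect_equal(temporal_sensitivity(tie2)$best_iti, 300)
  expect_error(temporal_sensitivity(prof[-2]), "missing ITI")
})

test_that("random-forest importance recovers a planted dependence", {
  set.seed(5)
  X <- matrix(runif(200 * 8, -0.1, 0.1), 200, 8,
              dimnames = list(NULL, paste0("m", 1:8)))
  y <- 3 * X[, 4]  # response depends on one molecule only
  r <- robustness_importance(X, y)
  expect_equal(sum(r$weights), 1, tolerance = 1e-9)
  expect_true(all(r$weights >= 0))
  expect_identical(r$ranking[1], "m4")
  expect_gt(r$weights["m4"], 0.5)
  expect_true(all(r$weights[setdiff(names(r$weights), "m4")] < 0.1))
  expect_error(robustness_importance(X, rep(1, nrow(X))), "constant")
  expect_error(robustness_importance(X[1:10, ], y[1:10]), "30")
})
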