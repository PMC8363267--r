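# trapezoidal integral
.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Area under the curve above basal
#'
#' Quantifies total kinase activity as the integral of a species' trajectory
#' above its unstimulated (basal) level: basal is the mean over the
#' pre-stimulus window, and the AUC integrates the positive part of the
#' basal-subtracted signal from stimulation onset to the end of the analysis
#' window.
#'
#' @param traj a `trajectory`.
#' @param species species to summarize (default `"ppERK"`, the doubly
#'   phosphorylated active ERK readout).
#' @param stim_onset stimulation onset time in s. The trajectory must contain
#'   a pre-stimulus window of at least `min_basal_window` s, unless `basal`
#'   is supplied directly.
#' @param window_end end of the integration window (default: trajectory end).
#' @param basal optional known basal level in nM (e.g. from
#'   [run_to_steady_state()]), bypassing the pre-stimulus window requirement.
#' @param min_basal_window minimum pre-stimulus window length in s (default 300).
#' @return an object of class `auc_result`: `auc` (nM s), `basal` (nM),
#'   `peak` (nM above basal), `time_to_peak` (s after onset), `time_to_basal`
#'   (s after onset; first time after the peak at which the signal stays
#'   within 5% of its peak excursion of basal for 60 s; `NA` if unresolved),
#'   and the window.
#' @export
auc_above_basal <- function(traj, species = "ppERK", stim_onset,
                            window_end = NULL, basal = NULL,
                            min_basal_window = 300) {
  y <- species_conc(traj, species)
  tt <- traj$times
  if (is.null(window_end)) window_end <- max(tt)
  if (stim_onset < min(tt) || window_end > max(tt) + 1e-9)
    stop("window [", stim_onset, ", ", window_end, "] outside trajectory span")
  if (is.null(basal)) {
    pre <- tt < stim_onset
    if (stim_onset - min(tt) < min_basal_window)
      stop("no pre-stimulus window of at least ", min_basal_window,
           " s; supply 'basal' explicitly or extend the run")
    basal <- mean(y[pre])
  }
  win <- tt >= stim_onset & tt <= window_end + 1e-9
  sig <- pmax(y[win] - basal, 0)
  tw <- tt[win]
  auc <- .trapz(tw, sig)
  ipk <- which.max(sig)
  peak <- sig[ipk]
  t_peak <- tw[ipk] - stim_onset
  t_basal <- NA_real_
  if (peak > 0) {
    thr <- 0.05 * peak
    below <- abs(y[win] - basal) <= thr
    after <- seq_along(tw) > ipk
    cand <- which(below & after)
    for (i in cand) {
      j <- tw >= tw[i] & tw <= tw[i] + 60
      if (all(abs(y[win][j] - basal) <= thr)) { t_basal <- tw[i] - stim_onset; break }
    }
  }
  structure(list(species = species, auc = auc, basal = basal,
                 window = c(stim_onset, window_end), peak = peak,
                 time_to_peak = t_peak, time_to_basal = t_basal),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat("<auc_result> ", x$species, ": AUC ", signif(x$auc, 5), " nM s above basal ",
      signif(x$basal, 4), " nM; peak ", signif(x$peak, 4),
      " nM at +", signif(x$time_to_peak, 4), " s\n", sep = "")
  invisible(x)
}

# ---- dose-response model selection ----------------------------------------

# AIC convention used throughout: n*ln(RSS/n) + 2k with k = #coefficients + 1
# (the residual variance counts as a parameter). Only comparisons matter.
.aic_rss <- function(n, rss, n_coef) n * log(rss / n) + 2 * (n_coef + 1)

.adj_r2 <- function(y, fitted, n_coef) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)   # degenerate flat response: any model fits exactly
  r2 <- 1 - sum((y - fitted)^2) / tss
  1 - (1 - r2) * (n - 1) / (n - n_coef - 1)
}

#' Fit and classify a dose-response relationship
#'
#' Least-squares fits of three candidate models of AUC versus stimulus
#' duration or concentration: linear `a + b x`, logarithmic
#' `a + b log10(x)`, and Hill `ymax x^n / (x^n + h^n)`. Each fit reports
#' adjusted R-squared and AIC; the response is classified `"linear"` when the
#' linear fit's adjusted R-squared is at least 0.9 (which short-circuits the
#' AIC comparison), and otherwise by the lowest-AIC converged model.
#'
#' The Hill fit is initialized at `ymax = max(y)`, `h` = the x at half-max by
#' interpolation, `n = 2`, with multi-start over `n` in {1, 2, 4} on failure;
#' a non-convergent Hill fit is flagged and excluded from selection.
#'
#' @param x stimulus durations (s) or concentrations (nM); at least 4 distinct
#'   values.
#' @param y response (AUC) per trial, same length as `x` (replicate trials
#'   appear as repeated x values).
#' @param models subset of `c("linear", "log", "hill")`.
#' @return an object of class `dose_response_fit`: per-model parameter
#'   estimates and standard deviations, `adjusted_r2`, `aic`, plus
#'   `classification` (`"linear"` or `"non-linear"`) and `best_model`.
#' @export
fit_dose_response <- function(x, y, models = c("linear", "log", "hill")) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(unique(x)) < 4) stop("need at least 4 distinct x values")
  models <- match.arg(models, several.ok = TRUE)
  n <- length(y)
  fits <- list()
  if ("linear" %in% models) {
    fm <- lm(y ~ x)
    fits$linear <- list(model = "linear",
                        params = coef(fm),
                        param_sd = suppressWarnings(sqrt(diag(vcov(fm)))),
                        adjusted_r2 = .adj_r2(y, fitted(fm), 2),
                        aic = .aic_rss(n, sum(resid(fm)^2), 2),
                        converged = TRUE)
  }
  if ("log" %in% models) {
    if (any(x <= 0)) {
      fits$log <- list(model = "log", converged = FALSE,
                       note = "non-positive x; log model skipped")
    } else {
      fm <- lm(y ~ log10(x))
      fits$log <- list(model = "log",
                       params = coef(fm),
                       param_sd = suppressWarnings(sqrt(diag(vcov(fm)))),
                       adjusted_r2 = .adj_r2(y, fitted(fm), 2),
                       aic = .aic_rss(n, sum(resid(fm)^2), 2),
                       converged = TRUE)
    }
  }
  if ("hill" %in% models) {
    ymax0 <- max(y)
    xo <- order(x)
    h0 <- tryCatch(approx(y[xo], x[xo], xout = ymax0 / 2, ties = mean)$y,
                   error = function(e) NA_real_)
    if (!is.finite(h0) || h0 <= 0) h0 <- stats::median(x)
    hill_try <- function(n0) {
      tryCatch(
        minpack.lm::nlsLM(y ~ ymax * x^nn / (x^nn + h^nn),
                          start = list(ymax = ymax0, h = h0, nn = n0),
                          lower = c(ymax = 0, h = 1e-9, nn = 1e-3),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    }
    fm <- hill_try(2)
    if (is.null(fm)) for (n0 in c(1, 4)) { fm <- hill_try(n0); if (!is.null(fm)) break }
    if (is.null(fm)) {
      fits$hill <- list(model = "hill", converged = FALSE,
                        note = "Hill fit did not converge; excluded from selection")
    } else {
      cf <- coef(fm)
      sds <- tryCatch(sqrt(diag(vcov(fm))), error = function(e) rep(NA_real_, 3))
      fits$hill <- list(model = "hill",
                        params = c(max = unname(cf["ymax"]),
                                   half_point = unname(cf["h"]),
                                   n = unname(cf["nn"])),
                        param_sd = c(max = unname(sds[1]),
                                     half_point = unname(sds[2]),
                                     n = unname(sds[3])),
                        adjusted_r2 = .adj_r2(y, fitted(fm), 3),
                        aic = .aic_rss(n, sum(resid(fm)^2), 3),
                        converged = TRUE)
    }
  }
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  lin_r2 <- if (!is.null(fits$linear)) fits$linear$adjusted_r2 else -Inf
  if (lin_r2 >= 0.9) {
    best <- "linear"
  } else {
    aics <- vapply(conv, `[[`, numeric(1), "aic")
    best <- names(which.min(aics))
  }
  structure(list(fits = fits, best_model = best,
                 classification = if (best == "linear") "linear" else "non-linear",
                 x = x, y = y),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> classification:", x$classification,
      "(best model:", x$best_model, ")\n")
  for (f in x$fits) {
    if (isTRUE(f$converged))
      cat(sprintf("  %-6s adjR2 %.4f  AIC %.2f  [%s]\n", f$model,
                  f$adjusted_r2, f$aic,
                  paste(sprintf("%s=%.4g", names(f$params), f$params),
                        collapse = ", ")))
    else cat(sprintf("  %-6s %s\n", f$model, f$note))
  }
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, model = object$best_model, ...) {
  f <- object$fits[[model]]
  if (is.null(f) || !isTRUE(f$converged)) stop("no converged '", model, "' fit")
  f$params
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL,
                                      model = object$best_model, ...) {
  x <- if (is.null(newdata)) object$x else
    if (is.list(newdata)) newdata$x else newdata
  p <- coef(object, model = model)
  switch(model,
         linear = p[1] + p[2] * x,
         log = p[1] + p[2] * log10(x),
         hill = p[["max"]] * x^p[["n"]] / (x^p[["n"]] + p[["half_point"]]^p[["n"]]))
}

# ---- combination vs summation ANCOVA --------------------------------------

#' Test whether two pathways combine linearly
#'
#' Two-way ANCOVA of response AUC with a continuous covariate (stimulus
#' duration or intertrain interval) and a categorical factor distinguishing
#' the measured combined response from the sum of the single-pathway
#' responses. When the type factor is significant (p < 0.05) the verdict is
#' `"sublinear"` if the combined response falls below the sum and
#' `"supralinear"` if above; otherwise `"linear"`.
#'
#' @param auc_combo per-trial AUC of the combined stimulation.
#' @param auc_sum per-trial sum of the single-pathway AUCs (same length and
#'   trial structure as `auc_combo`).
#' @param x covariate value per trial (duration or ITI), recycled across the
#'   two groups.
#' @return an object of class `ancova_result` with fields `f_stat`, `df`,
#'   `p_covariate`, `t_covariate`, `p_type`, `t_type`, `type_effect` (combined
#'   minus sum, adjusted) and `verdict`.
#' @export
summation_test <- function(auc_combo, auc_sum, x) {
  if (length(auc_combo) != length(auc_sum))
    stop("combination and summation groups must have equal trial counts")
  if (length(x) != length(auc_combo)) stop("x must match the per-group length")
  d <- data.frame(y = c(auc_sum, auc_combo),
                  x = c(x, x),
                  type = factor(rep(c("summation", "combination"), each = length(x)),
                                levels = c("summation", "combination")))
  fm <- lm(y ~ x + type, data = d)
  sm <- summary(fm)
  co <- sm$coefficients
  fstat <- unname(sm$fstatistic)
  eff <- co["typecombination", "Estimate"]
  p_type <- co["typecombination", "Pr(>|t|)"]
  verdict <- if (is.finite(p_type) && p_type < 0.05) {
    if (eff < 0) "sublinear" else "supralinear"
  } else "linear"
  structure(list(f_stat = fstat[1], df = c(fstat[2], fstat[3]),
                 p_covariate = co["x", "Pr(>|t|)"],
                 t_covariate = co["x", "t value"],
                 p_type = p_type,
                 t_type = co["typecombination", "t value"],
                 type_effect = eff, verdict = verdict, fit = fm),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf(paste0("<ancova_result> F(%d,%d) = %.2f; covariate t = %.2f ",
                     "(p = %.3g); type t = %.2f (p = %.3g) -> %s\n"),
              x$df[1], x$df[2], x$f_stat, x$t_covariate, x$p_covariate,
              x$t_type, x$p_type, x$verdict))
  invisible(x)
}

#' Single-pathway contribution to the full response
#'
#' Percent contribution of each single pathway: 100 times the single-pathway
#' AUC divided by the all-pathway AUC. Deliberately not renormalized, so the
#' contributions may sum to more than 100% when pathways overlap.
#'
#' @param auc_single named numeric vector of single-pathway AUCs.
#' @param auc_all AUC with all pathways intact (> 0).
#' @return named numeric vector of percentages.
#' @export
pathway_contribution <- function(auc_single, auc_all) {
  if (!is.numeric(auc_all) || length(auc_all) != 1 || auc_all <= 0)
    stop("auc_all must be a single positive number")
  100 * auc_single / auc_all
}

#' Temporal sensitivity across intertrain intervals
#'
#' Summarizes an ITI scan: the mean response over the five ITIs, the temporal
#' sensitivity (maximum minus minimum across ITIs), and the best ITI
#' (argmax; ties resolved toward the larger ITI).
#'
#' @param auc_by_iti named numeric vector of mean AUC keyed by ITI; all five
#'   ITIs (3, 20, 40, 80, 300 s) must be present.
#' @return list with `mean`, `sensitivity`, `best_iti`.
#' @export
temporal_sensitivity <- function(auc_by_iti) {
  itis <- as.numeric(names(auc_by_iti))
  missing <- setdiff(.LLTP_ITIS, itis)
  if (length(missing))
    stop("missing ITI(s): ", paste(missing, collapse = ", "))
  v <- auc_by_iti[as.character(.LLTP_ITIS)]
  itis <- .LLTP_ITIS
  list(mean = mean(v), sensitivity = max(v) - min(v),
       best_iti = max(itis[v == max(v)]))
}

#' Rank molecule perturbations by random-forest importance
#'
#' Fits a random-forest regression of a response (e.g. temporal sensitivity
#' of ppERK) on per-molecule fractional concentration changes and returns the
#' feature weights, normalized to sum to one, ranked from most to least
#' influential.
#'
#' @param perturbations numeric matrix or data frame, one row per
#'   perturbation draw, one column per molecule (fractional changes); at
#'   least 30 rows.
#' @param response numeric response per row; must not be constant.
#' @param n_trees number of trees (default 100).
#' @return an object of class `robustness_result` with `weights` (named,
#'   non-negative, summing to 1) and `ranking`.
#' @export
robustness_importance <- function(perturbations, response, n_trees = 100) {
  X <- as.data.frame(perturbations)
  if (nrow(X) < 30) stop("need at least 30 perturbation rows for forest fitting")
  if (length(response) != nrow(X)) stop("response length must match rows")
  if (sd(response) == 0)
    stop("constant response: feature weights are undefined")
  rf <- randomForest::randomForest(X, response, ntree = n_trees,
                                   importance = FALSE)
  imp <- randomForest::importance(rf)[, 1]
  if (sum(imp) <= 0) stop("degenerate forest: all importances zero")
  w <- pmax(imp, 0) / sum(pmax(imp, 0))
  structure(list(weights = w, ranking = names(sort(w, decreasing = TRUE)),
                 n_trees = n_trees, forest = rf),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat("<robustness_result> top features:\n")
  w <- sort(x$weights, decreasing = TRUE)
  for (i in seq_len(min(5, length(w))))
    cat(sprintf("  %-12s %.3f\n", names(w)[i], w[i]))
  invisible(x)
}
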