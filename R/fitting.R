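# Multi-start bounded least-squares fitting of the two models to heading
# time courses, and their comparison by SSR and AIC.
#
# Parameter bounds follow the study conventions: every rate/salience in
# (0, 1), lambda in (-30, 60). The RW family counts k = 5 parameters as
# written (lambda, beta, alpha_plan, alpha_tone, alpha_light) even though
# only the products alpha_i * beta are identifiable from a single time
# course; the SS family counts k = 2 (A, B). Residuals are evaluated only on
# valid (unmasked) trials, while the model state propagates through every
# trial, since the participant experienced them all.

rw_bounds <- list(lower = c(lam = -30, beta = 0, alpha_plan = 0,
                            alpha_tone = 0, alpha_light = 0),
                  upper = c(lam = 60, beta = 1, alpha_plan = 1,
                            alpha_tone = 1, alpha_light = 1))
ss_bounds <- list(lower = c(A = 0, B = 0), upper = c(A = 1, B = 1))

#' Predicted heading series for a parameter vector
#'
#' Delegates to the model simulators: the Rescorla-Wagner predicted heading
#' is the summed associative strength of the CSs present on each trial; the
#' state-space prediction is the motor state driven by the previous trial's
#' clamp error (+15 on error-clamp trials, 0 otherwise).
#'
#' @param model `"rw"` or `"ss"`.
#' @param params Named vector or list of parameters for the model.
#' @param schedule A `trial_schedule`.
#' @return Numeric predicted heading series (degrees).
#' @export
predict_series <- function(model = c("rw", "ss"), params, schedule) {
  model <- match.arg(model)
  p <- as.list(params)
  if (model == "rw")
    rw_simulate(schedule, rw_params(lam = p$lam, beta = p$beta,
                                    alpha_plan = p$alpha_plan,
                                    alpha_tone = p$alpha_tone,
                                    alpha_light = p$alpha_light))$v_total
  else
    ss_simulate(schedule, ss_params(A = p$A, B = p$B))$x
}

#' Akaike information criterion from residuals
#'
#' `AIC = n * log(ssr / n) + 2k`, the Gaussian-likelihood approximation on
#' the residual sum of squares.
#'
#' @param ssr Sum of squared residuals (> 0).
#' @param n Number of residual points (> 0).
#' @param k Number of free parameters.
#' @return The AIC value.
#' @examples
#' aic(100, 100, 2)  # 4
#' @export
aic <- function(ssr, n, k) {
  stopifnot(n > 0, k >= 0)
  if (ssr <= 0)
    stop("ssr must be > 0 for the residual AIC approximation; compare SSR directly for perfect fits")
  n * log(ssr / n) + 2 * k
}

#' Fit a model to an observed heading series by multi-start least squares
#'
#' Minimizes the sum of squared residuals between the observed (oriented,
#' baseline-subtracted) heading series and the model prediction over valid
#' trials, using bounded quasi-Newton local optimization (L-BFGS-B, gradient
#' tolerance 1e-8) from `n_starts` initial parameter sets drawn uniformly
#' within the bounds.
#'
#' @param obs Observed heading series aligned to `schedule`.
#' @param schedule The participant's `trial_schedule`.
#' @param model `"rw"` or `"ss"`.
#' @param valid Logical mask of trials entering the residual (default: all
#'   non-missing observations). At least 10 valid observations are required.
#' @param n_starts Number of random restarts (default 200).
#' @param seed Integer seed for the restart draws.
#' @return A `fit_result` list: `model`, named `par`, `ssr`, `n`, `k`,
#'   `aic`, `n_starts`, `best_start`, `converged`.
#' @export
fit_model <- function(obs, schedule, model = c("rw", "ss"), valid = NULL,
                      n_starts = 200, seed = 1L) {
  model <- match.arg(model)
  stopifnot(length(obs) == nrow(schedule))
  if (is.null(valid)) valid <- !is.na(obs)
  valid <- valid & !is.na(obs)
  if (sum(valid) < 10) stop("need at least 10 valid observations")
  obs0 <- ifelse(valid, obs, 0)  # masked entries never enter the residual
  b <- if (model == "rw") rw_bounds else ss_bounds
  cs <- cs_codes(schedule)
  us <- us_indicator(schedule)
  e <- 15 * us
  objective <- if (model == "rw")
    function(p) rw_ssr_cpp(cs, us, obs0, valid, p[3], p[4], p[5], p[2], p[1])
  else
    function(p) ss_ssr_cpp(e, obs0, valid, p[1], p[2])
  k <- length(b$lower)
  starts <- withr::with_seed(seed, {
    matrix(stats::runif(n_starts * k, rep(b$lower, each = n_starts),
                        rep(b$upper, each = n_starts)), ncol = k)
  })
  best <- NULL; best_start <- NA_integer_; any_conv <- FALSE
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[s, ], objective, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(factr = 1e3, pgtol = 1e-10, maxit = 2000,
                                  ndeps = rep(1e-7, length(b$lower)))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best_start <- s
    }
  }
  if (is.null(best))
    stop("all ", n_starts, " starts failed for model '", model, "'")
  par <- stats::setNames(best$par, names(b$lower))
  ssr <- best$value
  n <- sum(valid)
  structure(list(model = model, par = par, ssr = ssr, n = n, k = k,
                 aic = if (ssr > 0) aic(ssr, n, k) else -Inf,
                 n_starts = n_starts, best_start = best_start,
                 converged = any_conv),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s: SSR = %.4g, AIC = %.4g, n = %d, k = %d>\n",
              x$model, x$ssr, x$aic, x$n, x$k))
  print(round(x$par, 5))
  invisible(x)
}

#' Fit both models to every participant of a cohort
#'
#' Preprocesses each participant (orientation, baseline subtraction, outlier
#' screening), rebuilds the trial structure from the records, and fits the
#' requested models to the oriented heading series with outlier trials
#' masked out of the residual.
#'
#' @param cohort Long tibble of trial records.
#' @param models Character vector of models to fit.
#' @param n_starts Restarts per fit.
#' @param seed Base seed; each participant x model gets a distinct derived
#'   seed.
#' @return A tibble with one row per participant x model: fitted parameters
#'   (NA for parameters the model lacks), `ssr`, `aic`, `n`, `k`.
#' @export
fit_cohort <- function(cohort, models = c("rw", "ss"), n_starts = 200,
                       seed = 1L) {
  pre <- preprocess_cohort(cohort)
  parts <- split(pre, factor(pre$participant_id,
                             levels = unique(pre$participant_id)))
  rows <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    sched <- schedule_from_records(p)
    for (m in models) {
      f <- fit_model(p$theta, sched, model = m, valid = !p$outlier,
                     n_starts = n_starts,
                     seed = seed + 1000L * i + match(m, c("rw", "ss")))
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = unique(p$participant_id), model = m,
        lam = f$par["lam"], beta = f$par["beta"],
        alpha_plan = f$par["alpha_plan"], alpha_tone = f$par["alpha_tone"],
        alpha_light = f$par["alpha_light"],
        A = f$par["A"], B = f$par["B"],
        ssr = f$ssr, aic = f$aic, n = f$n, k = f$k)
    }
  }
  do.call(rbind, rows)
}

# Rebuild a trial_schedule from one participant's records so that fitting
# sees the CS/US structure the participant experienced. The CS+ cue is
# mapped back to the schedule's internal tone-is-CS+ convention.
schedule_from_records <- function(data) {
  plus <- infer_cs_plus(data)
  cs <- data$cs
  if (plus == "light") {
    cs[data$cs == "light"] <- "tone"
    cs[data$cs == "tone"] <- "light"
  }
  trials <- tibble::tibble(trial = data$trial, phase = data$phase, cs = cs,
                           us = data$clamp_deg)
  new_trial_schedule(trials, unique(data$design), seed = NA_integer_,
                     cs_plus = if (plus == "compound") "compound" else "tone")
}

#' Compare per-participant model fits
#'
#' Per-participant SSR and AIC differences (RW minus SS; negative favors the
#' Rescorla-Wagner model) with a paired t test and Cohen's d across the
#' cohort.
#'
#' @param fits Fit table from [fit_cohort()] containing both models.
#' @return A list: `per_participant` tibble (`d_ssr`, `d_aic`), and paired
#'   test summaries `ssr_test`, `aic_test` (each: `mean`, `ci95`, `t`, `df`,
#'   `p`, `cohen_d`).
#' @export
compare_models <- function(fits) {
  rw <- fits[fits$model == "rw", ]
  ss <- fits[fits$model == "ss", ]
  if (!nrow(rw) || !nrow(ss)) stop("fits must contain both models")
  if (!identical(rw$participant_id, ss$participant_id))
    stop("participant sets differ between models")
  if (!identical(rw$n, ss$n))
    stop("models were fit on different valid-trial sets")
  d_ssr <- rw$ssr - ss$ssr
  d_aic <- rw$aic - ss$aic
  summarize <- function(d) {
    if (stats::sd(d) == 0)  # identical fits: no variability to test against
      return(list(mean = mean(d), ci95 = c(mean(d), mean(d)), t = 0,
                  df = length(d) - 1, p = 1, cohen_d = 0))
    tt <- stats::t.test(d)
    list(mean = mean(d), ci95 = unname(tt$conf.int),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, cohen_d = mean(d) / stats::sd(d))
  }
  list(per_participant = tibble::tibble(participant_id = rw$participant_id,
                                        d_ssr = d_ssr, d_aic = d_aic),
       ssr_test = summarize(d_ssr), aic_test = summarize(d_aic))
}
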