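# Conditioning models of clamped-feedback reaching.
#
# Two trial-level models of the heading-angle time course:
#  * Rescorla-Wagner (RW): the predicted heading is the summed associative
#    strength between the US (clamped cursor feedback) and the CSs present on
#    the trial -- the movement plan (present on every trial) plus the tone
#    and/or light cue. All strengths are updated by a shared prediction error
#    lambda*US - V_total, scaled by each CS's salience alpha_i and the US
#    learning rate beta.
#  * State-space (SS): a single motor state x with retention A and learning
#    rate B driven by the previous trial's clamp error. It has no
#    representation of the current trial's cue.
#
# All simulation is in "adaptive-positive" coordinates: positive heading is
# away from the clamp, so the driving error on 15-degree-clamp trials is +15.

#' Rescorla-Wagner parameter bundle
#'
#' @param lam Maximum conditioning level lambda (degrees), the asymptote the
#'   summed associative strength approaches under a sustained error clamp.
#' @param beta US learning rate, in \[0, 1\].
#' @param alpha_plan,alpha_tone,alpha_light CS saliences, each in \[0, 1\].
#'   The movement plan carries most of the salience; the arbitrary cues carry
#'   little, which is what makes their conditioned effect small but nonzero.
#' @param experiment Convenience preset: `"exp1"` (beta = 0.12, alpha_cs =
#'   0.002) or `"exp4"` (beta = 0.02, alpha_cs = 0.1). Explicit arguments
#'   override the preset.
#' @return An `rw_params` list.
#' @examples
#' rw_params()                 # Experiment 1 simulation values
#' rw_params(experiment = "exp4")
#' @export
rw_params <- function(lam = 15, beta = NULL, alpha_plan = 0.99,
                      alpha_tone = NULL, alpha_light = NULL,
                      experiment = c("exp1", "exp4")) {
  experiment <- match.arg(experiment)
  defaults <- switch(experiment,
                     exp1 = list(beta = 0.12, alpha_cs = 0.002),
                     exp4 = list(beta = 0.02, alpha_cs = 0.1))
  if (is.null(beta)) beta <- defaults$beta
  if (is.null(alpha_tone)) alpha_tone <- defaults$alpha_cs
  if (is.null(alpha_light)) alpha_light <- defaults$alpha_cs
  p <- list(lam = lam, beta = beta, alpha_plan = alpha_plan,
            alpha_tone = alpha_tone, alpha_light = alpha_light)
  validate_rw_params(p)
  structure(p, class = "rw_params")
}

validate_rw_params <- function(p) {
  rates <- c(beta = p$beta, alpha_plan = p$alpha_plan,
             alpha_tone = p$alpha_tone, alpha_light = p$alpha_light)
  if (any(!is.finite(unlist(p))))
    stop("all Rescorla-Wagner parameters must be finite")
  bad <- names(rates)[rates < 0 | rates > 1]
  if (length(bad))
    stop("parameters out of [0, 1]: ", paste(bad, collapse = ", "))
  if ((p$alpha_plan + p$alpha_tone + p$alpha_light) * p$beta >= 2)
    stop("(alpha_plan + alpha_tone + alpha_light) * beta must be < 2 for a stable update")
  invisible(p)
}

#' State-space parameter bundle
#'
#' @param A Retention factor in \[0, 1\] (fraction of the motor state carried
#'   from one trial to the next).
#' @param B Learning rate in \[0, 1\] applied to the previous trial's error.
#' @return An `ss_params` list.
#' @export
ss_params <- function(A = 0.9, B = 0.12) {
  stopifnot(is.finite(A), is.finite(B), A >= 0, A <= 1, B >= 0, B <= 1)
  structure(list(A = A, B = B), class = "ss_params")
}

#' One Rescorla-Wagner update step
#'
#' The elementary update shared by every CS on a trial: the prediction error
#' is computed from the summed strength of the CSs present on the trial
#' (`v_present`), and each present CS moves by its own salience times the US
#' learning rate times that error.
#'
#' @param v_present Summed associative strength of the CSs present on the
#'   trial (degrees).
#' @param v_i Current strength of the CS being updated (degrees).
#' @param alpha_i Salience of that CS, in \[0, 1\].
#' @param beta US learning rate, in \[0, 1\].
#' @param lam Maximum conditioning level (degrees).
#' @param us US indicator: 1 on error-clamp trials, 0 otherwise.
#' @return Updated `v_i` (degrees).
#' @examples
#' rw_step(0, 0, 0.99, 0.12, 15, 1)   # 1.782
#' @export
rw_step <- function(v_present, v_i, alpha_i, beta, lam, us) {
  stopifnot(alpha_i >= 0, alpha_i <= 1, beta >= 0, beta <= 1,
            us %in% c(0, 1))
  v_i + alpha_i * beta * (lam * us - v_present)
}

# Integer CS codes for the C++ cores.
cs_codes <- function(schedule) {
  unname(c(tone = 1L, light = 2L, compound = 3L)[schedule$cs])
}

#' Simulate the Rescorla-Wagner model over a schedule
#'
#' Associative strengths start at 0. On each trial the predicted heading is
#' the pre-update summed strength of the movement-plan CS and the cue(s)
#' presented on that trial; after the trial, the plan and the presented cues
#' are updated by the shared prediction error `lam*US - V_total` (US = 0 on
#' 0-degree-clamp and no-feedback trials), while absent cues carry their
#' strengths forward unchanged.
#'
#' @param schedule A `trial_schedule`.
#' @param params An [rw_params()] bundle.
#' @return A tibble with per-trial `trial`, `phase`, `cs`, `us_ind`,
#'   pre-update strengths `v_plan`, `v_tone`, `v_light`, the predicted heading
#'   `v_total`, and the prediction error `spe`.
#' @examples
#' sched <- make_differential_schedule(600, 200, seed = 1)
#' traj <- rw_simulate(sched, rw_params())
#' tail(traj$v_total)
#' @export
rw_simulate <- function(schedule, params) {
  validate_rw_params(params)
  m <- rw_sim_cpp(cs_codes(schedule), us_indicator(schedule),
                  params$alpha_plan, params$alpha_tone, params$alpha_light,
                  params$beta, params$lam)
  tibble::tibble(trial = schedule$trial, phase = schedule$phase,
                 cs = schedule$cs, us_ind = us_indicator(schedule),
                 v_plan = m[, "v_plan"], v_tone = m[, "v_tone"],
                 v_light = m[, "v_light"], v_total = m[, "v_total"],
                 spe = m[, "spe"])
}

#' Simulate the state-space model over a schedule
#'
#' `x[1] = 0`; `x[n] = A*x[n-1] + B*e[n-1]`, where the driving error `e` is
#' +15 degrees on error-clamp trials and 0 on 0-degree-clamp and no-feedback
#' trials (adaptive-positive sign convention). The predicted heading is `x`.
#'
#' @param schedule A `trial_schedule`.
#' @param params An [ss_params()] bundle.
#' @param clamp_error Magnitude of the driving error on error-clamp trials
#'   (degrees, default 15).
#' @return A tibble with per-trial `trial`, `phase`, `cs`, driving error `e`,
#'   and motor state / predicted heading `x`.
#' @export
ss_simulate <- function(schedule, params, clamp_error = 15) {
  stopifnot(inherits(params, "ss_params") ||
              (is.list(params) && all(c("A", "B") %in% names(params))))
  e <- clamp_error * us_indicator(schedule)
  x <- ss_sim_cpp(e, params$A, params$B)
  tibble::tibble(trial = schedule$trial, phase = schedule$phase,
                 cs = schedule$cs, e = e, x = x)
}

# ---- trial-by-trial effects on a trajectory ---------------------------------

# Consecutive same-phase trial pairs of a heading series: returns a data.frame
# with delta, prev_type, cur_type for pairs (n-1, n) within `phase`.
phase_pairs <- function(heading, schedule, phase) {
  stopifnot(length(heading) == nrow(schedule))
  idx <- which(schedule$phase == phase)
  if (length(idx) < 2)
    stop("phase '", phase, "' contains fewer than 2 trials")
  type <- cs_type(schedule)
  n <- idx[-1]
  prev <- idx[-length(idx)]
  keep <- n == prev + 1  # consecutive trials only
  data.frame(n = n[keep],
             delta = heading[n[keep]] - heading[prev[keep]],
             prev_type = type[prev[keep]], cur_type = type[n[keep]],
             stringsAsFactors = FALSE)
}

# 2x2 cell summary of delta values by previous x current CS type, plus the
# derived contrasts. levels: c("+", "-") for differential designs.
delta_cells <- function(delta, prev_type, cur_type,
                        statistic = c("mean", "median"),
                        levels = c("+", "-"), who = "") {
  statistic <- match.arg(statistic)
  fun <- if (statistic == "mean") mean else stats::median
  cells <- matrix(NA_real_, 2, 2,
                  dimnames = list(prev = levels, cur = levels))
  for (i in levels) for (j in levels) {
    v <- delta[prev_type == i & cur_type == j]
    if (!length(v))
      stop(sprintf("empty cell (previous %s, current %s)%s", i, j,
                   if (nzchar(who)) paste0(" for ", who) else ""))
    cells[i, j] <- fun(v)
  }
  list(cells = cells,
       pavlovian  = mean(cells[, levels[1]]) - mean(cells[, levels[2]]),
       adaptation = mean(cells[levels[1], ]) - mean(cells[levels[2], ]),
       interaction = cells[1, 1] - cells[1, 2] - cells[2, 1] + cells[2, 2],
       statistic = statistic)
}

#' Pavlovian and adaptation effects of a simulated (or observed) trajectory
#'
#' Computes the trial-by-trial heading change `delta[n] = heading[n] -
#' heading[n-1]` over consecutive same-phase trial pairs and summarizes it in
#' the 2x2 cells defined by the CS type on the previous and current trial.
#' The Pavlovian effect is the current-CS contrast (cells averaged over
#' previous-CS levels with equal weight), the adaptation effect the
#' previous-CS contrast.
#'
#' @param heading Numeric heading series aligned to `schedule` (e.g.
#'   `rw_simulate(...)$v_total` or `ss_simulate(...)$x`).
#' @param schedule The `trial_schedule` the series was simulated/recorded on.
#' @param phase `"acquisition"` or `"probe"`.
#' @param statistic Cell statistic, `"mean"` (default) or `"median"`.
#' @return A list with the 2x2 `cells` matrix and scalars `pavlovian`,
#'   `adaptation`, `interaction` (degrees).
#' @export
trajectory_effects <- function(heading, schedule,
                               phase = c("acquisition", "probe"),
                               statistic = c("mean", "median")) {
  phase <- match.arg(phase)
  pp <- phase_pairs(heading, schedule, phase)
  delta_cells(pp$delta, pp$prev_type, pp$cur_type, statistic = statistic)
}

#' Model-predicted differential response to the current CS
#'
#' The structural Pavlovian contrast of a model trajectory: on each trial of
#' the phase, the difference between the heading the model would produce if
#' the CS+ cue were presented and if the CS- cue were presented, given the
#' same learning state -- for the Rescorla-Wagner model `V_tone - V_light`
#' (tone is the within-schedule CS+), for the state-space model identically 0
#' since its prediction does not depend on the current cue. Unlike the
#' empirical 2x2 cell contrast, this quantity is free of finite-schedule
#' sampling noise, which is what makes the state-space null exact.
#'
#' @param traj A trajectory tibble from [rw_simulate()] or [ss_simulate()].
#' @param phase `"acquisition"` or `"probe"`.
#' @return Mean predicted CS+/CS- heading difference over the phase (degrees).
#' @export
predicted_cs_contrast <- function(traj, phase = c("acquisition", "probe")) {
  phase <- match.arg(phase)
  rows <- traj$phase == phase
  if (!any(rows)) stop("phase '", phase, "' not present in trajectory")
  if (all(c("v_tone", "v_light") %in% names(traj)))
    mean(traj$v_tone[rows] - traj$v_light[rows])
  else if ("x" %in% names(traj))
    mean(traj$x[rows] - traj$x[rows])  # state-space: cue-independent
  else stop("unrecognized trajectory object")
}

# ---- parameter sweeps -------------------------------------------------------

#' Pavlovian-effect parameter sweep
#'
#' Evaluates the Pavlovian effect over a parameter grid for one of the two
#' models on differential schedules, as used for the model-prediction
#' heatmaps. For each grid point the effect is averaged over the supplied
#' schedules (several seeds smooth out schedule idiosyncrasies).
#'
#' @param model `"rw"` or `"ss"`.
#' @param grid Named list of parameter axes. For `"rw"`: any of `lam`,
#'   `beta`, `alpha_plan`, `alpha_cs` (sets `alpha_tone = alpha_light`);
#'   unlisted parameters come from `fixed`. For `"ss"`: `A` and `B`.
#' @param schedules A `trial_schedule` or list of them.
#' @param phase `"acquisition"` or `"probe"`.
#' @param contrast `"predictive"` (default): the model's differential
#'   response to the current CS, [predicted_cs_contrast()]; `"empirical"`:
#'   the realized 2x2 cell contrast, [trajectory_effects()].
#' @param fixed Baseline parameters for axes not in `grid` (default: the
#'   Experiment 1 presets).
#' @return A tibble with one row per grid point: the axis values and
#'   `pavlovian` (degrees).
#' @export
sweep_pavlovian <- function(model = c("rw", "ss"), grid, schedules,
                            phase = c("acquisition", "probe"),
                            contrast = c("predictive", "empirical"),
                            fixed = NULL) {
  model <- match.arg(model)
  phase <- match.arg(phase)
  contrast <- match.arg(contrast)
  if (inherits(schedules, "trial_schedule")) schedules <- list(schedules)
  allowed <- if (model == "rw") c("lam", "beta", "alpha_plan", "alpha_cs")
             else c("A", "B")
  if (!length(grid) || !all(names(grid) %in% allowed))
    stop("grid axes for model '", model, "' must be among: ",
         paste(allowed, collapse = ", "))
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  one_effect <- function(traj, sched) {
    if (contrast == "predictive") predicted_cs_contrast(traj, phase)
    else {
      h <- if (model == "rw") traj$v_total else traj$x
      trajectory_effects(h, sched, phase)$pavlovian
    }
  }
  pts$pavlovian <- vapply(seq_len(nrow(pts)), function(r) {
    if (model == "rw") {
      base <- if (is.null(fixed)) rw_params() else fixed
      p <- list(lam = base$lam, beta = base$beta,
                alpha_plan = base$alpha_plan, alpha_tone = base$alpha_tone,
                alpha_light = base$alpha_light)
      for (nm in names(grid)) {
        if (nm == "alpha_cs") p$alpha_tone <- p$alpha_light <- pts[[nm]][r]
        else p[[nm]] <- pts[[nm]][r]
      }
      p <- do.call(rw_params, p[c("lam", "beta", "alpha_plan",
                                  "alpha_tone", "alpha_light")])
      mean(vapply(schedules,
                  function(s) one_effect(rw_simulate(s, p), s), numeric(1)))
    } else {
      base <- if (is.null(fixed)) ss_params() else fixed
      A <- if ("A" %in% names(grid)) pts$A[r] else base$A
      B <- if ("B" %in% names(grid)) pts$B[r] else base$B
      p <- ss_params(A = A, B = B)
      mean(vapply(schedules,
                  function(s) one_effect(ss_simulate(s, p), s), numeric(1)))
    }
  }, numeric(1))
  tibble::as_tibble(pts)
}
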