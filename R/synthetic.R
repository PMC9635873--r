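# Synthetic participants with the statistical structure the analyses assume:
# a conditioning model generates the latent heading time course; iid Gaussian
# motor noise, platform-specific outliers, truncated-Gaussian RT/MT with an
# occasional slow trial, and a small feedback-correction discrepancy between
# the heading at 50 ms and at the target radius are layered on top.

#' Synthetic-cohort configuration
#'
#' Defaults emulate the lab-based differential-conditioning sessions: an
#' Experiment 1 Rescorla-Wagner generator, 3.5 degree motor noise, RT around
#' 293 +/- 49 ms and MT around 103 +/- 31.2 ms (truncated so regular trials
#' respect the task's speed admonitions), a small rate of slow trials, rare
#' heading outliers, and a feedback correction of -0.32 +/- 2.92 degrees.
#'
#' @param model Generating model, `"rw"` or `"ss"`.
#' @param params Model parameters ([rw_params()] or [ss_params()]); defaults
#'   to the model's standard preset.
#' @param platform `"lab"` or `"web"`; sets the default outlier rate and the
#'   bounds outside which injected outliers fall.
#' @param sigma_m Motor noise SD on the heading angle (degrees).
#' @param rt_mean,rt_sd,rt_range Regular-trial reaction-time distribution
#'   (ms): Gaussian truncated to `rt_range`.
#' @param mt_mean,mt_sd,mt_range Movement-time distribution (ms), likewise.
#' @param p_slow Probability that a trial is slow (RT > 400 ms or
#'   MT > 300 ms), producing the trials the delta analyses exclude.
#' @param outlier_rate Probability that a trial's heading is replaced by a
#'   draw outside the platform's outlier bounds; `NULL` = platform default
#'   (0.001 lab, 0.0135 web, matching reported exclusion rates).
#' @param correction_mean,correction_sd Feedback-correction distribution
#'   (degrees): heading at target radius minus heading at 50 ms.
#' @param salience_jitter_sd SD of a log-normal multiplicative jitter applied
#'   per participant to `alpha_tone` and `alpha_light` (0 = off). Used to
#'   induce between-participant salience trade-offs for overshadowing
#'   demonstrations; when > 0 the jittered pair is rescaled so
#'   `alpha_tone + alpha_light` keeps its configured sum.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(model = c("rw", "ss"), params = NULL,
                             platform = c("lab", "web"), sigma_m = 3.5,
                             rt_mean = 293, rt_sd = 49,
                             rt_range = c(100, 400),
                             mt_mean = 103, mt_sd = 31.2,
                             mt_range = c(30, 300),
                             p_slow = 0.07, outlier_rate = NULL,
                             correction_mean = -0.32, correction_sd = 2.92,
                             salience_jitter_sd = 0) {
  model <- match.arg(model)
  platform <- match.arg(platform)
  if (is.null(params))
    params <- if (model == "rw") rw_params() else ss_params()
  if (is.null(outlier_rate))
    outlier_rate <- if (platform == "lab") 0.001 else 0.0135
  stopifnot(sigma_m >= 0, rt_sd >= 0, mt_sd >= 0, correction_sd >= 0,
            p_slow >= 0, p_slow <= 1, outlier_rate >= 0, outlier_rate <= 1,
            salience_jitter_sd >= 0)
  structure(list(model = model, params = params, platform = platform,
                 sigma_m = sigma_m, rt_mean = rt_mean, rt_sd = rt_sd,
                 rt_range = rt_range, mt_mean = mt_mean, mt_sd = mt_sd,
                 mt_range = mt_range, p_slow = p_slow,
                 outlier_rate = outlier_rate,
                 correction_mean = correction_mean,
                 correction_sd = correction_sd,
                 salience_jitter_sd = salience_jitter_sd),
            class = "synthetic_config")
}

# Gaussian truncated to [lo, hi] by inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

# A heading value outside the platform's outlier bounds (oriented scale).
outlier_draw <- function(n, platform) {
  if (platform == "lab") {
    sign <- sample(c(-1, 1), n, replace = TRUE)
    sign * stats::runif(n, 101, 170)
  } else {
    high <- stats::runif(n) < 0.5
    ifelse(high, stats::runif(n, 71, 110), stats::runif(n, -90, -51))
  }
}

#' Generate one synthetic participant
#'
#' @param schedule The `trial_schedule` the participant experiences.
#' @param config A [synthetic_config()].
#' @param seed Participant-level integer seed (reproducible per seed).
#' @param participant_id Identifier written into the records.
#' @param clamp_dir `"cw"` or `"ccw"`: direction of the error clamp.
#'   Adaptation is recorded CCW-positive for cw clamps and CW-negative for
#'   ccw clamps, so the raw heading of a ccw participant is the negated
#'   adaptive-positive series.
#' @param cs_assignment Which physical cue (`"tone"` or `"light"`) plays the
#'   CS+ role for this participant; the schedule's internal convention (tone
#'   = CS+) is relabeled accordingly.
#' @return A tibble of per-trial records in the trial-record CSV schema (see
#'   [read_trials()]).
#' @export
generate_participant <- function(schedule, config, seed,
                                 participant_id = "p01",
                                 clamp_dir = c("cw", "ccw"),
                                 cs_assignment = c("tone", "light")) {
  clamp_dir <- match.arg(clamp_dir)
  cs_assignment <- match.arg(cs_assignment)
  stopifnot(inherits(config, "synthetic_config"))
  n <- nrow(schedule)
  withr::with_seed(seed, {
    params <- config$params
    if (config$model == "rw" && config$salience_jitter_sd > 0) {
      tot <- params$alpha_tone + params$alpha_light
      jit <- c(params$alpha_tone, params$alpha_light) *
        stats::rlnorm(2, 0, config$salience_jitter_sd)
      jit <- jit / sum(jit) * tot  # preserve the salience capacity
      params <- rw_params(lam = params$lam, beta = params$beta,
                          alpha_plan = params$alpha_plan,
                          alpha_tone = min(jit[1], 1),
                          alpha_light = min(jit[2], 1))
    }
    pred <- if (config$model == "rw") rw_simulate(schedule, params)$v_total
            else ss_simulate(schedule, params)$x
    theta <- pred + stats::rnorm(n, 0, config$sigma_m)
    is_out <- stats::runif(n) < config$outlier_rate
    if (any(is_out))
      theta[is_out] <- outlier_draw(sum(is_out), config$platform)
    raw <- if (clamp_dir == "cw") theta else -theta
    correction <- stats::rnorm(n, config$correction_mean, config$correction_sd)
    rt <- rtruncnorm(n, config$rt_mean, config$rt_sd,
                     config$rt_range[1], config$rt_range[2])
    mt <- rtruncnorm(n, config$mt_mean, config$mt_sd,
                     config$mt_range[1], config$mt_range[2])
    slow <- stats::runif(n) < config$p_slow
    if (any(slow)) {
      slow_rt <- stats::runif(n) < 0.5
      rt[slow & slow_rt] <- stats::runif(sum(slow & slow_rt), 401, 600)
      mt[slow & !slow_rt] <- stats::runif(sum(slow & !slow_rt), 301, 450)
    }
    cs <- schedule$cs
    if (cs_assignment == "light") {  # relabel physical cues
      cs[schedule$cs == "tone"] <- "light"
      cs[schedule$cs == "light"] <- "tone"
    }
    tibble::tibble(
      participant_id = participant_id,
      design = attr(schedule, "design"),
      platform = config$platform,
      clamp_dir = clamp_dir,
      phase = schedule$phase,
      trial = schedule$trial,
      cs = cs,
      clamp_deg = schedule$us,
      hand_angle_deg = raw,
      angle_50ms_deg = raw - correction,
      rt_ms = rt,
      mt_ms = mt)
  })
}

#' Generate a counterbalanced synthetic cohort
#'
#' Each participant gets a unique schedule (own seed) and a unique noise
#' seed; clamp direction and CS+ cue assignment are counterbalanced across
#' participants (crossed where the cohort size allows).
#'
#' @param design One of the four designs (see [make_differential_schedule()]
#'   and [make_compound_schedule()]).
#' @param n_participants Cohort size (>= 2 when counterbalancing).
#' @param config A [synthetic_config()].
#' @param seed Master integer seed; the whole cohort is a deterministic
#'   function of it.
#' @param counterbalance Counterbalance clamp direction and CS+ assignment
#'   (default TRUE).
#' @param n_acq,n_probe Trial counts passed to the schedule constructor
#'   (`n_probe` is per CS type for the compound design).
#' @return A long tibble of trial records, one block per participant.
#' @examples
#' coh <- generate_cohort("exp1_differential", 4,
#'                        synthetic_config(sigma_m = 2), seed = 1)
#' table(coh$participant_id)
#' @export
generate_cohort <- function(design = DESIGNS, n_participants,
                            config = synthetic_config(), seed = 1L,
                            counterbalance = TRUE,
                            n_acq = 600,
                            n_probe = if (design == "exp4_compound") 100 else 200) {
  design <- match.arg(design)
  if (counterbalance && n_participants < 2)
    stop("counterbalanced cohorts need at least 2 participants")
  ids <- sprintf("p%02d", seq_len(n_participants))
  withr::with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, 2 * n_participants)
  })
  sched_seeds <- seeds[seq_len(n_participants)]
  noise_seeds <- seeds[n_participants + seq_len(n_participants)]
  if (counterbalance) {
    clamp <- rep(c("cw", "ccw"), length.out = n_participants)
    csplus <- rep(c("tone", "tone", "light", "light"),
                  length.out = n_participants)
  } else {
    clamp <- rep("cw", n_participants)
    csplus <- rep("tone", n_participants)
  }
  out <- lapply(seq_len(n_participants), function(i) {
    sched <- if (design == "exp4_compound")
      make_compound_schedule(n_acq, n_probe, seed = sched_seeds[i])
    else
      make_differential_schedule(n_acq, n_probe, seed = sched_seeds[i],
                                 design = design)
    generate_participant(sched, config, seed = noise_seeds[i],
                         participant_id = ids[i], clamp_dir = clamp[i],
                         cs_assignment = csplus[i])
  })
  do.call(rbind, out)
}
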