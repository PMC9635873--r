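# Trial schedules for differential and compound conditioning designs.
#
# A schedule is a tibble with one row per trial:
#   trial  1-based index
#   phase  "acquisition" or "probe"
#   cs     "tone", "light" or "compound" (the movement-plan CS is implicit on
#          every trial and never appears in this column)
#   us     clamp angle in degrees (15 = error clamp, 0 = clamp straight to the
#          target); NA on no-feedback (probe) trials
# with attributes: design, seed, cs_plus (which cue is paired with the error
# clamp), lag1 (list: statistic, p, attempts).

DESIGNS <- c("exp1_differential", "exp2_delay", "exp3_simultaneous",
             "exp4_compound")

new_trial_schedule <- function(trials, design, seed, cs_plus, lag1 = NULL) {
  stopifnot(design %in% DESIGNS)
  out <- tibble::as_tibble(trials)
  structure(out,
            class = c("trial_schedule", class(out)),
            design = design, seed = seed, cs_plus = cs_plus, lag1 = lag1)
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule: %s, %d trials (%d acquisition / %d probe), seed %s>\n",
              attr(x, "design"), nrow(x),
              sum(x$phase == "acquisition"), sum(x$phase == "probe"),
              format(attr(x, "seed"))))
  if (!is.null(attr(x, "lag1"))) {
    l1 <- attr(x, "lag1")
    cat(sprintf("  acquisition lag-1 r = %.4f (p = %.3f, %d attempt%s)\n",
                l1$statistic, l1$p, l1$attempts, if (l1$attempts > 1) "s" else ""))
  }
  NextMethod()
}

#' Lag-1 autocorrelation of a CS sequence
#'
#' Correlates a +/-1-coded CS sequence with itself shifted by one trial, the
#' statistic used to screen candidate trial orders so that participants cannot
#' exploit first-order sequential structure to predict the upcoming cue.
#'
#' @param cs_sequence Numeric vector coded +1/-1 (any two distinct values
#'   work), length >= 3, not constant.
#' @return A list with `statistic` (the lag-1 correlation, in \[-1, 1\]) and
#'   `p` (two-sided p-value for zero correlation).
#' @examples
#' lag1_autocorrelation(rep(c(1, -1), 10))   # strict alternation: r = -1
#' @export
lag1_autocorrelation <- function(cs_sequence) {
  n <- length(cs_sequence)
  if (n < 3) stop("cs_sequence must have length >= 3")
  if (length(unique(cs_sequence)) < 2)
    stop("cs_sequence is constant; lag-1 correlation is undefined (zero variance)")
  x <- cs_sequence[-n]
  y <- cs_sequence[-1]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("lagged sub-sequence is constant; lag-1 correlation is undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(statistic = unname(ct$estimate), p = ct$p.value)
}

# Shuffle a balanced +/- multiset until the lag-1 criterion (two-sided
# p > alpha) passes. Returns list(cs = character vector, statistic, p, attempts).
balanced_sequence <- function(n, labels, alpha = 0.05, max_attempts = 1000L) {
  stopifnot(n %% 2 == 0)
  base <- rep(labels, each = n / 2)
  for (attempt in seq_len(max_attempts)) {
    cand <- sample(base)
    coded <- ifelse(cand == labels[1], 1, -1)
    l1 <- lag1_autocorrelation(coded)
    if (l1$p > alpha)
      return(list(cs = cand, statistic = l1$statistic, p = l1$p,
                  attempts = attempt))
  }
  stop(sprintf(
    "no CS sequence passing the lag-1 criterion found in %d attempts; the design is over-constrained",
    max_attempts))
}

#' Differential-conditioning trial schedule
#'
#' Builds the interleaved CS+/CS- schedule used in the differential designs:
#' `n_acq` acquisition trials (half paired with a 15 degree error clamp, half
#' with a 0 degree clamp) followed by `n_probe` no-feedback probe trials (half
#' per CS). Acquisition orders are drawn by shuffling a balanced multiset and
#' rejection-sampled until the CS sequence shows no significant lag-1
#' autocorrelation (two-sided p > 0.05), so exact 50/50 counts are guaranteed
#' and first-order predictability is ruled out.
#'
#' By convention the tone is the CS+ within a schedule; which physical cue a
#' participant experiences as CS+ is a counterbalancing property of the
#' participant (see [generate_cohort()]).
#'
#' @param n_acq,n_probe Even, non-negative trial counts (defaults: the
#'   600-trial acquisition / 200-trial probe differential session).
#' @param seed Integer seed; the schedule is a deterministic function of the
#'   arguments.
#' @param design Design label, one of the differential designs.
#' @param max_attempts Maximum rejection-sampling attempts before giving up.
#' @return A `trial_schedule` tibble (see package overview).
#' @examples
#' sched <- make_differential_schedule(600, 200, seed = 1)
#' table(sched$phase, sched$cs)
#' @export
make_differential_schedule <- function(n_acq = 600, n_probe = 200, seed = 1L,
                                       design = "exp1_differential",
                                       max_attempts = 1000L) {
  stopifnot(n_acq >= 0, n_probe >= 0, n_acq %% 2 == 0, n_probe %% 2 == 0,
            max_attempts >= 1)
  if (!design %in% DESIGNS[1:3])
    stop("design must be one of the differential designs: ",
         paste(DESIGNS[1:3], collapse = ", "))
  withr::with_seed(seed, {
    lag1 <- NULL
    cs_acq <- character(0)
    if (n_acq >= 4) {
      bal <- balanced_sequence(n_acq, c("tone", "light"),
                               max_attempts = max_attempts)
      cs_acq <- bal$cs
      lag1 <- bal[c("statistic", "p", "attempts")]
    } else if (n_acq > 0) {
      cs_acq <- sample(rep(c("tone", "light"), each = n_acq / 2))
    }
    cs_probe <- if (n_probe > 0)
      sample(rep(c("tone", "light"), each = n_probe / 2)) else character(0)
    trials <- tibble::tibble(
      trial = seq_len(n_acq + n_probe),
      phase = rep(c("acquisition", "probe"), c(n_acq, n_probe)),
      cs    = c(cs_acq, cs_probe),
      us    = c(ifelse(cs_acq == "tone", 15, 0), rep(NA_real_, n_probe)))
    new_trial_schedule(trials, design, seed, cs_plus = "tone", lag1 = lag1)
  })
}

#' Compound-conditioning trial schedule
#'
#' Builds the compound design: every acquisition trial presents the tone and
#' light together (compound CS) paired with the 15 degree error clamp; the
#' no-feedback probe phase presents `n_probe_per_cs` trials each of the
#' compound, the tone alone, and the light alone, in random order.
#'
#' @param n_acq Number of acquisition trials (default 600).
#' @param n_probe_per_cs Probe trials per CS type (default 100).
#' @param seed Integer seed.
#' @return A `trial_schedule` tibble.
#' @examples
#' sched <- make_compound_schedule(600, 100, seed = 1)
#' table(sched$cs[sched$phase == "probe"])
#' @export
make_compound_schedule <- function(n_acq = 600, n_probe_per_cs = 100,
                                   seed = 1L) {
  stopifnot(n_acq >= 0, n_probe_per_cs >= 0)
  withr::with_seed(seed, {
    cs_probe <- sample(rep(c("compound", "tone", "light"),
                           each = n_probe_per_cs))
    n_probe <- length(cs_probe)
    trials <- tibble::tibble(
      trial = seq_len(n_acq + n_probe),
      phase = rep(c("acquisition", "probe"), c(n_acq, n_probe)),
      cs    = c(rep("compound", n_acq), cs_probe),
      us    = c(rep(15, n_acq), rep(NA_real_, n_probe)))
    new_trial_schedule(trials, "exp4_compound", seed, cs_plus = "compound")
  })
}

# CS type per trial relative to the schedule's CS+ convention: "+" for the
# CS+ cue (or the compound), "-" otherwise. Used by the effects contrasts.
cs_type <- function(schedule) {
  ifelse(schedule$cs == attr(schedule, "cs_plus"), "+", "-")
}

# Does the CS set on each trial contain a given element cue?
cs_has <- function(schedule, cue) {
  schedule$cs == cue | schedule$cs == "compound"
}

# US indicator: 1 on error-clamp (15 degree) trials, 0 on 0-degree-clamp and
# no-feedback trials.
us_indicator <- function(schedule) {
  as.numeric(!is.na(schedule$us) & schedule$us == 15)
}
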