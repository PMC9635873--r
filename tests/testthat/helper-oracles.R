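# Independent oracle implementations used to cross-check the package. These
# deliberately mirror the published update rules as literal per-trial loops,
# written without reference to the package's own code paths.

# Literal loop transcription of the conditioning update: strengths start at
# 0; for each trial n > 1, the summed strength of the CSs present on trial
# n-1 produces the prediction error lam*US[n-1] - V_total[n-1], which
# updates the movement-plan CS and each cue present on trial n-1; absent
# cues carry forward. The prediction on trial n is the summed strength of
# the plan plus the cues presented on trial n.
rw_oracle <- function(schedule, params) {
  n <- nrow(schedule)
  cs <- schedule$cs
  us <- as.numeric(!is.na(schedule$us) & schedule$us == 15)
  Vp <- Vt <- Vl <- numeric(n)
  for (i in seq_len(n)[-1]) {
    prev <- i - 1
    if (cs[prev] == "tone") {
      vtot <- Vp[prev] + Vt[prev]
      err <- params$lam * us[prev] - vtot
      Vp[i] <- Vp[prev] + params$alpha_plan * params$beta * err
      Vt[i] <- Vt[prev] + params$alpha_tone * params$beta * err
      Vl[i] <- Vl[prev]
    } else if (cs[prev] == "light") {
      vtot <- Vp[prev] + Vl[prev]
      err <- params$lam * us[prev] - vtot
      Vp[i] <- Vp[prev] + params$alpha_plan * params$beta * err
      Vl[i] <- Vl[prev] + params$alpha_light * params$beta * err
      Vt[i] <- Vt[prev]
    } else {  # compound: tone and light both present
      vtot <- Vp[prev] + Vt[prev] + Vl[prev]
      err <- params$lam * us[prev] - vtot
      Vp[i] <- Vp[prev] + params$alpha_plan * params$beta * err
      Vt[i] <- Vt[prev] + params$alpha_tone * params$beta * err
      Vl[i] <- Vl[prev] + params$alpha_light * params$beta * err
    }
  }
  v_total <- Vp +
    ifelse(cs %in% c("tone", "compound"), Vt, 0) +
    ifelse(cs %in% c("light", "compound"), Vl, 0)
  list(v_plan = Vp, v_tone = Vt, v_light = Vl, v_total = v_total)
}

# Closed forms for constant conditions.
rw_closed_form <- function(n, lam, rate) lam * (1 - (1 - rate)^(seq_len(n) - 1))
ss_closed_form <- function(n, A, B, e) {
  if (A == 1) B * e * (seq_len(n) - 1)
  else B * e * (1 - A^(seq_len(n) - 1)) / (1 - A)
}

# Direct pairwise lag-1 correlation: cor of (s2..sn) with (s1..s_{n-1}).
lag1_brute <- function(s) stats::cor(s[-1], s[-length(s)])

# Longhand sums-of-squares decomposition of the 2x2 within-subject design.
# cells: data.frame with columns pp, pm, mp, mm (one row per participant).
anova2x2_longhand <- function(cells) {
  n <- nrow(cells)
  y <- array(NA_real_, c(n, 2, 2))  # subject x prev x cur
  y[, 1, 1] <- cells$pp; y[, 1, 2] <- cells$pm
  y[, 2, 1] <- cells$mp; y[, 2, 2] <- cells$mm
  grand <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)   # prev
  m_b <- apply(y, 3, mean)   # cur
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- 2 * n * sum((m_a - grand)^2)
  ss_b <- 2 * n * sum((m_b - grand)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + grand)^2)
  ss_as <- 2 * sum((m_sa - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_bs <- 2 * sum((m_sb - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_b) + grand)^2)
  resid <- y
  for (i in seq_len(n)) for (a in 1:2) for (b in 1:2)
    resid[i, a, b] <- y[i, a, b] - m_sa[i, a] - m_sb[i, b] - m_ab[a, b] +
      m_s[i] + m_a[a] + m_b[b] - grand
  ss_abs <- sum(resid^2)
  f <- function(ss_eff, ss_err, df_err)
    list(F = (ss_eff / 1) / (ss_err / df_err),
         eta_p2 = ss_eff / (ss_eff + ss_err))
  list(previous = f(ss_a, ss_as, n - 1),
       current = f(ss_b, ss_bs, n - 1),
       interaction = f(ss_ab, ss_abs, n - 1))
}

# Longhand Friedman statistic (no ties expected in the supplied table).
friedman_longhand <- function(mat) {
  N <- nrow(mat); k <- ncol(mat)
  R <- colSums(t(apply(mat, 1, rank)))
  12 / (N * k * (k + 1)) * sum(R^2) - 3 * N * (k + 1)
}

# A random differential-style schedule (unbalanced, mixed phases) for
# oracle-equivalence checks; optionally includes compound trials.
random_schedule <- function(n, seed, compound = FALSE) {
  withr::with_seed(seed, {
    cues <- if (compound) c("tone", "light", "compound") else c("tone", "light")
    cs <- sample(cues, n, replace = TRUE)
    phase <- rep(c("acquisition", "probe"), c(ceiling(0.75 * n), n - ceiling(0.75 * n)))
    us <- ifelse(phase == "probe", NA_real_,
                 ifelse(cs == "light", 0, 15))
    trials <- tibble::tibble(trial = seq_len(n), phase = phase, cs = cs,
                             us = us)
    adaptcond:::new_trial_schedule(trials, "exp1_differential", seed, "tone")
  })
}
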