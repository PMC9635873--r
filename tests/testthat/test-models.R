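all_csplus_schedule <- function(n) {
  trials <- tibble::tibble(trial = seq_len(n), phase = "acquisition",
                           cs = "tone", us = 15)
  adaptcond:::new_trial_schedule(trials, "exp1_differential", 0L, "tone")
}

test_that("rw_step implements the elementary update", {
  expect_equal(rw_step(0, 0, 0.99, 0.12, 15, 1), 1.782)
  expect_equal(rw_step(0, 0, 0.5, 0.5, 10, 0), 0)          # zero error, zero state
  expect_equal(rw_step(7.3, 2.1, 0, 0.12, 15, 1), 2.1)     # zero salience
  expect_equal(rw_step(3, 1, 0.2, 0.1, 15, 0), 1 + 0.2 * 0.1 * (-3))
})

test_that("rw_simulate matches the geometric-series closed form on constant conditions", {
  p <- rw_params()
  traj <- rw_simulate(all_csplus_schedule(600), p)
  cf <- rw_closed_form(600, p$lam, (p$alpha_plan + p$alpha_tone) * p$beta)
  for (n in c(1, 2, 10, 600))
    expect_equal(traj$v_total[n], cf[n], tolerance = 1e-12)
  expect_lt(max(abs(traj$v_total - cf)), 1e-10)
})

test_that("degenerate parameter settings behave as limits", {
  s <- make_differential_schedule(100, 20, seed = 4)
  zero <- rw_params(lam = 15, beta = 0.12, alpha_plan = 0, alpha_tone = 0,
                    alpha_light = 0)
  expect_true(all(rw_simulate(s, zero)$v_total == 0))
  # extinction: V decays monotonically toward 0 through the no-feedback probe
  traj <- rw_simulate(s, rw_params())
  vp <- traj$v_plan[traj$phase == "probe"]
  expect_true(all(diff(vp) <= 1e-12))
  expect_true(all(vp >= 0))
  expect_true(all(ss_simulate(s, ss_params(A = 0.9, B = 0))$x == 0))
  xa <- ss_simulate(s, ss_params(A = 0, B = 0.3))$x
  us_ind <- adaptcond:::us_indicator(s)
  expect_equal(xa[-1], 0.3 * 15 * us_ind[-length(us_ind)])  # memoryless limit
})

test_that("ss_simulate matches its closed form", {
  s <- all_csplus_schedule(200)
  x <- ss_simulate(s, ss_params(A = 0.9, B = 0.12))$x
  expect_equal(x[2], 1.8)
  expect_lt(max(abs(x - ss_closed_form(200, 0.9, 0.12, 15))), 1e-10)
})

test_that("rw parameter validation enforces bounds and stability", {
  expect_error(rw_params(beta = 1.2), "out of")
  expect_error(rw_params(alpha_plan = -0.1), "out of")
  expect_error(rw_params(beta = 1, alpha_plan = 1, alpha_tone = 1,
                         alpha_light = 1), "stable")
  expect_error(ss_params(A = 1.5))
})

test_that("simulator equals the literal pseudocode transcription on random schedules", {
  p <- rw_params(lam = 15, beta = 0.3, alpha_plan = 0.8, alpha_tone = 0.05,
                 alpha_light = 0.02)
  for (seed in 1:3) {
    s <- random_schedule(1000, seed)
    got <- rw_simulate(s, p)
    want <- rw_oracle(s, p)
    expect_equal(got$v_total, want$v_total, tolerance = 1e-14)
    expect_equal(got$v_tone, want$v_tone, tolerance = 1e-14)
  }
  # compound trials exercise the all-CSs-updated branch
  s <- random_schedule(800, 9, compound = TRUE)
  expect_equal(rw_simulate(s, p)$v_total, rw_oracle(s, p)$v_total,
               tolerance = 1e-14)
})

test_that("element strengths change only after trials presenting that element", {
  p <- rw_params(lam = 15, beta = 0.2, alpha_plan = 0.5, alpha_tone = 0.1,
                 alpha_light = 0.1)
  s <- random_schedule(300, 5, compound = TRUE)
  traj <- rw_simulate(s, p)
  dtone <- diff(traj$v_tone)
  tone_absent <- s$cs[-nrow(s)] == "light"
  expect_true(all(dtone[tone_absent] == 0))
  dplan <- diff(traj$v_plan)
  moving <- abs(traj$spe[-nrow(s)]) > 1e-12
  expect_true(all(dplan[moving] != 0))
})

test_that("trajectory effects show the conditioning signatures", {
  s <- make_differential_schedule(600, 200, seed = 1)
  traj <- rw_simulate(s, rw_params())
  acq <- trajectory_effects(traj$v_total, s, "acquisition")
  probe <- trajectory_effects(traj$v_total, s, "probe")
  expect_gt(acq$pavlovian, 0)
  expect_gt(probe$pavlovian, 0)
  expect_gt(acq$adaptation, 0)
  # the CS+/CS- difference is larger on trials following a CS- than a CS+
  expect_gt(acq$cells["-", "+"] - acq$cells["-", "-"],
            acq$cells["+", "+"] - acq$cells["+", "-"])
  # a constant heading series yields all-zero cells
  zero <- trajectory_effects(rep(3, 800), s, "acquisition")
  expect_true(all(zero$cells == 0))

  ss <- ss_simulate(s, ss_params())
  expect_identical(predicted_cs_contrast(ss, "acquisition"), 0)
  expect_identical(predicted_cs_contrast(ss, "probe"), 0)
  expect_gt(predicted_cs_contrast(traj, "acquisition"), 0)
})

test_that("compound strengths are exactly additive and overshadowing emerges", {
  s <- make_compound_schedule(600, 100, seed = 2)
  pairs <- list(c(0.02, 0.18), c(0.06, 0.14), c(0.1, 0.1), c(0.14, 0.06),
                c(0.18, 0.02))
  v_tone_end <- v_light_end <- tone_resp <- light_resp <- numeric(0)
  for (al in pairs) {
    p <- rw_params(lam = 15, beta = 0.02, alpha_plan = 0.99,
                   alpha_tone = al[1], alpha_light = al[2])
    traj <- rw_simulate(s, p)
    on_comp <- s$cs == "compound"
    expect_equal(traj$v_total[on_comp],
                 (traj$v_plan + traj$v_tone + traj$v_light)[on_comp])
    v_tone_end <- c(v_tone_end, traj$v_tone[600])
    v_light_end <- c(v_light_end, traj$v_light[600])
    probe <- s$phase == "probe"
    tone_resp <- c(tone_resp, mean(traj$v_tone[probe & s$cs == "tone"]))
    light_resp <- c(light_resp, mean(traj$v_light[probe & s$cs == "light"]))
  }
  expect_true(all(diff(v_tone_end) > 0))   # increasing in alpha_tone
  expect_true(all(diff(v_light_end) < 0))  # decreasing as alpha_light falls
  expect_lt(cor(tone_resp, light_resp), 0)
})

test_that("RW without cue saliences reduces to a state-space model on constant-US schedules", {
  s <- all_csplus_schedule(400)
  ap <- 0.8; beta <- 0.15; lam <- 15
  rw <- rw_simulate(s, rw_params(lam = lam, beta = beta, alpha_plan = ap,
                                 alpha_tone = 0, alpha_light = 0))
  A <- 1 - ap * beta
  B <- ap * beta * lam / 15
  ss <- ss_simulate(s, ss_params(A = A, B = B))
  expect_equal(rw$v_total, ss$x, tolerance = 1e-12)
})

test_that("parameter sweeps honor the grid and the model structure", {
  scheds <- lapply(1:2, function(i) make_differential_schedule(200, 0, seed = i))
  g <- sweep_pavlovian("ss", list(A = c(0.8, 0.9), B = c(0.1, 0.2)), scheds,
                       phase = "acquisition")
  expect_equal(nrow(g), 4)
  expect_true(all(g$pavlovian == 0))
  gr <- sweep_pavlovian("rw", list(alpha_cs = c(0, 0.001, 0.01, 0.05)),
                        scheds, phase = "acquisition")
  expect_equal(gr$pavlovian[1], 0)       # zero salience row is exactly zero
  expect_true(all(diff(gr$pavlovian) > 0))  # effect grows with salience
  expect_error(sweep_pavlovian("ss", list(alpha_cs = 0.1), scheds), "axes")
})
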