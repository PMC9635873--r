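# Minimal preprocessed-participant scaffold for effects tests: a chain of
# trial-level CS types with the implied consecutive deltas.
fake_pre <- function(types, delta, id = "p01", phase = "acquisition") {
  n <- length(types)
  stopifnot(length(delta) == n - 1)
  tibble::tibble(participant_id = id, phase = phase, trial = seq_len(n),
                 cs = ifelse(types == "+", "tone", "light"),
                 cs_type = types,
                 delta = c(NA, delta), delta_valid = c(FALSE, rep(TRUE, n - 1)))
}

test_that("cell statistics group deltas by the previous/current CS pair", {
  # chain +,+,-,-,+ yields singleton cells (+,+)=1, (+,-)=1, (-,-)=2, (-,+)=2
  pre <- fake_pre(c("+", "+", "-", "-", "+"), delta = c(1, 1, 2, 2))
  cs <- cell_stats(pre, "acquisition")
  expect_equal(unname(cs$cells), matrix(c(1, 2, 1, 2), 2))
  expect_equal(cs$pavlovian, 0)
  expect_equal(cs$adaptation, -1)

  same <- fake_pre(c("+", "+", "-", "-", "+"), rep(0.4, 4))
  cs2 <- cell_stats(same, "acquisition")
  expect_true(all(cs2$cells == 0.4))
  expect_equal(cs2$pavlovian, 0)
  expect_equal(cs2$interaction, 0)
})

test_that("cell statistics match a brute-force grouping loop on random series", {
  withr::with_seed(11, {
    s <- make_differential_schedule(200, 0, seed = 31)
    cfg <- synthetic_config(sigma_m = 3, p_slow = 0.05)
    pre <- preprocess_participant(generate_participant(s, cfg, seed = 1))
    got <- cell_stats(pre, "acquisition")
    # brute force
    acc <- list(`++` = c(), `+-` = c(), `-+` = c(), `--` = c())
    for (n in 2:200) {
      if (!pre$delta_valid[n]) next
      key <- paste0(pre$cs_type[n - 1], pre$cs_type[n])
      acc[[key]] <- c(acc[[key]], pre$theta[n] - pre$theta[n - 1])
    }
    expect_equal(got$cells["+", "+"], mean(acc[["++"]]))
    expect_equal(got$cells["+", "-"], mean(acc[["+-"]]))
    expect_equal(got$cells["-", "+"], mean(acc[["-+"]]))
    expect_equal(got$cells["-", "-"], mean(acc[["--"]]))
    # conservation: overall mean equals the count-weighted cell mean
    w <- lengths(acc)
    expect_equal(sum(vapply(acc, mean, numeric(1)) * w) / sum(w),
                 mean(pre$delta[pre$delta_valid]))
  })
  expect_error(cell_stats(fake_pre(c("+", "+"), 1), "acquisition"),
               "empty cell")
})

test_that("repeated-measures ANOVA matches the longhand decomposition and paired t", {
  withr::with_seed(21, {
    cells <- tibble::tibble(participant_id = sprintf("p%02d", 1:8),
                            pp = rnorm(8), pm = rnorm(8), mp = rnorm(8),
                            mm = rnorm(8))
    got <- rm_anova_2x2(cells)
    want <- anova2x2_longhand(cells)
    for (eff in c("previous", "current", "interaction")) {
      expect_equal(got[[eff]]$F, want[[eff]]$F, tolerance = 1e-10)
      expect_equal(got[[eff]]$eta_p2, want[[eff]]$eta_p2, tolerance = 1e-10)
      expect_true(got[[eff]]$eta_p2 >= 0 && got[[eff]]$eta_p2 <= 1)
    }
    # F of a 2-level within factor equals the squared paired t statistic
    tprev <- t.test((cells$pp + cells$pm) / 2, (cells$mp + cells$mm) / 2,
                    paired = TRUE)
    expect_lt(abs(got$previous$F - unname(tprev$statistic)^2), 1e-8)
    expect_equal(got$previous$p, tprev$p.value, tolerance = 1e-10)
    tcur <- t.test((cells$pp + cells$mp) / 2, (cells$pm + cells$mm) / 2,
                   paired = TRUE)
    expect_lt(abs(got$current$F - unname(tcur$statistic)^2), 1e-8)
    # Cohen's d for the paired contrast is mean/sd of the differences
    dcur <- (cells$pp + cells$mp) / 2 - (cells$pm + cells$mm) / 2
    expect_equal(got$current$cohen_d, mean(dcur) / sd(dcur))
  })
})

test_that("hand-built 4-participant table reproduces the longhand sums of squares", {
  cells <- tibble::tibble(participant_id = c("a", "b", "c", "d"),
                          pp = c(1.0, 0.8, 1.2, 0.9),
                          pm = c(0.2, 0.1, 0.4, 0.3),
                          mp = c(1.4, 1.1, 1.5, 1.2),
                          mm = c(0.1, 0.0, 0.2, 0.15))
  got <- rm_anova_2x2(cells)
  want <- anova2x2_longhand(cells)
  for (eff in c("previous", "current", "interaction"))
    expect_equal(got[[eff]]$F, want[[eff]]$F, tolerance = 1e-12)
  expect_equal(got$current$df, c(1, 3))
})

test_that("degenerate ANOVA inputs raise errors", {
  same <- tibble::tibble(participant_id = c("a", "b", "c"),
                         pp = 1, pm = 1, mp = 1, mm = 1)
  expect_error(rm_anova_2x2(same), "degenerate")
  expect_error(rm_anova_2x2(same[1:2, ]), "at least 3")
  miss <- same; miss$pp[1] <- NA
  expect_error(rm_anova_2x2(miss), "incomplete")
})

test_that("binned regression recovers exact linear structure and flags rank deficiency", {
  s <- make_differential_schedule(200, 0, seed = 13)
  type <- ifelse(s$cs == "tone", 1, -1)
  # build a heading series whose deltas are an exact function of the codes
  delta <- 0.7 * type[-1] + 0.4 * type[-200] - 0.2 * type[-1] * type[-200] + 0.05
  pre <- tibble::tibble(participant_id = "p01", phase = "acquisition",
                        trial = 1:200, cs = s$cs,
                        cs_type = ifelse(type == 1, "+", "-"),
                        delta = c(NA, delta),
                        delta_valid = c(FALSE, rep(TRUE, 199)))
  bd <- binned_dynamics(pre, bin_width = 50)
  expect_equal(nrow(bd), 12)
  expect_equal(bd$weight[bd$term == "current"], rep(0.7, 4), tolerance = 1e-10)
  expect_equal(bd$weight[bd$term == "previous"], rep(0.4, 4), tolerance = 1e-10)
  expect_equal(bd$weight[bd$term == "interaction"], rep(-0.2, 4),
               tolerance = 1e-10)
  # degenerate bin: only one valid pair
  pre2 <- pre
  pre2$delta_valid[2:49] <- FALSE
  bd2 <- binned_dynamics(pre2, bin_width = 50)
  expect_true(all(is.na(bd2$weight[bd2$bin == 1])))
})

test_that("Friedman analysis matches the longhand rank formula and ties give zero", {
  # three participants, three conditions, no ties
  coh <- do.call(rbind, lapply(1:3, function(i) {
    s <- make_compound_schedule(10, 5, seed = i)
    cfg <- synthetic_config(params = rw_params(experiment = "exp4"),
                            sigma_m = 1, p_slow = 0, outlier_rate = 0)
    generate_participant(s, cfg, seed = i, participant_id = sprintf("p%02d", i))
  }))
  pre <- preprocess_cohort(coh)
  res <- compound_probe_analysis(pre)
  mat <- as.matrix(res$medians[, c("compound", "tone", "light")])
  expect_equal(res$friedman$chisq, friedman_longhand(mat), tolerance = 1e-10)
  expect_equal(res$friedman$W, res$friedman$chisq / (3 * 2))
  expect_equal(res$pairwise$p_bonf, pmin(1, res$pairwise$p_raw * 3))

  # fully tied medians: no rank information, statistic 0
  tied <- res$medians
  tied$tone <- tied$light <- tied$compound
  mat2 <- as.matrix(tied[, c("compound", "tone", "light")])
  expect_equal(friedman_longhand(mat2), 0)
})

test_that("compound probe shows the additivity ordering on noiseless simulations", {
  coh <- do.call(rbind, lapply(1:4, function(i) {
    s <- make_compound_schedule(600, 100, seed = i)
    cfg <- synthetic_config(params = rw_params(experiment = "exp4"),
                            sigma_m = 0, p_slow = 0, outlier_rate = 0)
    generate_participant(s, cfg, seed = i, participant_id = sprintf("p%02d", i))
  }))
  pre <- preprocess_cohort(coh)
  res <- compound_probe_analysis(pre)
  expect_true(all(res$medians$compound > res$medians$tone))
  expect_true(all(res$medians$compound > res$medians$light))
  pooled <- pooled_singleton_anova(pre)
  expect_gt(pooled$current$mean_diff, 0)  # compound > singleton
})

test_that("pooled singleton ANOVA equals the ANOVA on manually pooled cells", {
  withr::with_seed(5, {
    coh <- generate_cohort("exp4_compound", 6,
                           synthetic_config(params = rw_params(experiment = "exp4"),
                                            sigma_m = 2),
                           seed = 7, n_acq = 200, n_probe = 40)
    pre <- preprocess_cohort(coh)
    got <- pooled_singleton_anova(pre)
    cells <- do.call(rbind, lapply(split(pre, pre$participant_id), function(p) {
      i <- which(p$phase == "probe" & p$delta_valid)
      prev <- ifelse(p$cs[i - 1] == "compound", "+", "-")
      cur <- ifelse(p$cs[i] == "compound", "+", "-")
      d <- p$delta[i]
      tibble::tibble(participant_id = unique(p$participant_id),
                     pp = mean(d[prev == "+" & cur == "+"]),
                     pm = mean(d[prev == "+" & cur == "-"]),
                     mp = mean(d[prev == "-" & cur == "+"]),
                     mm = mean(d[prev == "-" & cur == "-"]))
    }))
    want <- rm_anova_2x2(cells)
    expect_equal(got$current$F, want$current$F, tolerance = 1e-10)
    expect_equal(got$previous$F, want$previous$F, tolerance = 1e-10)
  })
})

test_that("overshadowing correlation behaves at its edge cases", {
  a <- c(0.1, 0.5, 0.3, 0.8, 0.2)
  perfect <- overshadow_correlation(a, 1 - a)
  expect_equal(perfect$r, -1)
  expect_error(overshadow_correlation(rep(1, 4), a[1:4]), "zero variance")
  expect_error(overshadow_correlation(a, a[1:3]))
  # independent draws are uncorrelated on average
  withr::with_seed(2, {
    rs <- replicate(200, overshadow_correlation(rnorm(10), rnorm(10))$r)
    expect_lt(abs(mean(rs)), 0.05)
  })
})
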