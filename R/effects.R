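# The statistical effect computations: 2x2 repeated-measures ANOVA on the
# trial-to-trial heading changes, Pavlovian/adaptation contrasts, binned
# dynamics regression, compound-probe Friedman analysis, overshadowing
# correlation, and the pooled singleton-vs-compound ANOVA.

# Pairs (prev trial, current trial) of valid deltas within a phase for one
# preprocessed participant.
valid_pairs <- function(pre, phase) {
  i <- which(pre$phase == phase & pre$delta_valid)
  data.frame(delta = pre$delta[i],
             prev_type = pre$cs_type[i - 1],
             cur_type = pre$cs_type[i],
             prev_cs = pre$cs[i - 1],
             cur_cs = pre$cs[i],
             trial = pre$trial[i],
             stringsAsFactors = FALSE)
}

#' Per-participant 2x2 cell statistics of the heading changes
#'
#' Cell (i, j) is the mean (or median) valid trial-to-trial heading change
#' over trials with CS type i on the previous trial and CS type j on the
#' current trial, within a phase.
#'
#' @param pre One participant's preprocessed records
#'   ([preprocess_participant()]).
#' @param phase `"acquisition"` or `"probe"`.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return A list as returned by the 2x2 cell summary: `cells` matrix plus
#'   `pavlovian`, `adaptation` and `interaction` contrasts (degrees).
#' @export
cell_stats <- function(pre, phase = c("acquisition", "probe"),
                       statistic = c("mean", "median")) {
  phase <- match.arg(phase)
  vp <- valid_pairs(pre, phase)
  delta_cells(vp$delta, vp$prev_type, vp$cur_type, statistic = statistic,
              who = sprintf("participant %s, %s phase",
                            unique(pre$participant_id), phase))
}

#' Cohort table of cell means and per-participant contrasts
#'
#' @param cohort_pre Preprocessed cohort ([preprocess_cohort()]).
#' @inheritParams cell_stats
#' @return A tibble with one row per participant: cells `pp`, `pm`, `mp`,
#'   `mm` (previous/current CS type, `p` = CS+, `m` = CS-) and the
#'   `pavlovian` and `adaptation` contrasts.
#' @export
cohort_cells <- function(cohort_pre, phase = c("acquisition", "probe"),
                         statistic = c("mean", "median")) {
  phase <- match.arg(phase)
  statistic <- match.arg(statistic)
  parts <- split(cohort_pre,
                 factor(cohort_pre$participant_id,
                        levels = unique(cohort_pre$participant_id)))
  rows <- lapply(parts, function(p) {
    cs <- cell_stats(p, phase, statistic)
    tibble::tibble(participant_id = unique(p$participant_id),
                   pp = cs$cells["+", "+"], pm = cs$cells["+", "-"],
                   mp = cs$cells["-", "+"], mm = cs$cells["-", "-"],
                   pavlovian = cs$pavlovian, adaptation = cs$adaptation)
  })
  do.call(rbind, rows)
}

#' Two-way repeated-measures ANOVA on the 2x2 cells
#'
#' Within-subject ANOVA with factors previous-trial CS and current-trial CS
#' (two levels each). Reports F, p and partial eta squared for the two main
#' effects (adaptation and Pavlovian) and their interaction, plus the group
#' mean difference and 95% CI for each contrast. For a two-level
#' within-subject factor the F statistic equals the squared paired t
#' statistic on the collapsed cell means.
#'
#' @param cells Cohort cell table ([cohort_cells()]): columns
#'   `participant_id`, `pp`, `pm`, `mp`, `mm`.
#' @return A list of per-effect results (`previous`, `current`,
#'   `interaction`), each with `F`, `df`, `p`, `eta_p2`, `mean_diff`,
#'   `ci95`.
#' @export
rm_anova_2x2 <- function(cells) {
  stopifnot(all(c("pp", "pm", "mp", "mm") %in% names(cells)))
  n <- nrow(cells)
  if (n < 3) stop("need at least 3 participants")
  if (any(!stats::complete.cases(cells[, c("pp", "pm", "mp", "mm")])))
    stop("incomplete cells")
  long <- data.frame(
    id = factor(rep(seq_len(n), 4)),
    prev = factor(rep(c("+", "+", "-", "-"), each = n), levels = c("+", "-")),
    cur = factor(rep(c("+", "-", "+", "-"), each = n), levels = c("+", "-")),
    value = c(cells$pp, cells$pm, cells$mp, cells$mm))
  fit <- stats::aov(value ~ prev * cur + Error(id / (prev * cur)),
                    data = long)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    row <- trimws(rownames(tab)) == term
    err <- trimws(rownames(tab)) == "Residuals"
    ss_eff <- tab[row, "Sum Sq"]; ss_err <- tab[err, "Sum Sq"]
    if (!is.finite(ss_err) || ss_err < 1e-24)
      stop("zero within-subject error variance for effect '", term,
           "': the ANOVA is degenerate")
    list(F = tab[row, "F value"], df = c(tab[row, "Df"], tab[err, "Df"]),
         p = tab[row, "Pr(>F)"], eta_p2 = ss_eff / (ss_eff + ss_err))
  }
  contrasts <- list(
    previous = (cells$pp + cells$pm) / 2 - (cells$mp + cells$mm) / 2,
    current = (cells$pp + cells$mp) / 2 - (cells$pm + cells$mm) / 2,
    interaction = cells$pp - cells$pm - cells$mp + cells$mm)
  out <- list(previous = pull("Error: id:prev", "prev"),
              current = pull("Error: id:cur", "cur"),
              interaction = pull("Error: id:prev:cur", "prev:cur"))
  for (nm in names(out)) {
    d <- contrasts[[nm]]
    tt <- stats::t.test(d)
    out[[nm]]$mean_diff <- mean(d)
    out[[nm]]$ci95 <- unname(tt$conf.int)
    out[[nm]]$cohen_d <- mean(d) / stats::sd(d)
  }
  out$n <- n
  class(out) <- "rm_anova_2x2"
  out
}

#' @export
print.rm_anova_2x2 <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (N = %d)\n", x$n))
  for (nm in c("previous", "current", "interaction")) {
    e <- x[[nm]]
    cat(sprintf(
      "  %-11s F(%d, %d) = %6.2f, p = %.4g, eta_p2 = %.3f, diff = %.3f [%.3f %.3f]\n",
      nm, e$df[1], e$df[2], e$F, e$p, e$eta_p2, e$mean_diff,
      e$ci95[1], e$ci95[2]))
  }
  invisible(x)
}

#' Binned dynamics regression of the heading changes
#'
#' Splits the acquisition phase into consecutive bins (default 50 trials) and
#' regresses, per bin, the valid heading changes on the coded previous-trial
#' CS, current-trial CS and their product (CS+ = +1, CS- = -1, so main-effect
#' weights are half-differences). Bins whose design matrix is rank-deficient
#' get missing weights.
#'
#' @param pre One participant's preprocessed records.
#' @param bin_width Trials per bin (default 50).
#' @return A tibble with `bin`, `term` (`previous`, `current`,
#'   `interaction`), and `weight` (degrees).
#' @export
binned_dynamics <- function(pre, bin_width = 50) {
  acq <- pre[pre$phase == "acquisition", ]
  n_bins <- nrow(acq) %/% bin_width
  if (n_bins < 2) stop("acquisition phase shorter than 2 bins")
  idx <- which(pre$phase == "acquisition" & pre$delta_valid)
  bin <- (match(idx, which(pre$phase == "acquisition")) - 1) %/% bin_width + 1
  code <- function(t) ifelse(t == "+", 1, -1)
  rows <- lapply(seq_len(n_bins), function(b) {
    i <- idx[bin == b]
    out <- tibble::tibble(bin = b,
                          term = c("previous", "current", "interaction"),
                          weight = NA_real_)
    if (length(i) >= 4) {
      df <- data.frame(delta = pre$delta[i],
                       prev = code(pre$cs_type[i - 1]),
                       cur = code(pre$cs_type[i]))
      X <- cbind(1, df$prev, df$cur, df$prev * df$cur)
      if (qr(X)$rank == 4) {
        fit <- stats::lm(delta ~ prev + cur + prev:cur, data = df)
        cf <- stats::coef(fit)
        out$weight <- unname(cf[c("prev", "cur", "prev:cur")])
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Cohort-level dynamics of the adaptation and Pavlovian effects
#'
#' Runs [binned_dynamics()] per participant, summarizes the per-bin group
#' mean weights, fits a per-participant OLS slope of each weight series over
#' bin index, and tests the slopes at the group level: one-sample t tests per
#' effect type and a paired t test between the Pavlovian (current) and
#' adaptation (previous) slopes. This per-participant slope + paired-t
#' scheme approximates a mixed-model type x bin interaction test.
#'
#' @param cohort_pre Preprocessed cohort.
#' @param bin_width Trials per bin.
#' @return A list: `weights` (participant x bin x term tibble),
#'   `group_weights` (mean +/- SEM per bin/term), `slopes` (per participant
#'   and term), `tests` (one-sample t per term and the current-vs-previous
#'   paired t).
#' @export
cohort_dynamics <- function(cohort_pre, bin_width = 50) {
  parts <- split(cohort_pre,
                 factor(cohort_pre$participant_id,
                        levels = unique(cohort_pre$participant_id)))
  w <- do.call(rbind, lapply(parts, function(p) {
    bd <- binned_dynamics(p, bin_width)
    bd$participant_id <- unique(p$participant_id)
    bd
  }))
  agg <- stats::aggregate(weight ~ bin + term, data = w,
                          FUN = function(v) c(mean = mean(v),
                                              sem = stats::sd(v) / sqrt(length(v))))
  group_weights <- tibble::tibble(bin = agg$bin, term = agg$term,
                                  mean = agg$weight[, "mean"],
                                  sem = agg$weight[, "sem"])
  slope_of <- function(d) {
    ok <- is.finite(d$weight)
    if (sum(ok) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(weight ~ bin, data = d[ok, ]))[2])
  }
  sl <- expand.grid(participant_id = unique(w$participant_id),
                    term = c("previous", "current"),
                    stringsAsFactors = FALSE)
  sl$slope <- mapply(function(id, tm)
    slope_of(w[w$participant_id == id & w$term == tm, ]),
    sl$participant_id, sl$term)
  s_prev <- sl$slope[sl$term == "previous"]
  s_cur <- sl$slope[sl$term == "current"]
  tests <- list(previous = stats::t.test(s_prev),
                current = stats::t.test(s_cur),
                current_vs_previous = stats::t.test(s_cur, s_prev,
                                                    paired = TRUE))
  list(weights = tibble::as_tibble(w), group_weights = group_weights,
       slopes = tibble::as_tibble(sl), tests = tests)
}

#' Compound-probe analysis (Friedman test over CS types)
#'
#' For the compound design's probe phase: per participant, the median valid
#' heading change for compound, tone-alone and light-alone trials (current
#' trial CS, regardless of the previous trial); a Friedman test over the
#' three conditions with Kendall's W effect size; and pairwise Wilcoxon
#' signed-rank tests, Bonferroni-corrected (p multiplied by 3, capped at 1).
#'
#' @param cohort_pre Preprocessed compound-design cohort.
#' @return A list: `medians` (participant x condition tibble), `friedman`
#'   (`chisq`, `df`, `p`, `W`), `pairwise` (tibble of comparisons with raw
#'   and corrected p).
#' @export
compound_probe_analysis <- function(cohort_pre) {
  parts <- split(cohort_pre,
                 factor(cohort_pre$participant_id,
                        levels = unique(cohort_pre$participant_id)))
  conds <- c("compound", "tone", "light")
  med <- do.call(rbind, lapply(parts, function(p) {
    vp <- valid_pairs(p, "probe")
    m <- vapply(conds, function(cc) {
      v <- vp$delta[vp$cur_cs == cc]
      if (!length(v)) stop("participant ", unique(p$participant_id),
                           " has no valid probe trials with CS '", cc, "'")
      stats::median(v)
    }, numeric(1))
    tibble::tibble(participant_id = unique(p$participant_id),
                   compound = m["compound"], tone = m["tone"],
                   light = m["light"])
  }))
  mat <- as.matrix(med[, conds])
  N <- nrow(mat); k <- ncol(mat)
  if (all(apply(mat, 1, stats::var) == 0)) {
    # every participant fully tied across conditions: no rank information
    fr <- list(statistic = 0, parameter = k - 1,
               p.value = 1)
  } else {
    fr <- stats::friedman.test(mat)
  }
  W <- unname(fr$statistic) / (N * (k - 1))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    wt <- stats::wilcox.test(mat[, pr[1]], mat[, pr[2]], paired = TRUE,
                             exact = FALSE)
    tibble::tibble(a = pr[1], b = pr[2], p_raw = wt$p.value,
                   p_bonf = min(1, wt$p.value * length(pairs)))
  }))
  list(medians = med,
       friedman = list(chisq = unname(fr$statistic),
                       df = unname(fr$parameter), p = fr$p.value, W = W),
       pairwise = pairwise)
}

#' Overshadowing correlation between elemental probe responses
#'
#' Pearson correlation, across participants, between the tone-alone and
#' light-alone probe heading-change summaries. A negative correlation is the
#' overshadowing signature: associative strength gained by one element of
#' the compound comes at the expense of the other.
#'
#' @param tone,light Per-participant tone-alone and light-alone probe
#'   heading-change means (degrees), equal length >= 3.
#' @return A list with `r`, `p` and `n`.
#' @export
overshadow_correlation <- function(tone, light) {
  stopifnot(length(tone) == length(light), length(tone) >= 3)
  if (stats::sd(tone) == 0 || stats::sd(light) == 0)
    stop("zero variance in elemental responses; correlation undefined")
  ct <- stats::cor.test(tone, light, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(tone))
}

#' Per-participant elemental probe responses
#'
#' Mean valid probe-phase heading change on tone-alone and light-alone
#' trials, per participant: the inputs to [overshadow_correlation()].
#'
#' @param cohort_pre Preprocessed compound-design cohort.
#' @return A tibble with `participant_id`, `tone`, `light` (degrees).
#' @export
elemental_probe_means <- function(cohort_pre) {
  parts <- split(cohort_pre,
                 factor(cohort_pre$participant_id,
                        levels = unique(cohort_pre$participant_id)))
  do.call(rbind, lapply(parts, function(p) {
    vp <- valid_pairs(p, "probe")
    tibble::tibble(participant_id = unique(p$participant_id),
                   tone = mean(vp$delta[vp$cur_cs == "tone"]),
                   light = mean(vp$delta[vp$cur_cs == "light"]))
  }))
}

#' Pooled singleton-vs-compound ANOVA on the compound probe
#'
#' Pools the tone-alone and light-alone probe trials into a "singleton"
#' level and runs the two-way repeated-measures ANOVA on (previous CS type)
#' x (current CS type), compound vs singleton.
#'
#' @param cohort_pre Preprocessed compound-design cohort.
#' @param statistic Cell statistic, `"mean"` (default) or `"median"`.
#' @return An [rm_anova_2x2()] result; the `current` effect is the Pavlovian
#'   compound-vs-singleton contrast.
#' @export
pooled_singleton_anova <- function(cohort_pre, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  parts <- split(cohort_pre,
                 factor(cohort_pre$participant_id,
                        levels = unique(cohort_pre$participant_id)))
  cells <- do.call(rbind, lapply(parts, function(p) {
    vp <- valid_pairs(p, "probe")
    # compound counts as "+", singletons (tone/light alone) as "-"
    cs <- delta_cells(vp$delta, vp$prev_type, vp$cur_type,
                      statistic = statistic,
                      who = sprintf("participant %s (pooled probe)",
                                    unique(p$participant_id)))
    tibble::tibble(participant_id = unique(p$participant_id),
                   pp = cs$cells["+", "+"], pm = cs$cells["+", "-"],
                   mp = cs$cells["-", "+"], mm = cs$cells["-", "-"])
  }))
  rm_anova_2x2(cells)
}
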