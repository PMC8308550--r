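# The statistics stage: repeated-measures ANOVA, baseline contrasts,
# Wilcoxon signed-rank, summaries, and comment tabulation.

toy_long <- function(seed = 1, S = 6, weeks = c(0, 2, 4),
                     herbal_shift = -1) {
  set.seed(seed)
  g <- expand.grid(participant = sprintf("P%02d", 1:S),
                   thigh = c("placebo", "herbal"), week = weeks,
                   stringsAsFactors = FALSE)
  g$outcome <- "y"
  g$value <- 10 - 0.2 * g$week + ifelse(g$thigh == "herbal",
                                        herbal_shift * g$week / 4, 0) +
    rnorm(nrow(g), 0, 0.7) +
    rep(rnorm(S, 0, 1), times = nrow(g) / S)
  g
}

test_that("rm_anova agrees with the within-subject aov decomposition", {
  d <- toy_long()
  got <- rm_anova(d, "y")
  fit <- stats::aov(value ~ thigh * factor(week) +
                      Error(factor(participant) / (thigh * factor(week))),
                    data = d)
  s <- summary(fit)
  pick <- function(stratum, row)
    s[[stratum]][[1]][row, c("Sum Sq", "F value", "Pr(>F)")]
  a_treat <- pick("Error: factor(participant):thigh", "thigh")
  a_week <- pick("Error: factor(participant):factor(week)", "factor(week)")
  a_int <- pick("Error: factor(participant):thigh:factor(week)",
                "thigh:factor(week)")
  expect_equal(got$ss[got$effect == "treatment"], a_treat[["Sum Sq"]],
               tolerance = 1e-9)
  expect_equal(got$F[got$effect == "treatment"], a_treat[["F value"]],
               tolerance = 1e-9)
  expect_equal(got$p[got$effect == "treatment"], a_treat[["Pr(>F)"]],
               tolerance = 1e-9)
  expect_equal(got$ss[got$effect == "week"], a_week[["Sum Sq"]],
               tolerance = 1e-9)
  expect_equal(got$F[got$effect == "week"], a_week[["F value"]],
               tolerance = 1e-9)
  expect_equal(got$ss[got$effect == "treatment:week"], a_int[["Sum Sq"]],
               tolerance = 1e-9)
  expect_equal(got$F[got$effect == "treatment:week"], a_int[["F value"]],
               tolerance = 1e-9)
})

test_that("rm_anova sum of squares decomposes the total exactly", {
  for (seed in 1:5) {
    d <- toy_long(seed = seed, S = 5, weeks = c(0, 2, 8, 12))
    got <- rm_anova(d, "y")
    expect_equal(sum(got$ss), attr(got, "ss_total"),
                 tolerance = 1e-8 * max(1, attr(got, "ss_total")))
    expect_true(all(got$ss >= 0))
  }
})

test_that("rm_anova handles degenerate and structured inputs", {
  d <- toy_long()
  d$value <- 5
  got <- rm_anova(d, "y")
  expect_true(all(got$ss == 0))
  expect_true(all(is.na(got$F)))
  # pure time trend, no treatment difference, no noise
  d2 <- toy_long()
  d2$value <- 10 - 0.2 * d2$week
  got2 <- rm_anova(d2, "y")
  expect_equal(got2$ss[got2$effect == "treatment"], 0, tolerance = 1e-18)
  expect_gt(got2$ss[got2$effect == "week"], 0)
  # permuting participant labels leaves the table unchanged
  d3 <- toy_long(seed = 4)
  perm <- setNames(sprintf("Q%02d", sample(6)), sprintf("P%02d", 1:6))
  d4 <- d3; d4$participant <- unname(perm[d3$participant])
  expect_equal(rm_anova(d3, "y")$ss, rm_anova(d4, "y")$ss,
               tolerance = 1e-10)
  # unbalanced data is refused with advice
  expect_error(rm_anova(d3[-1, ], "y"), "completers",
               class = "cm_unbalanced")
  # one-way variant
  one <- rm_anova(d3, "y", model = "one_way", arm = "herbal")
  expect_setequal(one$effect, c("subject", "week", "error"))
  expect_equal(sum(one$ss), attr(one, "ss_total"), tolerance = 1e-8)
})

test_that("baseline contrasts behave on null, single, and effect cases", {
  d <- toy_long(seed = 2)
  # identical to baseline: zero difference, p = 1
  d0 <- d; d0$value <- rep(d0$value[d0$week == 0], times = 3)
  r0 <- baseline_contrasts(d0, "y", arm = "herbal")
  expect_true(all(abs(r0$mean_diff) < 1e-12))
  expect_true(all(r0$p_raw == 1))
  # single post-baseline week: adjustment is the identity
  d1 <- d[d$week %in% c(0, 2), ]
  r1 <- baseline_contrasts(d1, "y", arm = "herbal")
  expect_equal(r1$p_adj, r1$p_raw)
  # Bonferroni inflates but caps at 1
  r <- baseline_contrasts(d, "y", arm = "herbal")
  expect_true(all(r$p_adj >= r$p_raw))
  expect_true(all(r$p_adj <= 1))
  expect_equal(r$p_adj, pmin(1, 2 * r$p_raw))
  expect_error(baseline_contrasts(d[d$week == 0, ], "y"),
               class = "cm_invalid_input")
})

test_that("an abstract-sized treatment effect is detected at week 12", {
  wk <- function(v) stats::setNames(v, c("0", "2", "4", "8", "12", "14"))
  cfg <- trial_config(outcome_models = list(css = list(
    trajectory = list(placebo = wk(c(12.9, 12.7, 12.5, 12.4, 12.3, 12.5)),
                      herbal = wk(c(13.4, 12.1, 11.7, 10.8, 9.9, 10.4))),
    participant_sd = 1, residual_sd = 0.8)))
  hits <- 0L
  for (s in 1:200) {
    ds <- completers(simulate_trial(cfg, seed = s))
    r <- baseline_contrasts(ds, "css", arm = "herbal")
    if (r$p_adj[r$week == 12] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.9)
})

test_that("wilcoxon signed-rank matches exhaustive enumeration", {
  # the fixed 5-pair case
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 1)
  got <- wilcoxon_signed_rank(x, y)
  expect_equal(got$p, wilcoxon_enum(x - y), tolerance = 1e-12)
  expect_true(got$W >= 0 &&
                got$W <= got$n_nonzero * (got$n_nonzero + 1) / 2)
  # random paired data with zeros and ties
  set.seed(31)
  for (i in 1:20) {
    d <- sample(-3:3, 9, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$p, wilcoxon_enum(d), tolerance = 1e-12)
    expect_equal(got$method, "exact")
  }
  # tie-free data agrees with the standard exact test
  set.seed(7)
  for (i in 1:10) {
    d <- round(rnorm(10), 3)
    if (any(d == 0) || anyDuplicated(abs(d))) next
    ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(wilcoxon_signed_rank(d)$p, ref, tolerance = 1e-12)
  }
})

test_that("wilcoxon edge cases and approximation behave", {
  # single pair: both sign assignments equally extreme -> p = 1
  one <- wilcoxon_signed_rank(3)
  expect_equal(one$p, 1)
  # symmetric swap: all-zero differences -> degenerate p = 1
  z <- wilcoxon_signed_rank(c(2, 5, 1), c(2, 5, 1))
  expect_true(z$degenerate)
  expect_equal(z$p, 1)
  expect_equal(z$n_nonzero, 0L)
  # mirrored pairs: W at the distribution centre, p = 1
  d <- c(2, -2, 1.5, -1.5)
  m <- wilcoxon_signed_rank(d)
  expect_equal(m$W, sum(rank(abs(d))) / 2)
  expect_equal(m$p, 1)
  # normal approximation tracks the exact path for n >= 10
  set.seed(13)
  for (i in 1:20) {
    d <- round(rnorm(12, 0.3, 1), 2)
    d <- d[d != 0]
    if (length(d) < 10) next
    pe <- wilcoxon_signed_rank(d)$p
    pa <- wilcoxon_signed_rank(d, exact_limit = 0)$p
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("summaries report n, mean, SD and SEM per cell", {
  d <- data.frame(participant = c("A", "B", "C", "A"),
                  thigh = c("herbal", "herbal", "herbal", "placebo"),
                  week = 0, outcome = "y", value = c(1, 2, 3, 4))
  s <- summarize_trial(d)
  h <- s[s$thigh == "herbal", ]
  expect_equal(h$mean, 2)
  expect_equal(h$sd, 1)
  expect_equal(h$sem, 1 / sqrt(3))
  p <- s[s$thigh == "placebo", ]
  expect_equal(p$sd, 0)
  expect_true(p$single_n)
  # identical values: SD and SEM are zero
  d2 <- d; d2$value <- 7
  expect_true(all(summarize_trial(d2)$sd == 0))
})

test_that("summaries recover configured circumference means in simulation", {
  ds <- completers(simulate_trial(trial_config(), seed = 6))
  s <- summarize_trial(ds, "circumference_lower")
  b <- s[s$thigh == "placebo" & s$week == 0, ]
  sem_cfg <- sqrt(4^2 + 0.3^2) / sqrt(18)
  expect_lt(abs(b$mean - 47.1), 3 * sem_cfg)
})

test_that("comment tabulation reproduces counts, percentages and totals", {
  cm <- rbind(
    data.frame(participant = sprintf("P%02d", 1:10), thigh = "herbal",
               category = "My skin seems firmer"),
    data.frame(participant = sprintf("P%02d", 1:8), thigh = "herbal",
               category = "My cellulite appears to be reduced"),
    data.frame(participant = sprintf("P%02d", 1:4), thigh = "herbal",
               category = "My thighs appear to be thinner"),
    data.frame(participant = sprintf("P%02d", 1:7), thigh = "herbal",
               category = "My thigh skin appears to be smoother"),
    data.frame(participant = sprintf("P%02d", 1:4), thigh = "placebo",
               category = "My skin seems firmer"),
    data.frame(participant = sprintf("P%02d", 1:5), thigh = "placebo",
               category = "My cellulite appears to be reduced"),
    data.frame(participant = sprintf("P%02d", 1:2), thigh = "placebo",
               category = "My thighs appear to be thinner"),
    data.frame(participant = sprintf("P%02d", 1:5), thigh = "placebo",
               category = "My thigh skin appears to be smoother"))
  tb <- tabulate_comments(cm, n_completers = 18)
  firmer <- tb[tb$category == "My skin seems firmer", ]
  expect_equal(firmer$herbal_count, 10L)
  expect_equal(firmer$herbal_pct, 56L)
  expect_equal(firmer$placebo_pct, 22L)
  tot <- attr(tb, "totals")
  expect_equal(unname(tot["placebo"]), 16)
  expect_equal(unname(tot["herbal"]), 29)
  # empty set: all zeros
  e <- tabulate_comments(cm[0, ], 18)
  expect_true(all(e$placebo_count == 0) && all(e$herbal_pct == 0))
  expect_error(tabulate_comments(
    data.frame(participant = "P01", thigh = "herbal", category = "nope"),
    18), class = "cm_invalid_input")
})
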