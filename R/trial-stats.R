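# Trial statistics: repeated-measures ANOVA from first-principles
# sum-of-squares partitioning, Bonferroni-corrected baseline contrasts on
# percent-of-baseline values, exact/approximate Wilcoxon signed-rank for
# paired Likert responses, grouped summaries, and diary comment tabulation.

# Pull one outcome from a trial_dataset (or accept a plain long data.frame).
trial_long <- function(dataset, outcome = NULL) {
  d <- if (inherits(dataset, "trial_dataset")) dataset$data else dataset
  if (!is.null(outcome)) d <- d[d$outcome == outcome, , drop = FALSE]
  if (nrow(d) == 0)
    cm_stop(sprintf("no records for outcome '%s'.", outcome %||% "<any>"),
            "cm_invalid_input")
  d
}

#' Repeated-measures ANOVA
#'
#' Within-subject analysis of variance for the contralateral design, computed
#' from a first-principles sum-of-squares partition of the subject x
#' treatment x week table. In the default two-way model the effects are
#' treatment (placebo vs herbal thigh), week, and their interaction; each is
#' tested against its own interaction-with-subject mean square
#' (`F = MS_effect / MS_effect:subject`). `model = "one_way"` analyses a
#' single arm with week as the only within-subject factor.
#'
#' The decomposition requires complete balanced data, i.e. the completers;
#' unbalanced input raises an error rather than silently dropping cells.
#'
#' @param dataset a `trial_dataset` or long data.frame with columns
#'   `participant`, `thigh`, `week`, `outcome`, `value`.
#' @param outcome which outcome to analyse.
#' @param model `"two_way"` (treatment x week, default) or `"one_way"`.
#' @param arm thigh analysed under `model = "one_way"`.
#' @return object of class `rm_anova_result`: data.frame with one row per
#'   source (`effect`, `ss`, `df`, `ms`, `F`, `p`), with attributes
#'   `ss_total` and `model`. F is NA where the error mean square is zero.
#' @export
rm_anova <- function(dataset, outcome, model = c("two_way", "one_way"),
                     arm = "herbal") {
  model <- match.arg(model)
  d <- trial_long(dataset, outcome)
  if (model == "one_way") d <- d[d$thigh == arm, , drop = FALSE]
  d$participant <- as.character(d$participant)
  subs <- sort(unique(d$participant))
  weeks <- sort(unique(d$week))
  arms <- sort(unique(d$thigh))
  expect <- length(subs) * length(weeks) * length(arms)
  key <- interaction(d$participant, d$thigh, d$week, drop = FALSE)
  if (nrow(d) != expect || anyDuplicated(key) > 0)
    cm_stop(paste(
      "unbalanced data: every participant needs one value per thigh per",
      "week. Filter to completers (see `completers()`) first."),
      "cm_unbalanced")
  y <- d$value
  m <- mean(y)
  S <- length(subs); A <- length(arms); B <- length(weeks)
  ms_s <- tapply(y, d$participant, mean)
  ms_w <- tapply(y, d$week, mean)
  ss_total <- sum((y - m)^2)
  ss_subject <- A * B * sum((ms_s - m)^2)
  ss_week <- S * A * sum((ms_w - m)^2)
  # subject x week cell means (always defined)
  m_sw <- tapply(y, list(d$participant, d$week), mean)
  ss_ws <- A * sum((sweep(sweep(m_sw, 1, ms_s), 2, ms_w) + m)^2)
  if (model == "one_way") {
    tab <- data.frame(
      effect = c("subject", "week", "error"),
      ss = c(ss_subject, ss_week, ss_ws),
      df = c(S - 1, B - 1, (S - 1) * (B - 1)))
  } else {
    ms_t <- tapply(y, d$thigh, mean)
    m_ts <- tapply(y, list(d$participant, d$thigh), mean)
    m_tw <- tapply(y, list(d$thigh, d$week), mean)
    ss_treat <- S * B * sum((ms_t - m)^2)
    ss_ts <- B * sum((sweep(sweep(m_ts, 1, ms_s), 2, ms_t) + m)^2)
    ss_tw <- S * sum((sweep(sweep(m_tw, 1, ms_t), 2, ms_w) + m)^2)
    ss_err <- ss_total - ss_subject - ss_treat - ss_week - ss_ts - ss_ws -
      ss_tw
    tab <- data.frame(
      effect = c("subject", "treatment", "week", "treatment:week",
                 "treatment:subject", "week:subject",
                 "treatment:week:subject"),
      ss = c(ss_subject, ss_treat, ss_week, ss_tw, ss_ts, ss_ws, ss_err),
      df = c(S - 1, A - 1, B - 1, (A - 1) * (B - 1), (A - 1) * (S - 1),
             (B - 1) * (S - 1), (A - 1) * (B - 1) * (S - 1)))
  }
  tab$ss <- pmax(tab$ss, 0)  # guard tiny negative rounding residue
  tab$ms <- ifelse(tab$df > 0, tab$ss / tab$df, NA_real_)
  err_of <- if (model == "one_way")
    c(subject = NA, week = "error", error = NA)
  else c(subject = NA, treatment = "treatment:subject",
         week = "week:subject", `treatment:week` = "treatment:week:subject",
         `treatment:subject` = NA, `week:subject` = NA,
         `treatment:week:subject` = NA)
  tab$F <- NA_real_
  tab$p <- NA_real_
  for (i in seq_len(nrow(tab))) {
    e <- err_of[[tab$effect[i]]]
    if (!is.na(e)) {
      ems <- tab$ms[tab$effect == e]
      edf <- tab$df[tab$effect == e]
      if (is.finite(ems) && ems > 0) {
        tab$F[i] <- tab$ms[i] / ems
        tab$p[i] <- stats::pf(tab$F[i], tab$df[i], edf, lower.tail = FALSE)
      }
    }
  }
  structure(tab, ss_total = ss_total, model = model,
            class = c("rm_anova_result", "data.frame"))
}

#' Paired contrasts against baseline with Bonferroni correction
#'
#' For each post-baseline week, a paired comparison of that week against week
#' 0 within one arm. By default values are first expressed as percent of each
#' participant's baseline (so the test is a one-sample t on
#' `pct - 100`); `normalize = FALSE` tests raw within-participant
#' differences. Raw p-values are Bonferroni-adjusted over the number of
#' post-baseline weeks tested (`p_adj = min(1, m * p)`).
#'
#' @param dataset a `trial_dataset` or long data.frame.
#' @param outcome which outcome to analyse.
#' @param arm `"herbal"` or `"placebo"`.
#' @param normalize test percent-of-baseline values (default) or raw
#'   differences.
#' @param baseline_week the reference week; default 0.
#' @return data.frame of class `pairwise_result`: one row per post-baseline
#'   week with `week`, `n`, `mean_diff` (mean percent change or raw
#'   difference), `t`, `df`, `p_raw`, `p_adj`.
#' @export
baseline_contrasts <- function(dataset, outcome, arm = "herbal",
                               normalize = TRUE, baseline_week = 0) {
  d <- trial_long(dataset, outcome)
  d <- d[d$thigh == arm, , drop = FALSE]
  weeks <- sort(unique(d$week))
  if (!baseline_week %in% weeks)
    cm_stop("baseline week absent from the data.", "cm_invalid_input")
  post <- setdiff(weeks, baseline_week)
  if (length(post) == 0)
    cm_stop("need at least one post-baseline week.", "cm_invalid_input")
  if (normalize) {
    d <- normalize_to_baseline(d, baseline_week)
    d$value <- d$pct_baseline
  }
  base <- d[d$week == baseline_week, c("participant", "value")]
  m <- length(post)
  res <- lapply(post, function(w) {
    dw <- d[d$week == w, c("participant", "value")]
    merged <- merge(base, dw, by = "participant",
                    suffixes = c("_base", "_week"))
    diffs <- merged$value_week - merged$value_base
    if (length(diffs) < 2)
      cm_stop(sprintf("fewer than 2 pairs at week %g.", w), "cm_invalid_input")
    if (stats::sd(diffs) == 0) {
      tt <- list(statistic = if (mean(diffs) == 0) 0 else Inf,
                 parameter = length(diffs) - 1,
                 p.value = if (mean(diffs) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(diffs)
    }
    data.frame(week = w, n = length(diffs), mean_diff = mean(diffs),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, p_adj = min(1, m * tt$p.value))
  })
  out <- do.call(rbind, res)
  class(out) <- c("pairwise_result", "data.frame")
  out
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Two-tailed signed-rank test with the standard conventions: zero
#' differences are dropped, tied absolute differences receive midranks, and
#' the statistic W is the sum of the ranks of the positive differences. For
#' `n_nonzero` up to `exact_limit` the two-sided p-value is computed by exact
#' enumeration of all sign assignments of the observed rank multiset (valid
#' under ties); beyond that a normal approximation with tie-corrected
#' variance and a 0.5 continuity correction is used. If every difference is
#' zero the test is degenerate and p = 1 is reported with a flag.
#'
#' @param x first sample (or differences, when `y` is NULL).
#' @param y optional second sample, paired with `x`.
#' @param exact_limit largest `n_nonzero` for exact enumeration; default 12.
#' @return object of class `wilcoxon_result`: list with `n_nonzero`, `W`,
#'   `p`, `method` ("exact" or "normal-approx"), `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 12) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (length(d) < 1)
    cm_stop("need at least one pair.", "cm_invalid_input")
  d <- d[!is.na(d)]
  dn <- d[d != 0]
  n <- length(dn)
  if (n == 0) {
    return(structure(list(n_nonzero = 0L, W = 0, p = 1,
                          method = "degenerate", degenerate = TRUE),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(dn))
  W <- sum(r[dn > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_limit) {
    # exact: all 2^n assignments of signs to the observed rank multiset
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.numeric(signs %*% r)
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(abs(dn))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx"
  }
  structure(list(n_nonzero = as.integer(n), W = W, p = p, method = method,
                 degenerate = FALSE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> W = %g, n = %d, p = %.4g (%s)\n",
              x$W, x$n_nonzero, x$p, x$method))
  invisible(x)
}

#' Grouped trial summary
#'
#' Mean, SD (n - 1 denominator) and SEM per (outcome, thigh, week). Cells
#' with a single value report SD and SEM of 0 and are flagged.
#'
#' @param dataset a `trial_dataset` or long data.frame.
#' @param outcomes optional subset of outcomes.
#' @return data.frame with `outcome`, `thigh`, `week`, `n`, `mean`, `sd`,
#'   `sem`, `single_n`.
#' @export
summarize_trial <- function(dataset, outcomes = NULL) {
  d <- trial_long(dataset)
  if (!is.null(outcomes)) d <- d[d$outcome %in% outcomes, , drop = FALSE]
  if (nrow(d) == 0) cm_stop("no records to summarize.", "cm_invalid_input")
  agg <- stats::aggregate(value ~ outcome + thigh + week, data = d,
                          FUN = function(v) {
                            n <- length(v)
                            s <- if (n > 1) stats::sd(v) else 0
                            c(n = n, mean = mean(v), sd = s,
                              sem = s / sqrt(n))
                          })
  out <- data.frame(agg[c("outcome", "thigh", "week")],
                    n = as.integer(agg$value[, "n"]),
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    sem = agg$value[, "sem"])
  out$single_n <- out$n == 1L
  out[order(out$outcome, out$thigh, out$week), , drop = FALSE]
}

#' Diary comment categories
#'
#' The fixed vocabulary for spontaneous diary comments about the thighs.
#' @return character vector of valid categories.
#' @export
comment_categories <- function() {
  c("My skin seems firmer",
    "My cellulite appears to be reduced",
    "My thighs appear to be thinner",
    "My thigh skin appears to be smoother")
}

#' Tabulate spontaneous diary comments
#'
#' Counts comments per (category, thigh) and expresses each count as a
#' percentage of the completer population, rounded to the nearest integer,
#' with per-thigh column totals.
#'
#' @param comments data.frame with columns `participant`, `thigh` (placebo or
#'   herbal), `category` (from [comment_categories]).
#' @param n_completers number of trial completers defining the denominator.
#' @return data.frame with one row per category (`category`, `placebo_count`,
#'   `placebo_pct`, `herbal_count`, `herbal_pct`) and attribute `totals`
#'   (named vector of per-thigh comment totals).
#' @export
tabulate_comments <- function(comments, n_completers) {
  if (n_completers < 1)
    cm_stop("`n_completers` must be >= 1.", "cm_invalid_input")
  cats <- comment_categories()
  if (nrow(comments) > 0) {
    if (!all(comments$category %in% cats))
      cm_stop(paste("unknown comment category:",
                    paste(unique(setdiff(comments$category, cats)),
                          collapse = "; ")), "cm_invalid_input")
    if (!all(comments$thigh %in% c("placebo", "herbal")))
      cm_stop("`thigh` must be 'placebo' or 'herbal'.", "cm_invalid_input")
  }
  cnt <- function(arm) vapply(cats, function(cc)
    sum(comments$thigh == arm & comments$category == cc), numeric(1))
  pc <- cnt("placebo"); hc <- cnt("herbal")
  pct <- function(k) as.integer(round(100 * k / n_completers))
  out <- data.frame(category = cats,
                    placebo_count = as.integer(pc), placebo_pct = pct(pc),
                    herbal_count = as.integer(hc), herbal_pct = pct(hc),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "totals") <- c(placebo = sum(pc), herbal = sum(hc))
  out
}
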