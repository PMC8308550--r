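# Synthetic contralateral-thigh trial generator: each participant carries a
# placebo thigh and a herbal-treatment thigh, measured at weeks
# 0/2/4/8/12/14, with block-of-four side randomization, per-participant
# random effects shared across thighs (the contralateral design's
# within-person correlation), and mid-trial withdrawals.

default_outcome_models <- function() {
  traj <- function(placebo, herbal) list(placebo = placebo, herbal = herbal)
  wk <- function(v) stats::setNames(v, c("0", "2", "4", "8", "12", "14"))
  list(
    css = list(
      trajectory = traj(wk(c(12.9, 12.7, 12.5, 12.4, 12.3, 12.5)),
                        wk(c(13.4, 12.1, 11.7, 10.8, 9.9, 10.4))),
      participant_sd = 1.0, residual_sd = 0.8),
    image_score = list(
      trajectory = traj(wk(c(8356, 8300, 8250, 8250, 8200, 8250)),
                        wk(c(8675, 8100, 7700, 7300, 6900, 7200))),
      participant_sd = 3400, residual_sd = 900),
    circumference_lower = list(
      trajectory = traj(wk(c(47.1, 46.8, 46.4, 46.3, 46.1, 46.2)),
                        wk(c(47.6, 47.3, 46.6, 46.4, 46.3, 46.4))),
      participant_sd = 4.0, residual_sd = 0.3),
    circumference_upper = list(
      trajectory = traj(wk(c(55.4, 55.1, 54.7, 54.6, 54.4, 54.5)),
                        wk(c(55.6, 55.3, 54.6, 54.4, 54.3, 54.4))),
      participant_sd = 4.6, residual_sd = 0.3),
    firmness_posterior = list(
      trajectory = traj(wk(c(0.95, 0.95, 0.95, 0.95, 0.95, 0.95)),
                        wk(c(0.95, 0.95, 0.95, 0.95, 0.95, 0.95))),
      participant_sd = 0.012, residual_sd = 0.008),
    firmness_anterior = list(
      trajectory = traj(wk(c(0.93, 0.935, 0.94, 0.945, 0.95, 0.95)),
                        wk(c(0.93, 0.935, 0.94, 0.945, 0.95, 0.95))),
      participant_sd = 0.02, residual_sd = 0.01),
    blood_flow = list(
      trajectory = traj(wk(c(0.40, 0.42, 0.44, 0.45, 0.45, 0.45)),
                        wk(c(0.42, 0.44, 0.46, 0.47, 0.47, 0.47))),
      participant_sd = 0.10, residual_sd = 0.04)
  )
}

default_likert_model <- function() {
  q <- function(placebo, herbal, sd) list(mean = c(placebo = placebo,
                                                   herbal = herbal), sd = sd)
  list(
    thighs_smoother    = q(3.44, 3.78, 0.9),
    thighs_firmer      = q(3.17, 3.44, 1.1),
    thighs_smaller     = q(2.83, 3.33, 1.1),
    cellulite_reduced  = q(3.00, 3.61, 1.0),
    overall_satisfaction = q(3.61, 4.11, 0.9)
  )
}

#' Trial configuration
#'
#' Design and generative parameters of the simulated contralateral trial.
#' Defaults mirror the emulated study: 20 women enrolled, withdrawals at
#' weeks 7 and 8 leaving 18 completers, visits at weeks 0/2/4/8/12/14, and
#' per-outcome mean trajectories anchored at the published baseline and
#' follow-up values, with noise split into a participant-level random effect
#' (shared by both thighs across all weeks) and a per-measurement residual.
#'
#' @param n_enrolled participants enrolled; default 20.
#' @param withdrawal_weeks weeks at which one participant each withdraws;
#'   default c(7, 8).
#' @param weeks scheduled measurement weeks; default c(0, 2, 4, 8, 12, 14).
#' @param outcome_models named list; each element has `trajectory` (a list
#'   with `placebo` and `herbal` named week->mean vectors), `participant_sd`
#'   and `residual_sd`. Defaults cover CSS, image score, circumferences,
#'   firmness and blood flow.
#' @param likert_model named list of questionnaire items, each with `mean`
#'   (named c(placebo=, herbal=)) and `sd`.
#' @param seed default seed used by the simulators when none is passed.
#' @return an object of class `trial_config`.
#' @export
trial_config <- function(n_enrolled = 20, withdrawal_weeks = c(7, 8),
                         weeks = c(0, 2, 4, 8, 12, 14),
                         outcome_models = default_outcome_models(),
                         likert_model = default_likert_model(),
                         seed = 1L) {
  if (n_enrolled < length(withdrawal_weeks))
    cm_stop("cannot withdraw more participants than are enrolled.",
            "cm_config_error")
  for (nm in names(outcome_models)) {
    om <- outcome_models[[nm]]
    if (om$participant_sd < 0 || om$residual_sd < 0)
      cm_stop(sprintf("negative sd in outcome model '%s'.", nm),
              "cm_config_error")
    for (arm in c("placebo", "herbal")) {
      tr <- om$trajectory[[arm]]
      if (!all(as.character(weeks) %in% names(tr)))
        cm_stop(sprintf(
          "trajectory for outcome '%s' (%s thigh) missing scheduled week(s) %s.",
          nm, arm, paste(setdiff(as.character(weeks), names(tr)),
                         collapse = ", ")), "cm_config_error")
    }
  }
  structure(list(n_enrolled = as.integer(n_enrolled),
                 withdrawal_weeks = withdrawal_weeks, weeks = weeks,
                 outcome_models = outcome_models,
                 likert_model = likert_model, seed = as.integer(seed)),
            class = "trial_config")
}

#' Simulate a contralateral trial
#'
#' Draws one synthetic trial: block-of-four randomization of the treated
#' side, per-participant random effects shared across both thighs, residual
#' noise per measurement, and one withdrawal per configured withdrawal week
#' (withdrawn participants keep records up to and including their withdrawal
#' week and contribute nothing afterwards). Deterministic for a fixed seed.
#'
#' @param config a [trial_config].
#' @param seed integer seed; defaults to `config$seed`.
#' @return an object of class `trial_dataset`: list with `data` (long-format
#'   data.frame: `participant`, `thigh` in placebo/herbal, `side` in
#'   left/right, `week`, `outcome`, `value`) and `ledger` (one row per
#'   participant: `participant`, `herbal_side`, `withdrawn_week` (NA if
#'   none), `completed`).
#' @export
simulate_trial <- function(config = trial_config(), seed = config$seed) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(seed)
  n <- config$n_enrolled
  ids <- sprintf("P%02d", seq_len(n))
  # block-of-four side randomization: two herbal-left, two herbal-right per
  # block, order shuffled within each block
  n_blocks <- ceiling(n / 4)
  herbal_side <- unlist(lapply(seq_len(n_blocks), function(b)
    sample(c("left", "left", "right", "right"))))[seq_len(n)]
  # one withdrawal per configured week, distinct participants
  wd <- sample(seq_len(n), length(config$withdrawal_weeks))
  withdrawn_week <- rep(NA_real_, n)
  withdrawn_week[wd] <- config$withdrawal_weeks
  ledger <- data.frame(participant = ids, herbal_side = herbal_side,
                       withdrawn_week = withdrawn_week,
                       completed = is.na(withdrawn_week),
                       stringsAsFactors = FALSE)

  outs <- names(config$outcome_models)
  rows <- vector("list", length(outs))
  for (oi in seq_along(outs)) {
    om <- config$outcome_models[[outs[oi]]]
    p_eff <- stats::rnorm(n, 0, om$participant_sd)
    grid <- expand.grid(participant = seq_len(n),
                        thigh = c("placebo", "herbal"),
                        week = config$weeks, stringsAsFactors = FALSE)
    mu <- mapply(function(th, wk) om$trajectory[[th]][[as.character(wk)]],
                 grid$thigh, grid$week)
    val <- mu + p_eff[grid$participant] +
      stats::rnorm(nrow(grid), 0, om$residual_sd)
    rows[[oi]] <- data.frame(participant = ids[grid$participant],
                             thigh = grid$thigh,
                             side = ifelse(grid$thigh == "herbal",
                                           herbal_side[grid$participant],
                                           ifelse(herbal_side[grid$participant] == "left",
                                                  "right", "left")),
                             week = grid$week, outcome = outs[oi],
                             value = val, stringsAsFactors = FALSE)
  }
  data <- do.call(rbind, rows)
  # drop records after each withdrawal
  keep <- is.na(withdrawn_week[match(data$participant, ids)]) |
    data$week <= withdrawn_week[match(data$participant, ids)]
  data <- data[keep, , drop = FALSE]
  data <- data[order(data$outcome, data$participant, data$thigh, data$week), ]
  rownames(data) <- NULL
  structure(list(data = data, ledger = ledger, config = config, seed = seed),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(
    "<trial_dataset> %d enrolled, %d withdrawn, %d completed; %d records over %d outcome(s)\n",
    nrow(x$ledger), sum(!x$ledger$completed), sum(x$ledger$completed),
    nrow(x$data), length(unique(x$data$outcome))))
  invisible(x)
}

#' Restrict a dataset to trial completers
#'
#' @param dataset a `trial_dataset`.
#' @return the dataset with withdrawn participants' records removed.
#' @export
completers <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  done <- dataset$ledger$participant[dataset$ledger$completed]
  dataset$data <- dataset$data[dataset$data$participant %in% done, ,
                               drop = FALSE]
  dataset
}

#' Simulate blinded evaluator grades
#'
#' Derives 0-3 grades from the latent severity outcome (default `css`,
#' 0-15): each of `n_evaluators` blinded evaluators reports
#' `clamp(round(latent / 5 + bias_e + noise), 0, 3)`, where `bias_e` is a
#' fixed per-evaluator bias and `noise` is fresh per grading.
#'
#' @param config a [trial_config].
#' @param dataset a `trial_dataset` containing the latent outcome.
#' @param latent_outcome outcome name to grade from; default `"css"`.
#' @param n_evaluators number of evaluators; default 3.
#' @param evaluator_bias_sd SD of the per-evaluator fixed bias; default 0.15.
#' @param evaluator_noise_sd SD of the per-grading noise; default 0.3.
#' @param seed integer seed; defaults to `config$seed + 1`.
#' @return data.frame with columns `participant`, `thigh`, `week`,
#'   `evaluator`, `grade`, suitable for [aggregate_grades].
#' @export
simulate_grades <- function(config, dataset, latent_outcome = "css",
                            n_evaluators = 3, evaluator_bias_sd = 0.15,
                            evaluator_noise_sd = 0.3,
                            seed = config$seed + 1L) {
  stopifnot(inherits(dataset, "trial_dataset"))
  lat <- dataset$data[dataset$data$outcome == latent_outcome, , drop = FALSE]
  if (nrow(lat) == 0)
    cm_stop(sprintf("dataset has no latent outcome '%s'.", latent_outcome),
            "cm_config_error")
  set.seed(seed)
  bias <- stats::rnorm(n_evaluators, 0, evaluator_bias_sd)
  out <- do.call(rbind, lapply(seq_len(n_evaluators), function(e) {
    g <- round_half_away(lat$value / 5 + bias[e] +
                           stats::rnorm(nrow(lat), 0, evaluator_noise_sd))
    data.frame(participant = lat$participant, thigh = lat$thigh,
               week = lat$week, evaluator = sprintf("E%d", e),
               grade = as.integer(pmin(3, pmax(0, g))),
               stringsAsFactors = FALSE)
  }))
  out[order(out$participant, out$thigh, out$week, out$evaluator), ,
      drop = FALSE]
}

#' Simulate a paired Likert questionnaire
#'
#' One 1-5 response per (question, participant, thigh): a normal draw around
#' the configured per-thigh mean, rounded and clamped to 1..5, paired within
#' participant.
#'
#' @param config a [trial_config] with a `likert_model`.
#' @param participants character vector of responding participants (defaults
#'   to all enrolled).
#' @param seed integer seed; defaults to `config$seed + 2`.
#' @return data.frame with columns `question`, `participant`,
#'   `placebo_score`, `herbal_score` (integers 1-5).
#' @export
simulate_likert <- function(config = trial_config(),
                            participants = sprintf("P%02d",
                                                   seq_len(config$n_enrolled)),
                            seed = config$seed + 2L) {
  set.seed(seed)
  qs <- names(config$likert_model)
  out <- do.call(rbind, lapply(qs, function(q) {
    m <- config$likert_model[[q]]
    draw <- function(mu) as.integer(pmin(5, pmax(1, round_half_away(
      stats::rnorm(length(participants), mu, m$sd)))))
    data.frame(question = q, participant = participants,
               placebo_score = draw(m$mean[["placebo"]]),
               herbal_score = draw(m$mean[["herbal"]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
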