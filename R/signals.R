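#' Per-activity outcome histories for one participant
#'
#' Collects a participant's binary outcomes into one ordered sequence per
#' activity (familiarization and free play concatenated in temporal order).
#' This is the structure the 15-trial PC/LP windows are read from.
#'
#' @param trials A trial tibble for a single participant (see
#'   [trial_schema()]), with familiarization rows preceding free-play rows.
#' @return An `outcome_history`: a named list of integer outcome vectors,
#'   one per activity.
#' @export
outcome_history <- function(trials) {
  validate_trials(trials)
  if (length(unique(trials$participant_id)) != 1L) {
    stop("outcome_history() expects a single participant", call. = FALSE)
  }
  trials <- trials[order(match(trials$stage, c("familiarization", "free_play")),
                         trials$trial), ]
  out <- lapply(activity_levels(), function(a) {
    as.integer(trials$outcome[trials$activity == a])
  })
  names(out) <- activity_levels()
  structure(out, class = "outcome_history")
}

#' @export
print.outcome_history <- function(x, ...) {
  cat("<outcome_history:",
      paste(sprintf("%s=%d", names(x), lengths(x)), collapse = " "), ">\n")
  invisible(x)
}

window_tail <- function(outcomes, n_plays, window_n) {
  if (!is.null(n_plays)) {
    if (n_plays > length(outcomes)) {
      stop("n_plays exceeds the number of recorded plays", call. = FALSE)
    }
    outcomes <- outcomes[seq_len(n_plays)]
  }
  if (length(outcomes) < window_n) {
    stop(sprintf("need >= %d outcomes on the activity, have %d",
                 window_n, length(outcomes)), call. = FALSE)
  }
  outcomes[(length(outcomes) - window_n + 1L):length(outcomes)]
}

#' Recent percent correct on one activity
#'
#' The proportion of correct guesses over the activity's most recent 15
#' plays (familiarization included), the dynamic competence signal PC.
#'
#' @param history An [outcome_history()].
#' @param activity Activity id, `"A1"`..`"A4"`.
#' @param n_plays Evaluate as of this many plays of the activity
#'   (default: all recorded plays).
#' @param window_n Window length (default 15).
#' @return PC in `[0, 1]`.
#' @export
recent_pc <- function(history, activity, n_plays = NULL, window_n = 15L) {
  stopifnot(inherits(history, "outcome_history"))
  activity <- match.arg(activity, activity_levels())
  mean(window_tail(history[[activity]], n_plays, window_n))
}

#' Resolve a learning-progress window split
#'
#' The LP signal contrasts the mean of an early sub-window against a late
#' sub-window of the 15-outcome PC window (positions indexed 1 = oldest to
#' 15 = newest). The default `"10v9"` contrasts positions 1-10 against 7-15
#' ("first 10 vs last 9", overlapping by 4). Non-overlapping alternatives:
#' `"10v5"` (1-10 vs 11-15) and `"8v7"` (1-8 vs 9-15).
#'
#' @param lp_split Split name.
#' @param window_n Window length (only 15 is meaningful for the defaults).
#' @return List with integer position vectors `first` and `second`.
#' @export
lp_split_positions <- function(lp_split = c("10v9", "10v5", "8v7"),
                               window_n = 15L) {
  lp_split <- match.arg(lp_split)
  sp <- switch(lp_split,
    "10v9" = list(first = 1:10, second = 7:15),
    "10v5" = list(first = 1:10, second = 11:15),
    "8v7"  = list(first = 1:8,  second = 9:15)
  )
  if (max(sp$second) != window_n) {
    stop("lp_split presets assume a 15-outcome window", call. = FALSE)
  }
  sp
}

window_lp <- function(window, split) {
  abs(mean(window[split$first]) - mean(window[split$second]))
}

#' Recent learning progress on one activity
#'
#' The absolute difference between the mean of the early and the late
#' sub-window of the activity's most recent 15 outcomes — a cheap estimate
#' of the temporal derivative of competence. The absolute value makes
#' performance declines register as progress-to-recover, so agents can
#' re-engage deteriorating activities.
#'
#' @inheritParams recent_pc
#' @param lp_split Sub-window split, see [lp_split_positions()].
#' @return LP in `[0, 1]`.
#' @export
recent_lp <- function(history, activity, n_plays = NULL,
                      lp_split = "10v9", window_n = 15L) {
  stopifnot(inherits(history, "outcome_history"))
  activity <- match.arg(activity, activity_levels())
  w <- window_tail(history[[activity]], n_plays, window_n)
  window_lp(w, lp_split_positions(lp_split, window_n))
}

#' Self-challenge index for a single trial
#'
#' `SC = 1 - (pc_choice - min) / (max - min)` where min and max are the
#' running extremes of PC experienced so far across all activities. SC near
#' 1 means the participant chose the activity they are currently worst at
#' (over-challenging); SC near 0 the activity they are best at. Undefined
#' (`NA`) when the running range is zero.
#'
#' @param pc_of_choice PC of the chosen activity at this trial.
#' @param running_min_pc,running_max_pc Running extremes of experienced PC.
#' @return SC in `[0, 1]`, or `NA` on a degenerate (zero) range.
#' @export
sc_trial <- function(pc_of_choice, running_min_pc, running_max_pc) {
  stopifnot(running_min_pc <= running_max_pc)
  if (running_max_pc == running_min_pc) return(NA_real_)
  1 - (pc_of_choice - running_min_pc) / (running_max_pc - running_min_pc)
}

#' Final percent correct on one activity
#'
#' Mean of the activity's last 15 outcomes, familiarization included when
#' fewer than 15 free-play trials were spent on it.
#'
#' @inheritParams recent_pc
#' @return fPC in `[0, 1]`.
#' @export
final_pc <- function(history, activity, window_n = 15L) {
  recent_pc(history, activity, n_plays = NULL, window_n = window_n)
}

#' Difficulty-weighted final performance
#'
#' A weighted average of final PC on the three learnable activities, each
#' weighted by its difficulty rank divided by the rank sum:
#' `dwfPC = fPC_A1 / 6 + fPC_A2 / 3 + fPC_A3 / 2`. The weights sum to 1.
#'
#' @param fpc_a1,fpc_a2,fpc_a3 Final PC on A1, A2, A3.
#' @return dwfPC in `[0, 1]`.
#' @export
dwfpc <- function(fpc_a1, fpc_a2, fpc_a3) {
  stopifnot(all(c(fpc_a1, fpc_a2, fpc_a3) >= 0),
            all(c(fpc_a1, fpc_a2, fpc_a3) <= 1))
  fpc_a1 / 6 + fpc_a2 / 3 + fpc_a3 / 2
}

#' Mastery of one activity
#'
#' A participant masters an activity by getting at least `threshold_k`
#' correct within a `window_n`-outcome stretch of consecutive plays of that
#' activity. The default 13/15 corresponds to a binomial chance probability
#' of 0.0037 (see [criterion_tail_probability()]). With
#' `scope = "any_window"` (default) the criterion may be met at any point in
#' the session; `"final_window"` checks only the last `window_n` outcomes.
#'
#' @inheritParams recent_pc
#' @param threshold_k Required correct count within the window.
#' @param scope `"any_window"` or `"final_window"`.
#' @return Logical.
#' @export
mastered <- function(history, activity, threshold_k = 13L, window_n = 15L,
                     scope = c("any_window", "final_window")) {
  stopifnot(inherits(history, "outcome_history"))
  activity <- match.arg(activity, activity_levels())
  scope <- match.arg(scope)
  y <- history[[activity]]
  if (length(y) < window_n) {
    stop(sprintf("need >= %d outcomes on %s", window_n, activity),
         call. = FALSE)
  }
  if (scope == "final_window") {
    return(sum(window_tail(y, NULL, window_n)) >= threshold_k)
  }
  !is.na(first_mastery_play(y, threshold_k, window_n))
}

# Index (within the activity's own play sequence) of the play on which the
# sliding-window criterion is first met; NA if never.
first_mastery_play <- function(y, threshold_k = 13L, window_n = 15L) {
  n <- length(y)
  if (n < window_n) return(NA_integer_)
  cs <- cumsum(y)
  win <- cs[window_n:n] - c(0L, cs[seq_len(n - window_n)])
  hit <- which(win >= threshold_k)
  if (length(hit) == 0L) NA_integer_ else hit[1L] + window_n - 1L
}

#' Chance probability of meeting a mastery criterion
#'
#' Upper-tail binomial probability `P(X >= threshold_k)` with
#' `X ~ Binomial(window_n, p_chance)` — the probability that a guesser with
#' no learning meets the criterion in one window. For 13/15 at chance 0.5
#' this is 0.0037.
#'
#' @param window_n Window length.
#' @param threshold_k Required correct count.
#' @param p_chance Per-trial chance success probability.
#' @return Tail probability.
#' @export
criterion_tail_probability <- function(window_n = 15L, threshold_k = 13L,
                                       p_chance = 0.5) {
  stopifnot(threshold_k >= 0, threshold_k <= window_n)
  if (p_chance < 0 || p_chance > 1) {
    stop("p_chance must lie in [0, 1]", call. = FALSE)
  }
  stats::pbinom(threshold_k - 1, size = window_n, prob = p_chance,
                lower.tail = FALSE)
}

#' Response-bias exclusion flag
#'
#' Flags participants who show a strong tendency to repeat a single response
#' category within an activity (e.g. always guessing the same food item
#' regardless of the stimulus): the participant is flagged if, in any
#' activity, the modal response category's relative frequency reaches
#' `threshold`. Returns `FALSE` with a warning when the optional `response`
#' column is absent.
#'
#' @param trials A trial tibble for a single participant, optionally with a
#'   `response` column.
#' @param threshold Modal-frequency cutoff in `(0, 1]` (default 0.95).
#' @return Logical exclusion flag.
#' @export
response_bias_flag <- function(trials, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!"response" %in% names(trials)) {
    warning("no `response` column; response-bias filter not applied",
            call. = FALSE)
    return(FALSE)
  }
  for (a in unique(trials$activity)) {
    r <- trials$response[trials$activity == a]
    r <- r[!is.na(r)]
    if (length(r) == 0L) next
    if (max(table(r)) / length(r) >= threshold) return(TRUE)
  }
  FALSE
}
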