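#' Trial-record schema
#'
#' All modules exchange trial-level data in one long format, one row per
#' trial:
#'
#' * `participant_id` — character identifier
#' * `group` — instruction-group label (e.g. `"IG"`, `"EG"`)
#' * `stage` — `"familiarization"` or `"free_play"`
#' * `trial` — 1-based trial index within the stage
#' * `activity` — `"A1"`..`"A4"`
#' * `outcome` — 1 (correct guess) or 0 (error)
#' * `response` — optional guessed response category (used only by the
#'   response-bias filter)
#'
#' Real datasets in this layout can be dropped in via [read_trials()].
#'
#' @return Character vector of required column names.
#' @export
trial_schema <- function() {
  c("participant_id", "group", "stage", "trial", "activity", "outcome")
}

#' Validate a trial table against the schema
#'
#' @param trials A data frame of trial records.
#' @return The input, invisibly, or an error identifying the first
#'   offending column or row.
#' @export
validate_trials <- function(trials) {
  missing_cols <- setdiff(trial_schema(), names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_stage <- which(!trials$stage %in% c("familiarization", "free_play"))
  if (length(bad_stage) > 0L) {
    stop(sprintf("row %d: stage '%s' not in {familiarization, free_play}",
                 bad_stage[1L], trials$stage[bad_stage[1L]]), call. = FALSE)
  }
  bad_act <- which(!trials$activity %in% activity_levels())
  if (length(bad_act) > 0L) {
    stop(sprintf("row %d: activity '%s' not in {%s}", bad_act[1L],
                 trials$activity[bad_act[1L]],
                 paste(activity_levels(), collapse = ",")), call. = FALSE)
  }
  bad_out <- which(!trials$outcome %in% c(0L, 1L))
  if (length(bad_out) > 0L) {
    stop(sprintf("row %d: outcome must be 0 or 1", bad_out[1L]), call. = FALSE)
  }
  bad_tr <- which(!is.finite(trials$trial) | trials$trial < 1)
  if (length(bad_tr) > 0L) {
    stop(sprintf("row %d: trial index must be >= 1", bad_tr[1L]), call. = FALSE)
  }
  invisible(trials)
}

#' Configure a synthetic cohort
#'
#' Describes the simulated experiment: the four-activity environment, a
#' forced familiarization stage (default 15 trials per activity, presented
#' round-robin A1..A4), a free-choice stage (default 250 trials), and the
#' distribution the generating utility weights are drawn from. By default
#' each simulated participant's `(w_pc, w_lp)` direction is uniform on the
#' unit circle with softmax gain `tau ~ U(20, 60)`, spanning PC-driven,
#' LP-driven and mixed strategies.
#'
#' @param n_per_group Participants per instruction group.
#' @param groups Group labels.
#' @param activities List of 4 [activity_spec()]s (default
#'   [default_activities()]).
#' @param horizon Number of free-choice trials.
#' @param familiarization_per_activity Forced trials per activity.
#' @param weight_sampler `NULL` for the default distribution, or a function
#'   `(n, group)` returning a data frame with columns `w_pc`, `w_lp`, `tau`.
#' @param lp_split,window_n Signal-window settings the simulated agents use
#'   (see [lp_split_positions()]).
#' @param master_seed Integer seed; participant `i` simulates under seed
#'   `master_seed + i`, so individual runs are replayable.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_per_group = 20L, groups = c("IG", "EG"),
                          activities = default_activities(),
                          horizon = 250L, familiarization_per_activity = 15L,
                          weight_sampler = NULL,
                          lp_split = "10v9", window_n = 15L,
                          master_seed = 1L) {
  stopifnot(n_per_group >= 1L, horizon >= 1L,
            familiarization_per_activity >= 1L, length(groups) >= 1L)
  activities <- check_activity_set(activities)
  if (is.null(weight_sampler)) weight_sampler <- default_weight_sampler
  stopifnot(is.function(weight_sampler))
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups,
         activities = activities, horizon = as.integer(horizon),
         familiarization_per_activity = as.integer(familiarization_per_activity),
         weight_sampler = weight_sampler, lp_split = lp_split,
         window_n = as.integer(window_n),
         master_seed = as.integer(master_seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config: %d x %s, fam %d/activity, horizon %d, seed %d>\n",
    x$n_per_group, paste(x$groups, collapse = "+"),
    x$familiarization_per_activity, x$horizon, x$master_seed))
  invisible(x)
}

# Generating-weight distribution: direction uniform on the unit circle,
# gain tau ~ U(20, 60).
default_weight_sampler <- function(n, group = NULL) {
  ang <- stats::runif(n, 0, 2 * pi)
  tibble::tibble(w_pc = cos(ang), w_lp = sin(ang),
                 tau = stats::runif(n, 20, 60))
}

# Mean and |first-vs-second sub-window| difference of the last `window_n`
# entries of y[1:count]. Shared by the simulator and the signal extractor so
# the generative model and the fitted likelihood agree exactly.
window_stats <- function(y, count, window_n, split) {
  w <- y[(count - window_n + 1L):count]
  c(mean(w), abs(mean(w[split$first]) - mean(w[split$second])))
}

#' Simulate one participant
#'
#' Runs the generative choice model forward: a round-robin familiarization
#' block (outcomes drawn from each activity's learning curve at its current
#' play count), then `horizon` free-choice trials in which the agent
#' computes PC and LP for every activity from its most recent 15 outcomes,
#' scores activities by `U = w_pc * PC + w_lp * LP`, samples a choice from
#' the softmax with gain `tau`, and receives Bernoulli feedback from the
#' chosen activity's learning curve.
#'
#' @param weights A [utility_weights()] object (the generating parameters).
#' @param config A [cohort_config()].
#' @param participant_id,group Labels stamped on the output rows.
#' @param seed Integer seed; fixed seed gives a bit-identical trial
#'   sequence.
#' @return A trial tibble ([trial_schema()] plus a `response` column).
#' @export
simulate_participant <- function(weights, config, participant_id = "p1",
                                 group = "IG", seed = 1L) {
  stopifnot(inherits(weights, "utility_weights"),
            inherits(config, "cohort_config"))
  acts <- config$activities
  window_n <- config$window_n
  fam_n <- config$familiarization_per_activity
  if (fam_n < window_n) {
    stop(sprintf(
      "familiarization_per_activity (%d) < window_n (%d): PC/LP windows would be incomplete at free play onset",
      fam_n, window_n), call. = FALSE)
  }
  split <- lp_split_positions(config$lp_split, window_n)
  horizon <- config$horizon
  n_act <- length(acts)
  set.seed(seed)

  total <- n_act * fam_n + horizon
  y_store <- matrix(NA_integer_, nrow = fam_n + horizon, ncol = n_act)
  counts <- integer(n_act)
  activity_col <- character(total)
  outcome_col <- integer(total)
  stage_col <- character(total)
  trial_col <- integer(total)
  response_col <- character(total)
  pcs <- numeric(n_act)
  lps <- numeric(n_act)

  row <- 0L
  # forced familiarization, round-robin A1..A4
  for (rep in seq_len(fam_n)) {
    for (a in seq_len(n_act)) {
      row <- row + 1L
      p <- learning_curve(acts[[a]], counts[a])
      out <- as.integer(stats::runif(1) < p)
      counts[a] <- counts[a] + 1L
      y_store[counts[a], a] <- out
      activity_col[row] <- activity_levels()[a]
      outcome_col[row] <- out
      stage_col[row] <- "familiarization"
      trial_col[row] <- row
      response_col[row] <- sample(c("f1", "f2"), 1L)
    }
  }
  for (a in seq_len(n_act)) {
    st <- window_stats(y_store[, a], counts[a], window_n, split)
    pcs[a] <- st[1L]; lps[a] <- st[2L]
  }

  # free play
  for (t in seq_len(horizon)) {
    row <- row + 1L
    u <- weights$w_pc * pcs + weights$w_lp * lps
    pr <- softmax_probs(u, weights$tau)
    a <- sample.int(n_act, 1L, prob = pr)
    p <- learning_curve(acts[[a]], counts[a])
    out <- as.integer(stats::runif(1) < p)
    counts[a] <- counts[a] + 1L
    y_store[counts[a], a] <- out
    st <- window_stats(y_store[, a], counts[a], window_n, split)
    pcs[a] <- st[1L]; lps[a] <- st[2L]
    activity_col[row] <- activity_levels()[a]
    outcome_col[row] <- out
    stage_col[row] <- "free_play"
    trial_col[row] <- t
    response_col[row] <- sample(c("f1", "f2"), 1L)
  }
  fam_total <- n_act * fam_n
  trial_col[seq_len(fam_total)] <- seq_len(fam_total)

  tibble::tibble(
    participant_id = participant_id, group = group, stage = stage_col,
    trial = trial_col, activity = activity_col, outcome = outcome_col,
    response = response_col
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws each participant's generating weights from the configured
#' distribution and simulates their full session. Participant `i` runs
#' under seed `master_seed + i`, so any individual can be re-simulated in
#' isolation; a fixed `master_seed` makes the whole cohort reproducible.
#'
#' @param config A [cohort_config()].
#' @return A list with `trials` (all participants' trial records) and
#'   `truth` (`participant_id, w_pc, w_lp, tau, group, seed`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(config$groups, each = config$n_per_group)
  n <- length(groups)
  set.seed(config$master_seed)
  w <- do.call(rbind, lapply(split(seq_len(n), groups)[unique(groups)],
    function(idx) config$weight_sampler(length(idx), groups[idx[1L]])))
  stopifnot(all(c("w_pc", "w_lp", "tau") %in% names(w)), nrow(w) == n)

  ids <- sprintf("p%03d", seq_len(n))
  truth <- tibble::tibble(
    participant_id = ids, w_pc = w$w_pc, w_lp = w$w_lp, tau = w$tau,
    group = groups, seed = config$master_seed + seq_len(n)
  )
  trials <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    simulate_participant(
      utility_weights(truth$w_pc[i], truth$w_lp[i], truth$tau[i]),
      config, participant_id = ids[i], group = groups[i],
      seed = truth$seed[i])
  }))
  list(trials = trials, truth = truth)
}

#' Read and write trial tables
#'
#' Plain-CSV I/O for the [trial_schema()] layout (UTF-8, Unix newlines,
#' decimal point). `read_trials()` validates the schema, so it doubles as
#' the adapter for real datasets exported in this layout.
#'
#' @param trials A trial tibble.
#' @param path CSV file path.
#' @return `read_trials()` returns a validated tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials, path, eol = "\n")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  trials$trial <- as.integer(trials$trial)
  trials$outcome <- as.integer(trials$outcome)
  validate_trials(trials)
  trials
}
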