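#' Per-trial PC/LP signal trajectories for one participant
#'
#' Replays a participant's session in temporal order and records, for every
#' free-play trial, the PC and LP of all four activities as they stood when
#' the choice was made (windows include familiarization outcomes), the
#' observed choice, and the trial-wise self-challenge index. These
#' trajectories are the sufficient statistics for the choice-model
#' likelihood: PC and LP for an activity change only on trials where it was
#' played.
#'
#' @param trials Trial tibble for a single participant.
#' @param lp_split LP sub-window split (see [lp_split_positions()]).
#' @param window_n Signal window length (default 15).
#' @return A `participant_signals` object: matrices `pc` and `lp`
#'   (free-play trials x 4 activities), `choice_idx`/`choice`, `outcome`,
#'   `sc` (trial-wise self-challenge, `NA` where undefined), `fam_pc`
#'   (end-of-familiarization PC per activity), and `mean_fam_pc` (the
#'   initial-performance covariate).
#' @export
compute_signals <- function(trials, lp_split = "10v9", window_n = 15L) {
  validate_trials(trials)
  pid <- unique(trials$participant_id)
  if (length(pid) != 1L) {
    stop("compute_signals() expects a single participant; use participant_summaries() for cohorts",
         call. = FALSE)
  }
  split <- lp_split_positions(lp_split, window_n)
  n_act <- length(activity_levels())
  fam <- trials[trials$stage == "familiarization", ]
  fam <- fam[order(fam$trial), ]
  free <- trials[trials$stage == "free_play", ]
  free <- free[order(free$trial), ]
  n_free <- nrow(free)
  if (n_free == 0L) stop("participant has no free-play trials", call. = FALSE)

  cap <- nrow(fam) + n_free
  y_store <- matrix(NA_integer_, nrow = cap, ncol = n_act)
  counts <- integer(n_act)
  pcs <- rep(NA_real_, n_act)
  lps <- rep(NA_real_, n_act)
  run_min <- Inf
  run_max <- -Inf

  fam_act <- match(fam$activity, activity_levels())
  fam_out <- as.integer(fam$outcome)
  for (i in seq_len(nrow(fam))) {
    a <- fam_act[i]
    counts[a] <- counts[a] + 1L
    y_store[counts[a], a] <- fam_out[i]
    if (counts[a] >= window_n) {
      st <- window_stats(y_store[, a], counts[a], window_n, split)
      pcs[a] <- st[1L]; lps[a] <- st[2L]
      run_min <- min(run_min, st[1L]); run_max <- max(run_max, st[1L])
    }
  }
  if (any(counts < window_n)) {
    short <- activity_levels()[counts < window_n]
    stop(sprintf(
      "activity %s has < %d outcomes at free-play onset; signal windows incomplete",
      paste(short, collapse = ","), window_n), call. = FALSE)
  }
  fam_pc <- stats::setNames(pcs, activity_levels())

  pc_mat <- matrix(NA_real_, nrow = n_free, ncol = n_act,
                   dimnames = list(NULL, activity_levels()))
  lp_mat <- pc_mat
  sc <- rep(NA_real_, n_free)
  choice_idx <- match(free$activity, activity_levels())
  free_out <- as.integer(free$outcome)

  for (t in seq_len(n_free)) {
    pc_mat[t, ] <- pcs
    lp_mat[t, ] <- lps
    a <- choice_idx[t]
    if (run_max > run_min) {
      sc[t] <- 1 - (pcs[a] - run_min) / (run_max - run_min)
    }
    counts[a] <- counts[a] + 1L
    y_store[counts[a], a] <- free_out[t]
    st <- window_stats(y_store[, a], counts[a], window_n, split)
    pcs[a] <- st[1L]; lps[a] <- st[2L]
    run_min <- min(run_min, st[1L]); run_max <- max(run_max, st[1L])
  }

  structure(
    list(participant_id = pid, group = unique(trials$group)[1L],
         pc = pc_mat, lp = lp_mat, choice_idx = choice_idx,
         choice = free$activity, outcome = free_out, sc = sc,
         fam_pc = fam_pc, mean_fam_pc = mean(fam_out),
         lp_split = lp_split, window_n = window_n),
    class = "participant_signals"
  )
}

#' @export
print.participant_signals <- function(x, ...) {
  cat(sprintf(
    "<participant_signals %s (%s): %d free-play trials, mean SC %.3f>\n",
    x$participant_id, x$group, length(x$choice_idx),
    mean(x$sc, na.rm = TRUE)))
  invisible(x)
}

#' Per-participant behavioral summaries
#'
#' Computes, for every participant in a trial table: final PC on each
#' learnable activity, difficulty-weighted final performance (dwfPC), the
#' number of activities mastered (NAM, 13/15 criterion by default), the
#' mean self-challenge index over defined free-play trials, the
#' initial-performance covariate (mean familiarization accuracy), and the
#' response-bias exclusion flag.
#'
#' @param trials Trial tibble (any number of participants).
#' @param lp_split,window_n Signal-window settings.
#' @param threshold_k Mastery criterion numerator (default 13).
#' @param mastery_scope `"any_window"` (default) or `"final_window"`.
#' @param bias_threshold Modal-response cutoff for the exclusion filter.
#' @return A tibble with one row per participant:
#'   `participant_id, group, fpc_a1, fpc_a2, fpc_a3, dwfpc, nam, mean_sc,
#'   mean_fam_pc, excluded_bias`.
#' @export
participant_summaries <- function(trials, lp_split = "10v9", window_n = 15L,
                                  threshold_k = 13L,
                                  mastery_scope = "any_window",
                                  bias_threshold = 0.95) {
  validate_trials(trials)
  has_response <- "response" %in% names(trials)
  if (!has_response) {
    warning("no `response` column; response-bias filter not applied",
            call. = FALSE)
  }
  rows <- lapply(split(trials, trials$participant_id), function(tr) {
    sig <- compute_signals(tr, lp_split = lp_split, window_n = window_n)
    hist <- outcome_history(tr)
    fpc <- vapply(c("A1", "A2", "A3"), function(a)
      final_pc(hist, a, window_n = window_n), numeric(1))
    mast <- vapply(c("A1", "A2", "A3"), function(a)
      mastered(hist, a, threshold_k = threshold_k, window_n = window_n,
               scope = mastery_scope), logical(1))
    tibble::tibble(
      participant_id = sig$participant_id, group = sig$group,
      fpc_a1 = fpc[["A1"]], fpc_a2 = fpc[["A2"]], fpc_a3 = fpc[["A3"]],
      dwfpc = dwfpc(fpc[["A1"]], fpc[["A2"]], fpc[["A3"]]),
      nam = sum(mast), mean_sc = mean(sig$sc, na.rm = TRUE),
      mean_fam_pc = sig$mean_fam_pc,
      excluded_bias = if (has_response) {
        response_bias_flag(tr, threshold = bias_threshold)
      } else FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$participant_id), ]
}
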