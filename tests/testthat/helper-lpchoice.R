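# Shared fixtures and independent oracles, built in code at test time.

# A minimal trial table with prescribed per-activity outcome sequences:
# 15 familiarization outcomes per activity (round-robin), then free-play
# rows given as (activity, outcome) pairs.
make_trials <- function(fam = NULL, free = NULL, participant_id = "t1",
                        group = "IG") {
  acts <- c("A1", "A2", "A3", "A4")
  if (is.null(fam)) {
    fam <- lapply(setNames(nm = acts), function(a) rep(1L, 15L))
  }
  fam_rows <- do.call(rbind, lapply(seq_len(15L), function(rep_i) {
    data.frame(activity = acts,
               outcome = vapply(acts, function(a) fam[[a]][rep_i], integer(1)))
  }))
  fam_df <- tibble::tibble(
    participant_id = participant_id, group = group, stage = "familiarization",
    trial = seq_len(nrow(fam_rows)), activity = fam_rows$activity,
    outcome = fam_rows$outcome)
  if (is.null(free)) return(fam_df)
  free_df <- tibble::tibble(
    participant_id = participant_id, group = group, stage = "free_play",
    trial = seq_len(nrow(free)), activity = free$activity,
    outcome = as.integer(free$outcome))
  dplyr::bind_rows(fam_df, free_df)
}

# Literal trial-by-trial likelihood oracle: replays a participant's session
# keeping plain per-activity outcome lists, recomputes PC and LP from
# scratch on every trial with naive sums, applies the softmax definition
# without max-subtraction, and accumulates -log p(choice). Deliberately
# unvectorized and independent of compute_signals()/total_nll().
oracle_nll <- function(trials, w_pc, w_lp, tau, lp_split = "10v9") {
  split <- lp_split_positions(lp_split)
  hist <- list(A1 = integer(), A2 = integer(), A3 = integer(),
               A4 = integer())
  fam <- trials[trials$stage == "familiarization", ]
  fam <- fam[order(fam$trial), ]
  for (i in seq_len(nrow(fam))) {
    a <- fam$activity[i]
    hist[[a]] <- c(hist[[a]], fam$outcome[i])
  }
  free <- trials[trials$stage == "free_play", ]
  free <- free[order(free$trial), ]
  nll <- 0
  for (i in seq_len(nrow(free))) {
    u <- numeric(4)
    for (k in 1:4) {
      y <- hist[[k]]
      win <- y[(length(y) - 14L):length(y)]
      pc <- sum(win) / 15
      lp <- abs(sum(win[split$first]) / length(split$first) -
                sum(win[split$second]) / length(split$second))
      u[k] <- w_pc * pc + w_lp * lp
    }
    p <- exp(u * tau) / sum(exp(u * tau))
    chosen <- match(free$activity[i], c("A1", "A2", "A3", "A4"))
    nll <- nll - log(p[chosen])
    hist[[chosen]] <- c(hist[[chosen]], free$outcome[i])
  }
  nll
}

# Exhaustive mastery oracle: scan every window explicitly.
oracle_mastered <- function(y, threshold_k = 13L, window_n = 15L) {
  if (length(y) < window_n) return(FALSE)
  for (s in seq_len(length(y) - window_n + 1L)) {
    if (sum(y[s:(s + window_n - 1L)]) >= threshold_k) return(TRUE)
  }
  FALSE
}

tiny_config <- function(...) {
  cohort_config(n_per_group = 2L, master_seed = 99L, ...)
}
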