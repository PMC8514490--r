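#' Forward-simulate time allocation from fitted coefficients
#'
#' Reproduces the coefficient-resampling simulation used to validate fitted
#' choice models: each iteration samples one `(w_pc, w_lp, tau)` triple from
#' the pool with replacement, runs a full agent (familiarization plus
#' `horizon` softmax-driven free-choice trials with Bernoulli feedback from
#' the environment's success model), and tallies the fraction of free-play
#' trials allocated to each activity. The environment's success model is
#' whatever `config$activities` supplies — synthetic play-count-indexed
#' learning curves by default, or flat empirical rates via
#' [empirical_activity_rates()].
#'
#' @param pool Data frame of fitted coefficients with columns `w_pc`,
#'   `w_lp`, `tau` (e.g. the bivariate rows of [fit_cohort()] output).
#' @param config A [cohort_config()] describing the environment (its
#'   `n_per_group`/`groups`/`weight_sampler` fields are ignored here).
#' @param n_iter Number of resampling iterations (default 500).
#' @param seed Integer seed; iteration `i` simulates under `seed + i`.
#' @return An `allocation_summary` tibble: `activity, mean_pct, se_pct,
#'   n_iter`. Mean percentages sum to 100.
#' @export
simulate_allocation <- function(pool, config, n_iter = 500L, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"), n_iter >= 1L)
  pool <- as.data.frame(pool)
  if (nrow(pool) == 0L) stop("empty coefficient pool", call. = FALSE)
  stopifnot(all(c("w_pc", "w_lp", "tau") %in% names(pool)))
  if (config$horizon < 1L) stop("invalid horizon", call. = FALSE)

  set.seed(seed)
  draw <- sample.int(nrow(pool), n_iter, replace = TRUE)
  shares <- matrix(NA_real_, nrow = n_iter, ncol = 4L,
                   dimnames = list(NULL, activity_levels()))
  for (i in seq_len(n_iter)) {
    w <- utility_weights(pool$w_pc[draw[i]], pool$w_lp[draw[i]],
                         pool$tau[draw[i]])
    tr <- simulate_participant(w, config, participant_id = "sim",
                               group = "sim", seed = seed + i)
    free_act <- tr$activity[tr$stage == "free_play"]
    shares[i, ] <- tabulate(match(free_act, activity_levels()), 4L) /
      length(free_act)
  }
  tibble::tibble(
    activity = activity_levels(),
    mean_pct = 100 * colMeans(shares),
    se_pct = 100 * apply(shares, 2L, stats::sd) / sqrt(n_iter),
    n_iter = n_iter
  )
}

#' Flat empirical success-rate environment
#'
#' Builds an activity set whose success probabilities are the static
#' per-activity success rates observed in a trial table — the adapter for
#' driving [simulate_allocation()] with observed rather than modeled
#' success rates.
#'
#' @param trials Trial tibble.
#' @return A list of four flat [activity_spec()]s.
#' @export
empirical_activity_rates <- function(trials) {
  validate_trials(trials)
  lapply(stats::setNames(nm = activity_levels()), function(a) {
    p <- mean(trials$outcome[trials$activity == a])
    if (is.nan(p)) stop(sprintf("no trials on %s", a), call. = FALSE)
    activity_spec(a, baseline_p = p, asymptote_p = p, learnable = FALSE)
  })
}

#' Mastery, preference, and self-challenge trajectories
#'
#' Tracks, across free-play trials, (a) the cumulative fraction of
#' participants who have met the A3 mastery criterion (sliding-window
#' 13/15 by default) at any point up to and including that trial, (b) among
#' participants who have not yet mastered A3, the fraction choosing A4
#' minus the fraction choosing A3 on that trial (`NA` once no non-masters
#' remain), and (c) the mean trial-wise self-challenge index.
#'
#' @param trials Trial tibble (real or simulated cohort).
#' @param threshold_k,window_n Mastery criterion (default 13/15).
#' @param lp_split Signal split for the SC computation.
#' @return Tibble: `trial, frac_mastered_a3, pref_a4_minus_a3, mean_sc,
#'   n_nonmasters`.
#' @export
mastery_trajectories <- function(trials, threshold_k = 13L, window_n = 15L,
                                 lp_split = "10v9") {
  validate_trials(trials)
  per <- split(trials, trials$participant_id)
  horizon <- max(vapply(per, function(tr) sum(tr$stage == "free_play"),
                        integer(1)))
  n <- length(per)
  mastery_trial <- rep(NA_real_, n)   # free-play trial of first mastery; 0 if during familiarization
  choice_mat <- matrix(NA_character_, nrow = n, ncol = horizon)
  sc_mat <- matrix(NA_real_, nrow = n, ncol = horizon)

  for (i in seq_along(per)) {
    tr <- per[[i]]
    fam <- tr[tr$stage == "familiarization", ]
    free <- tr[tr$stage == "free_play", ]
    free <- free[order(free$trial), ]
    a3 <- c(as.integer(fam$outcome[fam$activity == "A3"][order(fam$trial[fam$activity == "A3"])]),
            as.integer(free$outcome[free$activity == "A3"]))
    m_play <- first_mastery_play(a3, threshold_k, window_n)
    n_fam_a3 <- sum(fam$activity == "A3")
    if (!is.na(m_play)) {
      mastery_trial[i] <- if (m_play <= n_fam_a3) 0 else
        free$trial[free$activity == "A3"][m_play - n_fam_a3]
    }
    choice_mat[i, seq_len(nrow(free))] <- free$activity
    sig <- compute_signals(tr, lp_split = lp_split, window_n = window_n)
    sc_mat[i, seq_along(sig$sc)] <- sig$sc
  }

  out <- lapply(seq_len(horizon), function(t) {
    done <- !is.na(mastery_trial) & mastery_trial <= t
    nonmaster <- which(is.na(mastery_trial) | mastery_trial >= t)
    nonmaster <- nonmaster[!is.na(choice_mat[nonmaster, t])]
    pref <- if (length(nonmaster) == 0L) NA_real_ else {
      mean(choice_mat[nonmaster, t] == "A4") -
        mean(choice_mat[nonmaster, t] == "A3")
    }
    tibble::tibble(
      trial = t, frac_mastered_a3 = mean(done),
      pref_a4_minus_a3 = pref,
      mean_sc = if (all(is.na(sc_mat[, t]))) NA_real_ else
        mean(sc_mat[, t], na.rm = TRUE),
      n_nonmasters = length(nonmaster))
  })
  dplyr::bind_rows(out)
}

#' Parameter-recovery experiment
#'
#' Simulates participants from a grid of known normalized weight directions
#' and temperatures, refits the bivariate model, and summarizes how well
#' the generating direction is recovered: median recovered normalized
#' weights, sign-agreement rates, and drive-class agreement. Cells with
#' `tau = 0` generate uniform choices that carry no information about the
#' weight direction; they are flagged `identifiable = FALSE` rather than
#' errored.
#'
#' @param grid Data frame with columns `w_pc`, `w_lp`, `tau` (generating
#'   values; the weight pair need not be pre-normalized).
#' @param config A [cohort_config()] describing the environment.
#' @param n_reps Replicate simulations per grid cell.
#' @param seed Integer base seed.
#' @param ... Passed to [fit_participant()] (e.g. `n_ties`, `tie_tol`).
#' @return Tibble: one row per grid cell with `true_w_pc_hat,
#'   true_w_lp_hat, tau, n_reps, median_w_pc_hat, median_w_lp_hat,
#'   drive_agreement, sign_agreement, identifiable`.
#' @export
recovery_experiment <- function(grid, config, n_reps = 20L, seed = 1L, ...) {
  stopifnot(inherits(config, "cohort_config"), n_reps >= 1L)
  grid <- as.data.frame(grid)
  stopifnot(all(c("w_pc", "w_lp", "tau") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    tau <- grid$tau[g]
    identifiable <- tau > 0 && (grid$w_pc[g] != 0 || grid$w_lp[g] != 0)
    true_nw <- if (grid$w_pc[g] == 0 && grid$w_lp[g] == 0) {
      list(w_pc_hat = NA_real_, w_lp_hat = NA_real_)
    } else normalize_weights(grid$w_pc[g], grid$w_lp[g])
    true_drive <- if (identifiable) classify_drive(true_nw) else NA_character_

    rec <- matrix(NA_real_, nrow = n_reps, ncol = 2L)
    drive_ok <- sign_ok <- rep(NA, n_reps)
    for (r in seq_len(n_reps)) {
      s <- seed + 7717L * g + r
      w <- utility_weights(grid$w_pc[g], grid$w_lp[g], tau)
      tr <- simulate_participant(w, config, participant_id = "rec",
                                 group = "sim", seed = s)
      fit <- fit_participant(compute_signals(tr, lp_split = config$lp_split,
                                             window_n = config$window_n),
                             form = "bivariate", seed = s + 1L, ...)
      nw <- tryCatch(normalize_weights(fit), error = function(e) NULL)
      if (is.null(nw)) next
      rec[r, ] <- c(nw$w_pc_hat, nw$w_lp_hat)
      if (identifiable) {
        drive_ok[r] <- classify_drive(nw) == true_drive
        sign_ok[r] <- sign(nw$w_pc_hat) == sign(true_nw$w_pc_hat) &&
          sign(nw$w_lp_hat) == sign(true_nw$w_lp_hat)
      }
    }
    tibble::tibble(
      true_w_pc_hat = true_nw$w_pc_hat, true_w_lp_hat = true_nw$w_lp_hat,
      tau = tau, n_reps = n_reps,
      median_w_pc_hat = stats::median(rec[, 1L], na.rm = TRUE),
      median_w_lp_hat = stats::median(rec[, 2L], na.rm = TRUE),
      drive_agreement = if (identifiable) mean(drive_ok, na.rm = TRUE) else NA_real_,
      sign_agreement = if (identifiable) mean(sign_ok, na.rm = TRUE) else NA_real_,
      identifiable = identifiable)
  })
  dplyr::bind_rows(rows)
}

#' Circular correlation between two angle vectors
#'
#' The Fisher-Lee pairwise circular correlation,
#' `sum_{i<j} sin(t1_i - t1_j) sin(t2_i - t2_j)` over the geometric mean of
#' the marginal pairwise sums. Unlike mean-direction formulations it is
#' well defined when the angles are spread over the whole circle, which is
#' exactly the situation in a recovery experiment whose generating
#' directions are uniform. Used to score how well recovered
#' normalized-weight directions track the generating directions (each
#' `(w_pc_hat, w_lp_hat)` pair is an angle on the unit circle).
#'
#' @param theta1,theta2 Angle vectors in radians.
#' @return Correlation in `[-1, 1]`; 1 for a rigid rotation.
#' @export
circular_cor <- function(theta1, theta2) {
  stopifnot(length(theta1) == length(theta2), length(theta1) >= 2L)
  d1 <- sin(outer(theta1, theta1, "-"))
  d2 <- sin(outer(theta2, theta2, "-"))
  sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))
}
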