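#' Multi-start maximum-likelihood fit for one participant
#'
#' Fits a choice-model form to a participant's free-play choices by
#' minimizing the total negative log-likelihood with bounded quasi-Newton
#' (L-BFGS-B) optimization. Because the likelihood surface is multimodal in
#' `(w_pc, w_lp, tau)`, the optimizer is restarted from random
#' initializations — weights from `U(-1, 1)`, temperature from `U(0, 100)`
#' — until `n_ties` restarts have landed within `tie_tol` NLL units of the
#' incumbent best (the run that establishes a new best counts as its first
#' tie), or `max_restarts` is exhausted (flagged as non-converged).
#'
#' @param signals A `participant_signals` object from [compute_signals()],
#'   or a single-participant trial tibble.
#' @param form `"bivariate"`, `"pc_only"`, or `"lp_only"` (the `random`
#'   baseline needs no fitting; see [compare_models()]).
#' @param seed Integer seed for the initialization stream.
#' @param tie_tol NLL tolerance within which a restart counts as "just as
#'   good" as the incumbent best.
#' @param n_ties Required number of best-tying restarts (default 50).
#' @param max_restarts Restart budget before giving up.
#' @param lower_w,upper_w,lower_tau,upper_tau Optimizer box bounds. The
#'   initialization ranges are fixed by the protocol; wide bounds are
#'   harmless because of the `(c*w, tau/c)` scale degeneracy, and merely
#'   prevent overflow.
#' @param gradient `"numerical"` (finite differences, default) or
#'   `"analytic"`.
#' @return A `fit_result`: best [utility_weights()], `nll`, `aic`,
#'   `n_restarts`, `n_best_ties`, `converged`.
#' @export
fit_participant <- function(signals, form = "bivariate", seed = 1L,
                            tie_tol = 1e-4, n_ties = 50L,
                            max_restarts = 2000L,
                            lower_w = -10, upper_w = 10,
                            lower_tau = 0, upper_tau = 1000,
                            gradient = c("numerical", "analytic")) {
  if (is.data.frame(signals)) signals <- compute_signals(signals)
  stopifnot(inherits(signals, "participant_signals"))
  form <- match.arg(form, c("bivariate", "pc_only", "lp_only"))
  gradient <- match.arg(gradient)
  n_free <- length(signals$choice_idx)
  if (n_free == 0L) stop("participant has zero free-play trials", call. = FALSE)

  pc <- signals$pc
  lp <- signals$lp
  idx <- signals$choice_idx
  rows <- cbind(seq_len(nrow(pc)), idx)
  k_act <- ncol(pc)

  # par layout: (w..., tau); pc_only/lp_only drop the absent weight
  sig_mat <- switch(form, bivariate = NULL, pc_only = pc, lp_only = lp)
  nll_fn <- if (form == "bivariate") {
    function(par) {
      u <- par[1L] * pc + par[2L] * lp
      -sum(row_choice_loglik(u, par[3L], idx))
    }
  } else {
    function(par) -sum(row_choice_loglik(par[1L] * sig_mat, par[2L], idx))
  }
  grad_fn <- if (gradient == "analytic") {
    function(par) {
      tau <- par[length(par)]
      u <- if (form == "bivariate") par[1L] * pc + par[2L] * lp
           else par[1L] * sig_mat
      z <- tau * u
      m <- z[, 1L]
      for (k in 2:k_act) m <- pmax(m, z[, k])
      e <- exp(z - m)
      p <- e / rowSums(e)
      du <- -(u[rows] - rowSums(p * u))                 # d NLL / d tau
      gw <- function(s) -tau * sum(s[rows] - rowSums(p * s))
      if (form == "bivariate") c(gw(pc), gw(lp), sum(du))
      else c(gw(sig_mat), sum(du))
    }
  } else NULL

  n_w <- if (form == "bivariate") 2L else 1L
  lower <- c(rep(lower_w, n_w), lower_tau)
  upper <- c(rep(upper_w, n_w), upper_tau)

  set.seed(seed)
  best <- NULL
  best_nll <- Inf
  ties <- 0L
  n_restarts <- 0L
  while (n_restarts < max_restarts && ties < n_ties) {
    n_restarts <- n_restarts + 1L
    par0 <- c(stats::runif(n_w, -1, 1), stats::runif(1, 0, 100))
    res <- tryCatch(
      stats::optim(par0, nll_fn, gr = grad_fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200L)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (res$value < best_nll - tie_tol) {
      best <- res
      best_nll <- res$value
      ties <- 1L
    } else if (res$value <= best_nll + tie_tol) {
      ties <- ties + 1L
      if (res$value < best_nll) { best <- res; best_nll <- res$value }
    }
  }
  if (is.null(best)) stop("all optimizer restarts failed", call. = FALSE)

  par <- best$par
  w <- switch(form,
    bivariate = utility_weights(par[1L], par[2L], par[3L]),
    pc_only   = utility_weights(par[1L], 0, par[2L]),
    lp_only   = utility_weights(0, par[1L], par[2L]))
  structure(
    list(participant_id = signals$participant_id, form = form, weights = w,
         nll = best_nll, aic = aic(best_nll, model_n_params(form)),
         n_restarts = n_restarts, n_best_ties = ties,
         converged = ties >= n_ties, n_trials = n_free),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result %s [%s]: w_pc=%.3f w_lp=%.3f tau=%.2f NLL=%.3f AIC=%.3f (%d restarts%s)>\n",
    x$participant_id, x$form, x$weights$w_pc, x$weights$w_lp, x$weights$tau,
    x$nll, x$aic, x$n_restarts,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Fit all model forms across a cohort
#'
#' Runs [fit_participant()] for each participant and requested form and
#' evaluates the zero-parameter random baseline analytically. Participants
#' who mastered no activity carry too little signal to constrain the model
#' and are excluded by default, as are participants flagged by the
#' response-bias filter; exclusions are reported, never silent.
#'
#' @param trials Trial tibble for the cohort.
#' @param forms Model forms to evaluate.
#' @param seed Base seed; each participant x form fit derives its own
#'   initialization stream from it.
#' @param exclude_nam0 Drop participants with NAM = 0 before fitting.
#' @param exclude_bias Drop participants flagged by [response_bias_flag()].
#' @param summaries Optional precomputed [participant_summaries()] table
#'   (avoids recomputation).
#' @param lp_split,window_n Signal settings passed to [compute_signals()].
#' @param ... Passed on to [fit_participant()] (tie_tol, n_ties,
#'   max_restarts, gradient, bounds).
#' @return A list with `fits` (tibble: `participant_id, form, w_pc, w_lp,
#'   tau, nll, aic, n_restarts, n_best_ties, converged`) and `excluded`
#'   (tibble: `participant_id, reason`).
#' @export
fit_cohort <- function(trials, forms = model_forms(), seed = 1L,
                       exclude_nam0 = TRUE, exclude_bias = TRUE,
                       summaries = NULL, lp_split = "10v9", window_n = 15L,
                       ...) {
  validate_trials(trials)
  forms <- match.arg(forms, model_forms(), several.ok = TRUE)
  if (is.null(summaries)) {
    summaries <- suppressWarnings(
      participant_summaries(trials, lp_split = lp_split, window_n = window_n))
  }
  excluded <- tibble::tibble(participant_id = character(), reason = character())
  keep <- summaries$participant_id
  if (exclude_bias) {
    drop <- summaries$participant_id[summaries$excluded_bias]
    excluded <- dplyr::bind_rows(excluded,
      tibble::tibble(participant_id = drop,
                     reason = rep("response_bias", length(drop))))
    keep <- setdiff(keep, drop)
  }
  if (exclude_nam0) {
    drop <- intersect(keep, summaries$participant_id[summaries$nam == 0L])
    excluded <- dplyr::bind_rows(excluded,
      tibble::tibble(participant_id = drop,
                     reason = rep("nam_zero", length(drop))))
    keep <- setdiff(keep, drop)
  }

  fit_rows <- list()
  for (i in seq_along(keep)) {
    sig <- compute_signals(trials[trials$participant_id == keep[i], ],
                           lp_split = lp_split, window_n = window_n)
    for (j in seq_along(forms)) {
      fm <- forms[j]
      if (fm == "random") {
        n_free <- length(sig$choice_idx)
        nll <- n_free * log(length(activity_levels()))
        fit_rows[[length(fit_rows) + 1L]] <- tibble::tibble(
          participant_id = keep[i], form = "random", w_pc = 0, w_lp = 0,
          tau = 0, nll = nll, aic = aic(nll, 0L), n_restarts = 0L,
          n_best_ties = 0L, converged = TRUE)
      } else {
        fr <- fit_participant(sig, form = fm,
                              seed = seed + 1009L * i + 101L * j, ...)
        fit_rows[[length(fit_rows) + 1L]] <- tibble::tibble(
          participant_id = keep[i], form = fm, w_pc = fr$weights$w_pc,
          w_lp = fr$weights$w_lp, tau = fr$weights$tau, nll = fr$nll,
          aic = fr$aic, n_restarts = fr$n_restarts,
          n_best_ties = fr$n_best_ties, converged = fr$converged)
      }
    }
  }
  list(fits = dplyr::bind_rows(fit_rows), excluded = excluded)
}

#' Project fitted weights onto the unit circle
#'
#' Divides `(w_pc, w_lp)` by its Euclidean norm. Because the softmax model
#' has a one-dimensional scale degeneracy (any rescaling of the weights can
#' be absorbed into `tau`), only the direction of the weight vector is
#' identified; the normalized pair expresses the relative preference for PC
#' versus LP.
#'
#' @param w_pc,w_lp Raw fitted weights, or pass a [utility_weights()] /
#'   `fit_result` as `w_pc`.
#' @return A `normalized_weights` object with fields `w_pc_hat`, `w_lp_hat`
#'   (unit Euclidean norm).
#' @export
normalize_weights <- function(w_pc, w_lp = NULL) {
  if (inherits(w_pc, "fit_result")) w_pc <- w_pc$weights
  if (inherits(w_pc, "utility_weights")) {
    w_lp <- w_pc$w_lp
    w_pc <- w_pc$w_pc
  }
  stopifnot(is.numeric(w_pc), is.numeric(w_lp))
  nrm <- sqrt(w_pc^2 + w_lp^2)
  if (nrm == 0) {
    stop("cannot normalize the zero weight vector; the weight scale has been absorbed into tau — inspect tau and refit if needed",
         call. = FALSE)
  }
  structure(list(w_pc_hat = w_pc / nrm, w_lp_hat = w_lp / nrm),
            class = "normalized_weights")
}

#' @export
print.normalized_weights <- function(x, ...) {
  cat(sprintf("<normalized_weights (%.4f, %.4f)>\n", x$w_pc_hat, x$w_lp_hat))
  invisible(x)
}

#' Classify a participant's choice drive
#'
#' Bins the normalized weight pair into three equally spaced segments per
#' axis — `[-1, -0.33)`, `[-0.33, 0.33)`, `[0.33, 1]` — and labels the
#' participant `pc_driven` (strongly negative PC weight, near-zero LP
#' weight: attracted to low-competence activities), `lp_driven` (strongly
#' positive LP weight, near-zero PC weight: attracted to improving
#' activities), or `neither`.
#'
#' @param nw A `normalized_weights` object (or anything
#'   [normalize_weights()] accepts).
#' @param edge Bin-edge magnitude (default 1/3, printed as 0.33).
#' @return `"pc_driven"`, `"lp_driven"`, or `"neither"`.
#' @export
classify_drive <- function(nw, edge = 0.33) {
  if (!inherits(nw, "normalized_weights")) nw <- normalize_weights(nw)
  near_zero <- function(v) v >= -edge && v < edge
  if (nw$w_pc_hat < -edge && near_zero(nw$w_lp_hat)) return("pc_driven")
  if (nw$w_lp_hat >= edge && near_zero(nw$w_pc_hat)) return("lp_driven")
  "neither"
}

#' Compare model forms by AIC
#'
#' For each participant with all requested forms evaluated, returns the
#' lowest-AIC form, the AIC margin to the next-best form, and whether that
#' margin reaches the conventional 2-point threshold. Exact AIC ties break
#' toward the form with fewer parameters.
#'
#' @param fits The `fits` tibble from [fit_cohort()] (any number of
#'   participants).
#' @param forms Forms that must be present per participant.
#' @return Tibble: `participant_id, best_form, best_aic, delta_aic,
#'   decisive` (`delta_aic >= 2`), `bivariate_best`.
#' @export
compare_models <- function(fits, forms = model_forms()) {
  stopifnot(all(c("participant_id", "form", "aic") %in% names(fits)))
  rows <- lapply(split(fits, fits$participant_id), function(f) {
    miss <- setdiff(forms, f$form)
    if (length(miss) > 0L) {
      stop(sprintf("participant %s missing form(s): %s",
                   f$participant_id[1L], paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    f <- f[f$form %in% forms, ]
    k <- vapply(f$form, model_n_params, integer(1))
    ord <- order(f$aic, k)
    delta <- f$aic[ord[2L]] - f$aic[ord[1L]]
    tibble::tibble(
      participant_id = f$participant_id[1L], best_form = f$form[ord[1L]],
      best_aic = f$aic[ord[1L]], delta_aic = delta, decisive = delta >= 2,
      bivariate_best = f$form[ord[1L]] == "bivariate")
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$participant_id), ]
}
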