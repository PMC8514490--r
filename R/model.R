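#' Utility weights for the intrinsic-utility choice model
#'
#' A parameter triple `(w_pc, w_lp, tau)`: linear weights on the dynamic
#' percent-correct (PC) and learning-progress (LP) signals, and a softmax
#' gain ("temperature") `tau >= 0`. `tau = 0` collapses the choice rule to
#' uniform random selection. Note the one-dimensional scale degeneracy:
#' `(c * w_pc, c * w_lp, tau / c)` yields identical choice probabilities for
#' any `c > 0`, which is why fitted weights are reported on the unit circle
#' (see [normalize_weights()]).
#'
#' @param w_pc,w_lp Real weights on PC and LP.
#' @param tau Nonnegative softmax gain.
#' @return An object of class `utility_weights`.
#' @export
utility_weights <- function(w_pc, w_lp, tau) {
  stopifnot(is.numeric(w_pc), is.numeric(w_lp), is.numeric(tau),
            length(w_pc) == 1L, length(w_lp) == 1L, length(tau) == 1L)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  structure(list(w_pc = w_pc, w_lp = w_lp, tau = tau),
            class = "utility_weights")
}

#' @export
print.utility_weights <- function(x, ...) {
  cat(sprintf("<utility_weights w_pc=%.4g w_lp=%.4g tau=%.4g>\n",
              x$w_pc, x$w_lp, x$tau))
  invisible(x)
}

#' Model forms and their free-parameter counts
#'
#' Four forms of the choice model: `bivariate` (free `w_pc`, `w_lp`, `tau`;
#' 3 parameters), `pc_only` (`w_lp = 0`; 2), `lp_only` (`w_pc = 0`; 2), and
#' `random` (uniform probabilities, no parameters).
#'
#' @param form Character form name.
#' @return Integer number of free parameters.
#' @export
model_n_params <- function(form) {
  form <- match.arg(form, model_forms())
  c(bivariate = 3L, pc_only = 2L, lp_only = 2L, random = 0L)[[form]]
}

#' @rdname model_n_params
#' @export
model_forms <- function() c("bivariate", "pc_only", "lp_only", "random")

#' Intrinsic utility of an activity
#'
#' The linear combination `U = w_pc * pc + w_lp * lp`.
#'
#' @param weights A [utility_weights()] object.
#' @param pc Percent-correct signal in `[0, 1]` (vectorized).
#' @param lp Learning-progress signal in `[0, 1]` (vectorized).
#' @return Real utility value(s).
#' @export
utility <- function(weights, pc, lp) {
  stopifnot(inherits(weights, "utility_weights"))
  weights$w_pc * pc + weights$w_lp * lp
}

#' Softmax choice probabilities
#'
#' `p_i = exp(tau * U_i) / sum_k exp(tau * U_k)`, computed with
#' max-subtraction for numerical stability. `tau = 0` yields exactly uniform
#' probabilities.
#'
#' @param utilities Numeric vector of utilities (one per activity).
#' @param tau Nonnegative softmax gain.
#' @return Probability vector summing to 1.
#' @export
softmax_probs <- function(utilities, tau) {
  stopifnot(is.numeric(utilities), all(is.finite(utilities)))
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  z <- tau * utilities
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Log-likelihood of one observed choice
#'
#' The categorical log-likelihood: the log of the probability the model
#' assigned to the activity actually chosen.
#'
#' @param probs Probability vector over activities (names optional).
#' @param observed_choice Index or activity name of the observed choice.
#' @return Log-probability (a nonpositive real).
#' @export
trial_loglik <- function(probs, observed_choice) {
  if (is.character(observed_choice)) {
    if (!observed_choice %in% names(probs)) {
      stop("observed choice not among the activity set", call. = FALSE)
    }
    observed_choice <- match(observed_choice, names(probs))
  }
  if (observed_choice < 1 || observed_choice > length(probs)) {
    stop("observed choice not among the activity set", call. = FALSE)
  }
  log(probs[[observed_choice]])
}

# Log-softmax rows of tau*U for a T x K utility matrix; returns the log
# probability of the chosen column per row. Avoids underflow at large tau.
row_choice_loglik <- function(u_mat, tau, choice_idx) {
  z <- tau * u_mat
  m <- z[, 1L]
  for (k in 2:ncol(z)) m <- pmax(m, z[, k])
  lse <- m + log(rowSums(exp(z - m)))
  z[cbind(seq_len(nrow(z)), choice_idx)] - lse
}

#' Total negative log-likelihood of a participant's free-play choices
#'
#' Sums the per-trial categorical negative log-likelihood over the free-play
#' stage. Familiarization trials feed the PC/LP windows but never enter the
#' likelihood. The `random` form returns `T * log(4)` regardless of the data.
#'
#' @param weights A [utility_weights()] object (ignored for `form = "random"`
#'   except that it must still be valid).
#' @param form One of [model_forms()]. `pc_only` forces `w_lp = 0`;
#'   `lp_only` forces `w_pc = 0`.
#' @param signals A `participant_signals` object from [compute_signals()],
#'   holding the per-trial PC/LP matrices and the observed choice sequence.
#' @return Nonnegative total NLL.
#' @export
total_nll <- function(weights, form = "bivariate", signals) {
  form <- match.arg(form, model_forms())
  stopifnot(inherits(signals, "participant_signals"))
  n <- length(signals$choice_idx)
  if (form == "random") return(n * log(length(activity_levels())))
  w_pc <- if (form == "lp_only") 0 else weights$w_pc
  w_lp <- if (form == "pc_only") 0 else weights$w_lp
  if (anyNA(signals$pc) || anyNA(signals$lp)) {
    stop("missing PC/LP signal values; windows incomplete", call. = FALSE)
  }
  u <- w_pc * signals$pc + w_lp * signals$lp
  -sum(row_choice_loglik(u, weights$tau, signals$choice_idx))
}

#' Akaike information criterion
#'
#' `AIC = 2k + 2 * NLL`. The uniform-random baseline has `k = 0`, so for 250
#' free-play trials over 4 activities its AIC is `500 * log(4) = 693.147`.
#'
#' @param nll Minimized negative log-likelihood.
#' @param n_free_params Number of free parameters `k`.
#' @return AIC value.
#' @export
aic <- function(nll, n_free_params) {
  stopifnot(is.finite(nll), n_free_params >= 0)
  2 * n_free_params + 2 * nll
}
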