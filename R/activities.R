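#' Define a learning activity
#'
#' An activity is described by a saturating-exponential success curve: a
#' learner's probability of a correct guess rises from `baseline_p` toward
#' `asymptote_p` with practice, at a rate set by `learning_rate` (the number
#' of prior plays over which roughly 63% of the baseline-to-asymptote gap is
#' closed). An unlearnable activity has a flat curve (`learnable = FALSE`
#' forces `asymptote_p == baseline_p`).
#'
#' @param activity_id One of `"A1"`, `"A2"`, `"A3"`, `"A4"`.
#' @param baseline_p Success probability before any practice.
#' @param asymptote_p Ceiling success probability after extensive practice.
#' @param learning_rate Positive scale (in plays) of the exponential approach
#'   to the asymptote. Ignored for flat curves.
#' @param learnable Logical; `FALSE` pins the curve at `baseline_p`.
#' @return An object of class `activity_spec`.
#' @seealso [learning_curve()], [default_activities()]
#' @export
activity_spec <- function(activity_id, baseline_p, asymptote_p,
                          learning_rate = 20, learnable = TRUE) {
  activity_id <- match.arg(activity_id, activity_levels())
  stopifnot(
    is.numeric(baseline_p), length(baseline_p) == 1L,
    is.numeric(asymptote_p), length(asymptote_p) == 1L,
    is.numeric(learning_rate), length(learning_rate) == 1L, learning_rate > 0
  )
  if (baseline_p < 0 || asymptote_p > 1 || baseline_p > asymptote_p) {
    stop("need 0 <= baseline_p <= asymptote_p <= 1", call. = FALSE)
  }
  if (!learnable && !isTRUE(all.equal(baseline_p, asymptote_p))) {
    stop("an unlearnable activity must have a flat curve (baseline_p == asymptote_p)",
         call. = FALSE)
  }
  structure(
    list(activity_id = activity_id, baseline_p = baseline_p,
         asymptote_p = asymptote_p, learning_rate = learning_rate,
         learnable = learnable),
    class = "activity_spec"
  )
}

#' @export
print.activity_spec <- function(x, ...) {
  cat(sprintf("<activity_spec %s: p %.2f -> %.2f, rate %g, %s>\n",
              x$activity_id, x$baseline_p, x$asymptote_p, x$learning_rate,
              if (x$learnable) "learnable" else "unlearnable"))
  invisible(x)
}

activity_levels <- function() c("A1", "A2", "A3", "A4")

#' Default four-activity environment
#'
#' Three learnable activities of increasing difficulty (harder activities
#' learn more slowly and top out lower) plus one unlearnable activity whose
#' success probability is fixed at 0.5 regardless of practice. Defaults are
#' chosen so that familiarization-stage performance is ordered
#' A1 > A2 > A3 > A4 (with A4 near chance).
#'
#' @return A named list of four [activity_spec()] objects.
#' @export
default_activities <- function() {
  list(
    A1 = activity_spec("A1", baseline_p = 0.5, asymptote_p = 0.95,
                       learning_rate = 8),
    A2 = activity_spec("A2", baseline_p = 0.5, asymptote_p = 0.92,
                       learning_rate = 25),
    A3 = activity_spec("A3", baseline_p = 0.5, asymptote_p = 0.90,
                       learning_rate = 60),
    A4 = activity_spec("A4", baseline_p = 0.5, asymptote_p = 0.5,
                       learning_rate = 1, learnable = FALSE)
  )
}

#' Success probability after a given amount of practice
#'
#' Evaluates the saturating-exponential learning curve
#' `p = asymptote - (asymptote - baseline) * exp(-n / rate)`.
#' Monotonically nondecreasing in `n_prior_plays`; constant for
#' unlearnable activities.
#'
#' @param spec An [activity_spec()].
#' @param n_prior_plays Nonnegative number of plays completed so far
#'   (vectorized).
#' @return Success probability in `[0, 1]`.
#' @examples
#' a1 <- activity_spec("A1", 0.5, 0.95, learning_rate = 20)
#' learning_curve(a1, 0)   # baseline
#' learning_curve(a1, 20)  # one e-folding toward the asymptote
#' @export
learning_curve <- function(spec, n_prior_plays) {
  stopifnot(inherits(spec, "activity_spec"), all(n_prior_plays >= 0))
  spec$asymptote_p -
    (spec$asymptote_p - spec$baseline_p) * exp(-n_prior_plays / spec$learning_rate)
}

check_activity_set <- function(activities) {
  if (!is.list(activities) || length(activities) != 4L ||
      !all(vapply(activities, inherits, logical(1), "activity_spec"))) {
    stop("`activities` must be a list of 4 activity_spec objects", call. = FALSE)
  }
  ids <- vapply(activities, `[[`, character(1), "activity_id")
  if (!setequal(ids, activity_levels())) {
    stop("activities must cover exactly A1..A4", call. = FALSE)
  }
  activities <- activities[match(activity_levels(), ids)]
  names(activities) <- activity_levels()
  activities
}
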