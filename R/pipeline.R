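#' Quadratic self-challenge regression
#'
#' Ordinary least squares of difficulty-weighted final performance on the
#' mean self-challenge index, its square, and control covariates (initial
#' familiarization accuracy and instruction group). An inverted-U
#' relationship — best outcomes at intermediate self-challenge — shows up
#' as a negative quadratic coefficient and an AIC advantage over the
#' linear-only model.
#'
#' @param summaries A [participant_summaries()] tibble (columns `dwfpc`,
#'   `mean_sc`, `mean_fam_pc`, `group`).
#' @param controls Include the control covariates (default `TRUE`; the
#'   group indicator is dropped automatically when only one group is
#'   present).
#' @return An `sc_quadratic_fit` list: `coefficients` (term/estimate/
#'   std_error/t/p tibble), `quadratic_coef`, `aic_quadratic`,
#'   `aic_linear`, `delta_aic` (linear minus quadratic; positive favors
#'   the quadratic model), `quadratic_preferred`, and the two `lm` fits.
#' @export
sc_quadratic_fit <- function(summaries, controls = TRUE) {
  need <- c("dwfpc", "mean_sc", "mean_fam_pc", "group")
  stopifnot(all(need %in% names(summaries)))
  d <- summaries[stats::complete.cases(summaries[, c("dwfpc", "mean_sc")]), ]
  if (nrow(d) < 10L) {
    stop("need >= 10 participants with defined mean SC and dwfPC", call. = FALSE)
  }
  rhs <- "mean_sc + I(mean_sc^2)"
  rhs_lin <- "mean_sc"
  if (controls) {
    rhs <- paste(rhs, "+ mean_fam_pc")
    rhs_lin <- paste(rhs_lin, "+ mean_fam_pc")
    if (length(unique(d$group)) > 1L) {
      rhs <- paste(rhs, "+ group")
      rhs_lin <- paste(rhs_lin, "+ group")
    }
  }
  quad <- stats::lm(stats::as.formula(paste("dwfpc ~", rhs)), data = d)
  lin <- stats::lm(stats::as.formula(paste("dwfpc ~", rhs_lin)), data = d)
  if (anyNA(stats::coef(quad))) {
    stop("rank-deficient design in the SC regression", call. = FALSE)
  }
  ct <- summary(quad)$coefficients
  structure(
    list(
      coefficients = tibble::tibble(
        term = rownames(ct), estimate = ct[, 1L], std_error = ct[, 2L],
        statistic = ct[, 3L], p_value = ct[, 4L]),
      quadratic_coef = unname(stats::coef(quad)[["I(mean_sc^2)"]]),
      aic_quadratic = stats::AIC(quad), aic_linear = stats::AIC(lin),
      delta_aic = stats::AIC(lin) - stats::AIC(quad),
      quadratic_preferred = stats::AIC(quad) < stats::AIC(lin),
      n = nrow(d), model_quadratic = quad, model_linear = lin),
    class = "sc_quadratic_fit"
  )
}

#' @export
print.sc_quadratic_fit <- function(x, ...) {
  cat(sprintf(
    "<sc_quadratic_fit: n=%d, quadratic coef %.4f, AIC quad %.2f vs linear %.2f (delta %.2f)>\n",
    x$n, x$quadratic_coef, x$aic_quadratic, x$aic_linear, x$delta_aic))
  invisible(x)
}

#' Configure an end-to-end pipeline run
#'
#' Bundles every tunable parameter of the analysis into one serializable
#' list: the input source (a trial CSV, or `NULL` to simulate a cohort),
#' signal-window settings, mastery criterion, fitting protocol, stage
#' toggles, simulation sizes, and seeds. The configuration is echoed
#' verbatim into the output directory of every run.
#'
#' @param input Path to a trial CSV in the [trial_schema()] layout, or
#'   `NULL` to generate a synthetic cohort.
#' @param cohort A [cohort_config()] used when `input` is `NULL` (and, in
#'   all cases, as the environment for the allocation simulation).
#' @param lp_split,window_n,threshold_k,mastery_scope,bias_threshold
#'   Signal and index settings (see the signals functions).
#' @param forms Model forms to fit.
#' @param fit_seed,tie_tol,n_ties,max_restarts Fitting protocol.
#' @param do_fit,do_allocation,do_regression Stage toggles.
#' @param alloc_iter,alloc_seed Allocation-simulation size and seed.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, cohort = cohort_config(),
                       lp_split = "10v9", window_n = 15L,
                       threshold_k = 13L, mastery_scope = "any_window",
                       bias_threshold = 0.95, forms = model_forms(),
                       fit_seed = 1L, tie_tol = 1e-4, n_ties = 50L,
                       max_restarts = 2000L, do_fit = TRUE,
                       do_allocation = TRUE, do_regression = TRUE,
                       alloc_iter = 500L, alloc_seed = 1L,
                       out_dir = tempfile("lpchoice_run")) {
  structure(
    list(input = input, cohort = cohort, lp_split = lp_split,
         window_n = as.integer(window_n), threshold_k = as.integer(threshold_k),
         mastery_scope = mastery_scope, bias_threshold = bias_threshold,
         forms = forms, fit_seed = as.integer(fit_seed), tie_tol = tie_tol,
         n_ties = as.integer(n_ties), max_restarts = as.integer(max_restarts),
         do_fit = do_fit, do_allocation = do_allocation,
         do_regression = do_regression, alloc_iter = as.integer(alloc_iter),
         alloc_seed = as.integer(alloc_seed), out_dir = out_dir),
    class = "run_config"
  )
}

# Serializable view of a run_config (functions and spec objects flattened).
config_as_list <- function(config) {
  co <- config$cohort
  list(
    input = config$input,
    cohort = list(
      n_per_group = co$n_per_group, groups = co$groups,
      horizon = co$horizon,
      familiarization_per_activity = co$familiarization_per_activity,
      master_seed = co$master_seed,
      activities = lapply(co$activities, function(a) {
        a_list <- unclass(a); a_list
      })),
    lp_split = config$lp_split, window_n = config$window_n,
    threshold_k = config$threshold_k, mastery_scope = config$mastery_scope,
    bias_threshold = config$bias_threshold, forms = config$forms,
    fit_seed = config$fit_seed, tie_tol = config$tie_tol,
    n_ties = config$n_ties, max_restarts = config$max_restarts,
    do_fit = config$do_fit, do_allocation = config$do_allocation,
    do_regression = config$do_regression, alloc_iter = config$alloc_iter,
    alloc_seed = config$alloc_seed)
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [run_config()] arguments
#' (nested `cohort:` keys mirror [cohort_config()], including an optional
#' `activities:` list of activity fields).
#'
#' @param path YAML file path.
#' @param out_dir Output directory (overrides any value in the file).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  co <- y$cohort %||% list()
  acts <- if (is.null(co$activities)) default_activities() else {
    lapply(co$activities, function(a) {
      activity_spec(a$activity_id, a$baseline_p, a$asymptote_p,
                    a$learning_rate %||% 20, a$learnable %||% TRUE)
    })
  }
  cohort <- cohort_config(
    n_per_group = co$n_per_group %||% 20L, groups = co$groups %||% c("IG", "EG"),
    activities = acts, horizon = co$horizon %||% 250L,
    familiarization_per_activity = co$familiarization_per_activity %||% 15L,
    lp_split = y$lp_split %||% "10v9", window_n = y$window_n %||% 15L,
    master_seed = co$master_seed %||% 1L)
  args <- y[setdiff(names(y), c("cohort"))]
  args$cohort <- cohort
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_table <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(x, path, eol = "\n")
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one input: load or simulate trial records,
#' compute per-participant behavioral summaries, fit all model forms with
#' the multi-start protocol, compare forms by AIC, classify choice drives,
#' forward-simulate time allocation from the fitted bivariate pool, and
#' fit the quadratic self-challenge regression. Writes a deterministic
#' bundle of CSV outputs plus a plain-text report, the echoed
#' configuration, and an MD5 manifest; every stage logs row counts, and
#' exclusions (response bias, zero mastery) are itemized, never silent.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  if (is.null(config$input)) {
    cohort <- generate_cohort(config$cohort)
    trials <- cohort$trials
    write_table(cohort$truth, config$out_dir, "ground_truth.csv")
    say("simulated cohort: %d participants, %d trial records",
        nrow(cohort$truth), nrow(trials))
  } else {
    trials <- read_trials(config$input)
    say("read %d trial records from %s", nrow(trials), config$input)
  }
  write_table(trials, config$out_dir, "trials.csv")

  summaries <- suppressWarnings(participant_summaries(
    trials, lp_split = config$lp_split, window_n = config$window_n,
    threshold_k = config$threshold_k, mastery_scope = config$mastery_scope,
    bias_threshold = config$bias_threshold))
  write_table(summaries, config$out_dir, "participant_summary.csv")
  say("summaries: %d participants; %d flagged by response-bias filter; %d with NAM=0",
      nrow(summaries), sum(summaries$excluded_bias), sum(summaries$nam == 0L))

  results <- list(trials = trials, summaries = summaries,
                  out_dir = config$out_dir)

  if (config$do_fit) {
    fc <- fit_cohort(trials, forms = config$forms, seed = config$fit_seed,
                     summaries = summaries, lp_split = config$lp_split,
                     window_n = config$window_n, tie_tol = config$tie_tol,
                     n_ties = config$n_ties,
                     max_restarts = config$max_restarts)
    write_table(fc$fits, config$out_dir, "model_fits.csv")
    write_table(fc$excluded, config$out_dir, "exclusions.csv")
    say("fitted %d participant x form combinations; excluded %d participants (%s)",
        nrow(fc$fits), nrow(fc$excluded),
        if (nrow(fc$excluded) == 0L) "none" else
          paste(table(fc$excluded$reason), names(table(fc$excluded$reason)),
                collapse = ", "))
    comparison <- compare_models(fc$fits, forms = config$forms)
    write_table(comparison, config$out_dir, "model_comparison.csv")
    say("bivariate best for %d/%d participants (decisive for %d)",
        sum(comparison$bivariate_best), nrow(comparison),
        sum(comparison$bivariate_best & comparison$decisive))

    biv <- fc$fits[fc$fits$form == "bivariate", ]
    classification <- dplyr::bind_rows(lapply(seq_len(nrow(biv)), function(i) {
      nw <- tryCatch(normalize_weights(biv$w_pc[i], biv$w_lp[i]),
                     error = function(e) NULL)
      tibble::tibble(
        participant_id = biv$participant_id[i],
        w_pc_hat = if (is.null(nw)) NA_real_ else nw$w_pc_hat,
        w_lp_hat = if (is.null(nw)) NA_real_ else nw$w_lp_hat,
        drive = if (is.null(nw)) NA_character_ else classify_drive(nw))
    }))
    write_table(classification, config$out_dir, "drive_classification.csv")
    say("drive classes: %s",
        paste(names(table(classification$drive)), table(classification$drive),
              sep = "=", collapse = " "))
    results$fits <- fc$fits
    results$excluded <- fc$excluded
    results$comparison <- comparison
    results$classification <- classification

    if (config$do_allocation && nrow(biv) > 0L) {
      alloc <- simulate_allocation(biv, config$cohort,
                                   n_iter = config$alloc_iter,
                                   seed = config$alloc_seed)
      write_table(alloc, config$out_dir, "alloc.csv")
      say("allocation simulation (%d iterations): %s", config$alloc_iter,
          paste(alloc$activity, sprintf("%.1f%%", alloc$mean_pct),
                sep = "=", collapse = " "))
      results$allocation <- alloc
    }
  }

  if (config$do_regression) {
    reg <- tryCatch(sc_quadratic_fit(summaries), error = function(e) {
      say("SC regression skipped: %s", conditionMessage(e))
      NULL
    })
    if (!is.null(reg)) {
      write_table(reg$coefficients, config$out_dir, "sc_quadratic.csv")
      say("SC quadratic coefficient %.4f; AIC quadratic %.2f vs linear %.2f",
          reg$quadratic_coef, reg$aic_quadratic, reg$aic_linear)
      results$sc_regression <- reg
    }
  }

  yaml::write_yaml(config_as_list(config), file.path(config$out_dir, "config.yaml"))
  writeLines(log_lines, file.path(config$out_dir, "report.txt"))
  write_manifest(config$out_dir)
  invisible(results)
}

# MD5 manifest so downstream consumers can detect stale/edited outputs.
write_manifest <- function(dir) {
  files <- setdiff(list.files(dir), "manifest.json")
  md5 <- tools::md5sum(file.path(dir, files))
  jsonlite::write_json(as.list(stats::setNames(unname(md5), files)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(files)
}

#' Verify an output bundle against its manifest
#'
#' Recomputes MD5 checksums of every file recorded in a run's
#' `manifest.json` and errors on the first mismatch or missing file —
#' guarding downstream stages against stale or hand-edited upstream
#' outputs.
#'
#' @param dir A [run_pipeline()] output directory.
#' @return `TRUE` invisibly if the bundle is intact.
#' @export
verify_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf)
  for (f in names(manifest)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing bundle file: ", f, call. = FALSE)
    if (unname(tools::md5sum(path)) != manifest[[f]]) {
      stop("stale or modified bundle file: ", f, call. = FALSE)
    }
  }
  invisible(TRUE)
}
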