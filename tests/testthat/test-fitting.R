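test_that("weight normalization projects onto the unit circle", {
  nw <- normalize_weights(3, 4)
  expect_equal(c(nw$w_pc_hat, nw$w_lp_hat), c(0.6, 0.8))
  nw <- normalize_weights(-1, 0)
  expect_equal(c(nw$w_pc_hat, nw$w_lp_hat), c(-1, 0))
  nw <- normalize_weights(0.02, -0.02)
  expect_equal(c(nw$w_pc_hat, nw$w_lp_hat), c(1, -1) / sqrt(2))
  expect_equal(nw$w_pc_hat^2 + nw$w_lp_hat^2, 1, tolerance = 1e-9)
  expect_error(normalize_weights(0, 0), "tau")
  expect_equal(normalize_weights(utility_weights(3, 4, 10))$w_pc_hat, 0.6)
})

test_that("drive classification uses the printed half-open bins", {
  expect_equal(classify_drive(normalize_weights(-0.9, 0.1)), "pc_driven")
  expect_equal(classify_drive(normalize_weights(0.1, 0.9)), "lp_driven")
  expect_equal(classify_drive(normalize_weights(0.7071, 0.7071)), "neither")
  expect_equal(classify_drive(normalize_weights(0.9, -0.1)), "neither")
  expect_equal(classify_drive(normalize_weights(-0.1, -0.9)), "neither")
  # edges: -0.33 is outside bin1, inside bin2; 0.33 starts bin3
  sc <- function(w_pc_hat, w_lp_hat) {
    structure(list(w_pc_hat = w_pc_hat, w_lp_hat = w_lp_hat),
              class = "normalized_weights")
  }
  # -0.33 itself falls in the near-zero bin [-0.33, 0.33), 0.33 in [0.33, 1]
  expect_equal(classify_drive(sc(-0.33, sqrt(1 - 0.33^2))), "lp_driven")
  expect_equal(classify_drive(sc(-0.34, 0.2)), "pc_driven")
  expect_equal(classify_drive(sc(0.2, 0.33)), "lp_driven")
  expect_equal(classify_drive(sc(0.33, 0.9)), "neither")
  expect_equal(classify_drive(sc(0.1, 0.4)), "lp_driven")
})

test_that("model comparison picks the AIC argmin with a parsimony tie-break", {
  fits <- tibble::tibble(
    participant_id = "p1",
    form = c("bivariate", "pc_only", "lp_only", "random"),
    aic = c(490, 510, 520, 693))
  cmp <- compare_models(fits)
  expect_equal(cmp$best_form, "bivariate")
  expect_equal(cmp$delta_aic, 20)
  expect_true(cmp$decisive)
  # exact ties break toward fewer parameters
  fits$aic <- rep(500, 4)
  cmp <- compare_models(fits)
  expect_equal(cmp$best_form, "random")
  expect_equal(cmp$delta_aic, 0)
  expect_false(cmp$decisive)
  expect_error(compare_models(fits[1:3, ]), "missing form")
})

test_that("fitting is deterministic and its best NLL improves with restarts", {
  tr <- simulate_participant(utility_weights(-0.7, 0.4, 40), tiny_config(),
                             seed = 33)
  sig <- compute_signals(tr)
  f1 <- fit_participant(sig, "bivariate", seed = 9, n_ties = 5)
  f2 <- fit_participant(sig, "bivariate", seed = 9, n_ties = 5)
  expect_identical(f1, f2)
  f3 <- fit_participant(sig, "bivariate", seed = 9, n_ties = 20)
  expect_lte(f3$nll, f1$nll + 1e-12)  # same stream: more restarts never worse
  expect_true(f3$converged)
  expect_gte(f3$n_best_ties, 20)
})

test_that("numerical and analytic gradients reach the same optimum", {
  tr <- simulate_participant(utility_weights(0.5, 0.7, 30), tiny_config(),
                             seed = 44)
  sig <- compute_signals(tr)
  fn <- fit_participant(sig, "bivariate", seed = 2, n_ties = 10)
  fa <- fit_participant(sig, "bivariate", seed = 2, n_ties = 10,
                        gradient = "analytic")
  expect_equal(fa$nll, fn$nll, tolerance = 1e-4)
})

test_that("a uniform chooser gains almost nothing over the random baseline", {
  tr <- simulate_participant(utility_weights(0, 0, 0), cohort_config(),
                             seed = 55)
  sig <- compute_signals(tr)
  fit <- fit_participant(sig, "bivariate", seed = 3, n_ties = 10)
  expect_lt(abs(fit$nll - 250 * log(4)), 3)
  expect_gt(aic(fit$nll, 3), aic(250 * log(4), 0))
})

test_that("univariate and bivariate NLLs respect model nesting", {
  cfg <- tiny_config()
  for (s in 1:3) {
    tr <- simulate_participant(
      utility_weights(runif(1, -1, 1), runif(1, -1, 1), runif(1, 20, 60)),
      cfg, seed = 60 + s)
    sig <- compute_signals(tr)
    nb <- fit_participant(sig, "bivariate", seed = s, n_ties = 10)$nll
    np <- fit_participant(sig, "pc_only", seed = s, n_ties = 10)$nll
    nl <- fit_participant(sig, "lp_only", seed = s, n_ties = 10)$nll
    expect_lte(nb, min(np, nl) + 1e-3)
    expect_lte(min(np, nl), 250 * log(4) + 1e-6)
  }
})

test_that("cohort fitting excludes zero-mastery and biased participants visibly", {
  co <- generate_cohort(cohort_config(n_per_group = 4L, master_seed = 70L))
  s <- participant_summaries(co$trials)
  fc <- fit_cohort(co$trials, forms = c("bivariate", "random"), seed = 1,
                   n_ties = 3, summaries = s)
  n_nam0 <- sum(s$nam == 0)
  expect_equal(nrow(fc$excluded), n_nam0)
  expect_setequal(unique(fc$fits$form), c("bivariate", "random"))
  expect_equal(nrow(fc$fits), 2 * (nrow(s) - n_nam0))
  expect_false(any(fc$fits$participant_id %in% fc$excluded$participant_id))
})
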