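test_that("allocation summaries conserve time and reproduce under a seed", {
  pool <- data.frame(w_pc = c(-1, 0.5), w_lp = c(0, 0.5), tau = c(40, 20))
  cfg <- cohort_config()
  a1 <- simulate_allocation(pool, cfg, n_iter = 15, seed = 3)
  a2 <- simulate_allocation(pool, cfg, n_iter = 15, seed = 3)
  expect_identical(a1, a2)
  expect_equal(sum(a1$mean_pct), 100, tolerance = 1e-6)
  expect_true(all(a1$se_pct >= 0))
  expect_error(simulate_allocation(pool[0, ], cfg), "empty")
})

test_that("a pool of uniform agents allocates about a quarter everywhere", {
  pool <- data.frame(w_pc = 0, w_lp = 0, tau = 0)
  a <- simulate_allocation(pool, cohort_config(), n_iter = 30, seed = 5)
  expect_true(all(abs(a$mean_pct - 25) < 3))
})

test_that("PC-averse pools favor the unlearnable activity; LP pools avoid it", {
  cfg <- cohort_config()
  pc_pool <- data.frame(w_pc = -1, w_lp = 0, tau = c(30, 40, 50))
  lp_pool <- data.frame(w_pc = 0, w_lp = 1, tau = c(30, 40, 50))
  a_pc <- simulate_allocation(pc_pool, cfg, n_iter = 40, seed = 7)
  a_lp <- simulate_allocation(lp_pool, cfg, n_iter = 40, seed = 7)
  a4 <- function(a) a$mean_pct[a$activity == "A4"]
  expect_gt(a4(a_pc), max(a_pc$mean_pct[a_pc$activity != "A4"]))
  expect_lt(a4(a_lp), a4(a_pc))
})

test_that("empirical-rate adapter pins success probabilities at observed rates", {
  co <- generate_cohort(tiny_config())
  acts <- empirical_activity_rates(co$trials)
  for (a in names(acts)) {
    obs <- mean(co$trials$outcome[co$trials$activity == a])
    expect_equal(learning_curve(acts[[a]], 0), obs)
    expect_equal(learning_curve(acts[[a]], 500), obs)
  }
})

test_that("mastery trajectories track the A3 criterion and preferences", {
  co <- generate_cohort(cohort_config(n_per_group = 5L, master_seed = 17L))
  mt <- mastery_trajectories(co$trials)
  expect_equal(nrow(mt), 250)
  expect_true(all(diff(mt$frac_mastered_a3) >= 0))   # cumulative
  expect_true(all(mt$frac_mastered_a3 >= 0 & mt$frac_mastered_a3 <= 1))
  defined <- mt$pref_a4_minus_a3[!is.na(mt$pref_a4_minus_a3)]
  expect_true(all(defined >= -1 & defined <= 1))
  # the final mastered fraction matches per-participant mastery flags
  s <- participant_summaries(co$trials)
  frac_direct <- mean(vapply(split(co$trials, co$trials$participant_id),
                             function(tr) mastered(outcome_history(tr), "A3"),
                             logical(1)))
  expect_equal(mt$frac_mastered_a3[250], frac_direct)
})

test_that("with every participant mastered the preference series is undefined", {
  fam_perfect <- list(A1 = rep(1L, 15), A2 = rep(1L, 15), A3 = rep(1L, 15),
                      A4 = rep(1L, 15))
  tr <- make_trials(fam = fam_perfect,
                    free = data.frame(activity = rep(c("A1", "A2", "A3", "A4"), 5),
                                      outcome = 1L))
  mt <- mastery_trajectories(tr)
  expect_equal(mt$frac_mastered_a3, rep(1, nrow(mt)))  # mastered in familiarization
  expect_true(all(is.na(mt$pref_a4_minus_a3)))
  expect_equal(mt$n_nonmasters, rep(0L, nrow(mt)))
})

test_that("uniform agents show no A4-vs-A3 preference on average", {
  cfg <- cohort_config(n_per_group = 10L, master_seed = 19L,
                       weight_sampler = function(n, group)
                         tibble::tibble(w_pc = rep(0, n), w_lp = 0, tau = 0))
  co <- generate_cohort(cfg)
  mt <- mastery_trajectories(co$trials)
  expect_lt(abs(mean(mt$pref_a4_minus_a3, na.rm = TRUE)), 0.1)
})

test_that("circular correlation scores rotations as perfect and reflections as -1", {
  set.seed(23)
  th <- runif(60, -pi, pi)
  expect_equal(circular_cor(th, th), 1)
  expect_equal(circular_cor(th, th + 2.1), 1)      # rigid rotation
  expect_equal(circular_cor(th, -th), -1)          # reflection
  expect_lt(abs(circular_cor(th, runif(60, -pi, pi))), 0.3)
  # small angular noise barely degrades it
  expect_gt(circular_cor(th, th + rnorm(60, 0, 0.05)), 0.95)
})

test_that("recovery experiments recover directions and flag unidentifiable cells", {
  grid <- data.frame(w_pc = c(-1, 0), w_lp = c(0, 1), tau = c(50, 0))
  rec <- recovery_experiment(grid, cohort_config(), n_reps = 3, seed = 9,
                             n_ties = 5)
  expect_equal(rec$identifiable, c(TRUE, FALSE))
  expect_lt(rec$median_w_pc_hat[1], -0.9)
  expect_equal(rec$drive_agreement[1], 1)
  expect_true(is.na(rec$drive_agreement[2]))
})
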