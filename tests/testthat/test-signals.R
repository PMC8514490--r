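hist_from <- function(...) {
  spec <- list(...)
  fam <- lapply(setNames(nm = c("A1", "A2", "A3", "A4")), function(a) {
    if (a %in% names(spec)) as.integer(spec[[a]][1:15]) else rep(1L, 15L)
  })
  outcome_history(make_trials(fam = fam))
}

test_that("recent PC is the mean of the last 15 outcomes", {
  expect_equal(recent_pc(hist_from(A1 = rep(1, 15)), "A1"), 1)
  expect_equal(recent_pc(hist_from(A1 = rep(0, 15)), "A1"), 0)
  h <- hist_from(A2 = c(rep(1, 13), 0, 0))
  expect_equal(recent_pc(h, "A2"), 13 / 15)
  expect_equal(round(100 * recent_pc(h, "A2"), 1), 86.7)
})

test_that("recent PC requires a full window and respects play cutoffs", {
  tr <- make_trials(free = data.frame(activity = rep("A1", 5), outcome = rep(0, 5)))
  h <- outcome_history(tr)
  expect_equal(recent_pc(h, "A1"), 10 / 15)          # last 15 of 20 plays
  expect_equal(recent_pc(h, "A1", n_plays = 15L), 1) # as of familiarization end
  expect_error(recent_pc(h, "A1", n_plays = 10L), ">= 15")
})

test_that("learning progress contrasts early vs late sub-windows", {
  # constant windows carry zero progress
  expect_equal(recent_lp(hist_from(A1 = rep(1, 15)), "A1"), 0)
  expect_equal(recent_lp(hist_from(A1 = rep(0, 15)), "A1"), 0)
  # hand-evaluated default split: positions 1-10 vs 7-15
  h_up <- hist_from(A1 = c(rep(0, 10), rep(1, 5)))
  expect_equal(recent_lp(h_up, "A1"), abs(0 / 10 - 5 / 9))
  expect_equal(recent_lp(h_up, "A1"), 0.5556, tolerance = 1e-4)
  h_down <- hist_from(A1 = c(rep(1, 5), rep(0, 10)))
  expect_equal(recent_lp(h_down, "A1"), abs(5 / 10 - 0 / 9))
})

test_that("LP is symmetric under 0/1 exchange and bounded by 1", {
  set.seed(41)
  for (i in 1:200) {
    w <- sample(0:1, 15, replace = TRUE)
    fam <- list(A1 = w, A2 = 1L - w, A3 = rep(1L, 15), A4 = rep(1L, 15))
    h <- outcome_history(make_trials(fam = fam))
    for (sp in c("10v9", "10v5", "8v7")) {
      lp_w <- recent_lp(h, "A1", lp_split = sp)
      expect_equal(lp_w, recent_lp(h, "A2", lp_split = sp),
                   tolerance = 1e-12)
      expect_true(lp_w >= 0 && lp_w <= 1)
    }
  }
})

test_that("alternative LP splits are non-overlapping and cover the window", {
  for (sp in c("10v5", "8v7")) {
    pos <- lp_split_positions(sp)
    expect_length(intersect(pos$first, pos$second), 0)
    expect_setequal(c(pos$first, pos$second), 1:15)
  }
  pos <- lp_split_positions("10v9")
  expect_identical(pos$first, 1:10)
  expect_identical(pos$second, 7:15)
})

test_that("self-challenge rescales choice PC within the running range", {
  expect_equal(sc_trial(0.4, 0.4, 0.9), 1)
  expect_equal(sc_trial(0.9, 0.4, 0.9), 0)
  expect_equal(sc_trial(0.65, 0.4, 0.9), 0.5)
  expect_true(is.na(sc_trial(0.5, 0.5, 0.5)))
})

test_that("dwfPC applies the rank weights 1/6, 1/3, 1/2", {
  expect_equal(dwfpc(1, 1, 1), 1)
  expect_equal(dwfpc(0.5, 0.5, 0.5), 0.5)
  expect_equal(dwfpc(0.9, 0.8, 0.6), 0.9 / 6 + 0.8 / 3 + 0.6 / 2)
  expect_equal(dwfpc(0.9, 0.8, 0.6), 0.7167, tolerance = 1e-4)
})

test_that("mastery matches an exhaustive window scan on random sequences", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(15:60, 1)
    y <- as.integer(runif(n) < runif(1, 0.3, 0.95))
    extra <- if (n > 15) data.frame(activity = "A1", outcome = y[16:n]) else NULL
    h <- outcome_history(make_trials(fam = list(A1 = y[1:15], A2 = rep(1L, 15),
                                                A3 = rep(1L, 15), A4 = rep(1L, 15)),
                                     free = extra))
    expect_identical(mastered(h, "A1"), oracle_mastered(y))
  }
})

test_that("mastery detects a single qualifying window inside poor performance", {
  y <- c(rep(0L, 10), rep(1L, 12), 0L, 0L, 1L, rep(0L, 20))
  expect_true(oracle_mastered(y))   # window positions 11-25 hold 13 ones
  fam <- y[1:15]
  free <- data.frame(activity = "A1", outcome = y[16:length(y)])
  h <- outcome_history(make_trials(fam = list(A1 = fam, A2 = rep(1L, 15),
                                              A3 = rep(1L, 15), A4 = rep(1L, 15)),
                                   free = free))
  expect_true(mastered(h, "A1"))                       # 13 ones within one window
  expect_false(mastered(h, "A1", scope = "final_window"))
  alt <- as.integer(rep(c(1, 0), 20))                  # alternating: at most 8/15
  h2 <- outcome_history(make_trials(
    fam = list(A1 = alt[1:15], A2 = rep(1L, 15), A3 = rep(1L, 15),
               A4 = rep(1L, 15)),
    free = data.frame(activity = "A1", outcome = alt[16:40])))
  expect_false(mastered(h2, "A1"))
})

test_that("criterion tail probability matches the binomial distribution", {
  expect_equal(criterion_tail_probability(15, 13, 0.5), 121 / 32768)
  expect_equal(round(criterion_tail_probability(15, 13, 0.5), 4), 0.0037)
  expect_equal(criterion_tail_probability(15, 0, 0.5), 1)
  expect_equal(criterion_tail_probability(15, 15, 0.5), 2^-15)
  expect_error(criterion_tail_probability(15, 13, 1.5), "p_chance")
})

test_that("response-bias filter flags modal-response repeaters", {
  tr <- make_trials(free = data.frame(activity = rep("A1", 50),
                                      outcome = rep(1, 50)))
  tr$response <- "f1"
  expect_true(response_bias_flag(tr))
  tr$response <- "f1"   # balance responses within every activity
  for (a in unique(tr$activity)) {
    idx <- which(tr$activity == a)
    tr$response[idx[seq_along(idx) %% 2 == 0]] <- "f2"
  }
  expect_false(response_bias_flag(tr))
  # 50 free-play trials with modal frequency 0.96 on one activity
  tr2 <- make_trials(free = data.frame(activity = rep("A1", 50),
                                       outcome = rep(1, 50)))
  tr2$response <- "balanced"
  tr2$response[tr2$stage == "free_play"] <- c(rep("f1", 48), "f2", "f2")
  tr2$response[tr2$stage == "familiarization"] <-
    rep(c("f1", "f2"), length.out = 60)
  free_only <- tr2[tr2$stage == "free_play", ]
  expect_true(response_bias_flag(free_only, threshold = 0.95))
  expect_false(response_bias_flag(free_only, threshold = 0.97))
  tr2$response <- NULL
  expect_warning(flag <- response_bias_flag(tr2), "response")
  expect_false(flag)
})
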