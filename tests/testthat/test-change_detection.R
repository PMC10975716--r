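test_that("condition models score identical training repetitions identically", {
  ex <- v_execution(amplitude = 50)
  reps <- lapply(1:3, function(r)
    squat_execution("s", 0, r, ex$trajectories))
  cm <- train_condition_model(reps, "hip", N = 3, M = 6, seed = 1)
  lls <- vapply(cm$training_symbols, function(s) forward_loglik(cm$hmm, s),
                numeric(1))
  expect_equal(lls, rep(lls[1], 3))
})

test_that("training improves the fit over the initial model", {
  g <- generate_cohort(generator_params(n_subjects = 1, seed = 23))
  reps <- g$dataset$executions[1:3]
  cm <- train_condition_model(reps, "hip", N = 4, M = 12, seed = 2)
  init <- init_linear_hmm(4, 12, seed = 2)
  ll_trained <- sum(vapply(cm$training_symbols, function(s)
    forward_loglik(cm$hmm, s), numeric(1)))
  ll_init <- sum(vapply(cm$training_symbols, function(s)
    forward_loglik(init, s), numeric(1)))
  expect_gt(ll_trained, ll_init)
})

test_that("classification breaks ties toward the baseline condition and flags them", {
  g <- generate_cohort(generator_params(n_subjects = 1, seed = 29))
  reps <- g$dataset$executions[1:3]
  m0 <- train_condition_model(reps, "hip", N = 2, M = 8, seed = 1)
  m1 <- m0
  m1$load_pct_bw <- 75
  cl <- classify_execution(reps[[1]], "hip", list(m0, m1))
  expect_true(cl$tie)
  expect_equal(cl$label, 0)
  expect_error(classify_execution(reps[[1]], "ankle", list(m0, m1)),
               "marker")
})

test_that("executions from well-separated conditions are attributed correctly", {
  p <- strong_effect_params(seed = 31, n_subjects = 1)
  g <- generate_cohort(p)
  loads <- vapply(g$dataset$executions, `[[`, numeric(1), "load_pct_bw")
  b <- g$dataset$executions[loads == 0]
  l <- g$dataset$executions[loads == 75]
  pooled <- do.call(rbind, lapply(c(b, l), squathmm:::ascent_coords,
                                  marker = "hip"))
  cb <- build_codebook(pooled, 20, seed = 1)
  mb <- train_condition_model(b, "hip", N = 4, M = 20, seed = 1, codebook = cb)
  ml <- train_condition_model(l, "hip", N = 4, M = 20, seed = 1, codebook = cb)
  for (e in b) expect_equal(classify_execution(e, "hip", list(mb, ml))$label, 0)
  for (e in l) expect_equal(classify_execution(e, "hip", list(mb, ml))$label, 75)
})

test_that("indistinguishable conditions yield no minimum state count and rate 1/2", {
  g <- generate_cohort(generator_params(n_subjects = 1, seed = 37))
  loads <- vapply(g$dataset$executions, `[[`, numeric(1), "load_pct_bw")
  b <- g$dataset$executions[loads == 0]
  copy <- lapply(b, function(e) { e$load_pct_bw <- 75; e })
  r <- min_states_search(b, copy, "hip", N_range = 2:5, M = 10, seed = 1)
  expect_true(is.na(r$min_states))
  expect_equal(r$identification_rate, 0.5)
  expect_true(all(r$per_execution_scores$tie))
})

test_that("a strong load effect is recognized with perfect identification", {
  p <- strong_effect_params(seed = 41, n_subjects = 1)
  g <- generate_cohort(p)
  loads <- vapply(g$dataset$executions, `[[`, numeric(1), "load_pct_bw")
  b <- g$dataset$executions[loads == 0]
  l <- g$dataset$executions[loads == 75]
  r <- min_states_search(b, l, "hip", N_range = 2:20, M = 20, seed = 1)
  expect_false(is.na(r$min_states))
  expect_equal(r$identification_rate, 1.0)
  # the reported minimum is minimal: every smaller candidate fell short
  rates <- r$rate_by_N
  smaller <- rates[as.integer(names(rates)) < r$min_states]
  if (length(smaller)) expect_true(all(smaller < 1))
  expect_equal(unname(rates[as.character(r$min_states)]), 1.0)
})

test_that("the search outcome is invariant to execution ordering", {
  p <- strong_effect_params(seed = 43, n_subjects = 1)
  g <- generate_cohort(p)
  loads <- vapply(g$dataset$executions, `[[`, numeric(1), "load_pct_bw")
  b <- g$dataset$executions[loads == 0]
  l <- g$dataset$executions[loads == 75]
  r1 <- min_states_search(b, l, "hip", N_range = 2:10, M = 15, seed = 1)
  r2 <- min_states_search(rev(b), rev(l), "hip", N_range = 2:10, M = 15,
                          seed = 1)
  expect_identical(r1$min_states, r2$min_states)
  expect_equal(r1$identification_rate, r2$identification_rate)
})

test_that("the pipeline is deterministic and its reports are internally consistent", {
  p <- strong_effect_params(seed = 47, n_subjects = 3)
  g <- generate_cohort(p)
  res1 <- run_pipeline(g$dataset, markers = "hip", load_pairs = list(c(0, 75)),
                       N_range = 2:10, M = 15, seed = 5)
  res2 <- run_pipeline(g$dataset, markers = "hip", load_pairs = list(c(0, 75)),
                       N_range = 2:10, M = 15, seed = 5)
  expect_identical(res1$summary, res2$summary)
  for (r in res1$reports) {
    if (!is.na(r$min_states))
      expect_equal(r$identification_rate, 1.0)
  }
  expect_equal(nrow(res1$summary), 3)
})

test_that("detection power rises with effect size on a small synthetic grid", {
  powers <- vapply(c(0, 1, 4), function(eff) {
    hits <- 0L; cases <- 0L
    for (sd in 1:8) {
      p <- generator_params(n_subjects = 2, seed = 600 + sd,
                            loads = c(0, 75), noise_sd = 0.5,
                            load_effect = list("0" = c(0, 0),
                                               "75" = c(eff, eff / 2)))
      g <- generate_cohort(p)
      res <- suppressWarnings(
        run_pipeline(g$dataset, markers = "hip", load_pairs = list(c(0, 75)),
                     N_range = 2:6, M = 15, seed = 1))
      hits <- hits + sum(res$summary$gated &
                           !is.na(res$summary$min_states))
      cases <- cases + nrow(res$summary)
    }
    hits / cases
  }, numeric(1))
  expect_true(all(diff(powers) >= 0))
  expect_lt(powers[1], 0.3)
  expect_gt(powers[3], 0.7)
})

test_that("the wide recognition summary lays out gated cells per subject", {
  p <- strong_effect_params(seed = 53, n_subjects = 3)
  g <- generate_cohort(p)
  res <- run_pipeline(g$dataset, markers = "hip", load_pairs = list(c(0, 75)),
                      N_range = 2:10, M = 15, seed = 5)
  w <- recognition_summary(res, ipc_threshold = 5)
  expect_equal(nrow(w), 1)
  expect_true(all(c("S01", "S02", "S03") %in% names(w)))
  gated <- res$summary$gated
  for (s in res$summary$subject[gated])
    expect_match(w[[s]], "p=")
  expect_true(w$frac_gated_above_threshold >= 0 || is.na(w$frac_gated_above_threshold))
})
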