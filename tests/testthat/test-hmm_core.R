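test_that("codebook construction is deterministic and recovers cluster structure", {
  # M = 1: the single centroid is the coordinate mean
  pts <- cbind(c(1, 2, 3, 10), c(0, 1, -1, 4))
  cb1 <- build_codebook(pts, 1)
  expect_equal(unname(cb1$centroids[1, ]), colMeans(pts), ignore_attr = TRUE)
  # three well-separated clusters
  set.seed(8)
  truth <- rbind(c(0, 0), c(20, 0), c(10, 30))
  pts <- do.call(rbind, lapply(1:3, function(k)
    cbind(stats::rnorm(50, truth[k, 1], 0.3),
          stats::rnorm(50, truth[k, 2], 0.3))))
  cb <- build_codebook(pts, 3, seed = 4)
  ord <- order(truth[, 2], truth[, 1])
  expect_lt(max(abs(cb$centroids - truth[ord, ])), 0.5)
  # determinism and centroid ordering by y then x
  cb2 <- build_codebook(pts, 3, seed = 4)
  expect_identical(cb, cb2)
  expect_false(is.unsorted(cb$centroids[, 2]))
  # M exceeding distinct points
  expect_error(build_codebook(rbind(c(0, 0), c(0, 0), c(1, 1)), 3),
               "distinct")
})

test_that("quantization matches exhaustive nearest-centroid search with low-index ties", {
  cb <- build_codebook(rbind(c(0, 0), c(4, 0), c(2, 5), c(0, 6), c(5, 5)), 5,
                       seed = 0)
  # all frames at a centroid location
  at2 <- matrix(rep(cb$centroids[2, ], 7), ncol = 2, byrow = TRUE)
  expect_equal(quantize(at2, cb), rep(2L, 7))
  # equidistant point takes the lowest centroid index
  mid <- (cb$centroids[1, ] + cb$centroids[2, ]) / 2
  expect_equal(quantize(rbind(mid), cb), 1L)
  # random coordinates vs brute-force scan
  set.seed(31)
  pts <- cbind(stats::runif(200, -1, 6), stats::runif(200, -1, 7))
  brute <- apply(pts, 1, function(p)
    which.min(colSums((t(cb$centroids) - p)^2)))
  expect_equal(quantize(pts, cb), as.integer(brute))
  # trajectory interface with a phase window
  tr <- marker_trajectory("hip", 0:9, x = pts[1:10, 1], y = pts[1:10, 2])
  expect_equal(quantize(tr, cb, phase = 3:7),
               as.integer(brute[3:7]))
})

test_that("initial linear model has the left-right structure and valid rows", {
  h1 <- init_linear_hmm(1, 4)
  expect_equal(h1$A, matrix(1, 1, 1))
  expect_equal(h1$pi, 1)
  h3 <- init_linear_hmm(3, 5, seed = 2)
  expect_equal(sum(h3$A != 0), 5)        # 2(N-1) + 1 allowed entries
  expect_equal(h3$A[3, 3], 1)
  expect_equal(h3$A[lower.tri(h3$A)], rep(0, 3))
  set.seed(40)
  for (k in 1:15) {
    N <- sample(1:6, 1); M <- sample(1:8, 1)
    h <- init_linear_hmm(N, M, seed = k)
    expect_equal(rowSums(h$A), rep(1, N))
    expect_equal(rowSums(h$B), rep(1, N))
    expect_equal(h$pi, c(1, rep(0, N - 1)))
  }
  expect_error(init_linear_hmm(0, 3), "N and M")
})

test_that("forward log-likelihood agrees with exhaustive path enumeration", {
  # N = 1 closed form: sum of emission log-probabilities
  h1 <- init_linear_hmm(1, 3, seed = 1)
  obs <- c(1L, 3L, 2L, 2L)
  expect_equal(forward_loglik(h1, obs), sum(log(h1$B[1, obs])))
  # impossible symbol (emission prob exactly zero in all reachable states)
  h0 <- squathmm:::new_dhmm(2, 2, rbind(c(0.5, 0.5), c(0, 1)),
                            rbind(c(1, 0), c(1, 0)), c(1, 0))
  expect_identical(forward_loglik(h0, c(1L, 2L)), -Inf)
  expect_error(forward_loglik(h1, 4L), "symbol")
  # randomized equivalence with the brute-force path sum
  set.seed(77)
  for (k in 1:40) {
    N <- sample(1:3, 1); M <- sample(1:3, 1); Tn <- sample(1:6, 1)
    h <- random_linear_hmm(N, M)
    obs <- sample.int(M, Tn, replace = TRUE)
    expect_equal(forward_loglik(h, obs), enumerate_loglik(h, obs),
                 tolerance = 1e-10)
  }
})

test_that("Baum-Welch increases likelihood, preserves topology and recovers parameters", {
  # monotone non-decreasing log-likelihood on random problems
  set.seed(55)
  for (k in 1:10) {
    N <- sample(2:4, 1); M <- sample(3:6, 1)
    seqs <- lapply(1:3, function(i) sample.int(M, 30, replace = TRUE))
    fit <- baum_welch(init_linear_hmm(N, M, seed = k), seqs)
    ll <- fit$iterations$loglik
    expect_true(all(diff(ll) >= -1e-8))
    # structural zeros stay exactly zero; stochasticity preserved
    expect_equal(fit$A[lower.tri(fit$A)], rep(0, N * (N - 1) / 2))
    upper <- fit$A[upper.tri(fit$A)]
    allowed <- outer(1:N, 1:N, function(i, j) j == i + 1)[upper.tri(fit$A)]
    expect_equal(upper[!allowed], rep(0, sum(!allowed)))
    expect_equal(rowSums(fit$A), rep(1, N), tolerance = 1e-9)
    expect_equal(rowSums(fit$B), rep(1, N), tolerance = 1e-9)
    expect_equal(sum(fit$pi), 1, tolerance = 1e-9)
  }
})

test_that("Baum-Welch closed forms hold in degenerate settings", {
  # single repeated symbol, N = 1: emissions converge to an indicator
  fit <- baum_welch(init_linear_hmm(1, 3, seed = 9), list(rep(2L, 50)))
  expect_gt(fit$B[1, 2], 1 - 3e-6)
  expect_lt(max(fit$B[1, -2]), 2e-6)
})

test_that("Baum-Welch recovers a known two-state model from simulated sequences", {
  A <- rbind(c(0.9, 0.1), c(0, 1))
  B <- rbind(c(0.8, 0.15, 0.05), c(0.1, 0.2, 0.7))
  truth <- squathmm:::new_dhmm(2, 3, A, B, c(1, 0))
  seqs <- simulate(truth, nsim = 10, seed = 123, length_out = 200)
  fit <- baum_welch(init_linear_hmm(2, 3, seed = 3), seqs)
  # align states (linear order can only match identically or flipped)
  l1 <- sum(abs(fit$B - B))
  l1_flip <- sum(abs(fit$B[2:1, ] - B))
  expect_lt(min(l1, l1_flip) / 2, 0.1)   # per-row L1 below 0.1
})

test_that("model JSON serialization round-trips probabilities bit-exactly", {
  g <- generate_cohort(generator_params(n_subjects = 1, seed = 17))
  cm <- train_condition_model(g$dataset$executions[1:3], "hip", N = 3, M = 8,
                              seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_dhmm_json(cm$hmm, f, codebook = cm$codebook)
  back <- read_dhmm_json(f)
  expect_identical(back$hmm$A, cm$hmm$A)
  expect_identical(back$hmm$B, cm$hmm$B)
  expect_identical(back$hmm$pi, cm$hmm$pi)
  expect_identical(back$codebook$centroids, cm$codebook$centroids)
})
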