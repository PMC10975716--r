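# Shared fixtures and independent oracles for the test suite.

# V-shaped noiseless execution: linear descent then ascent of the given
# amplitude, minimum exactly at frame `split` (0-based).
v_execution <- function(amplitude = 60, n_frames = 91L, split = 45L,
                        subject = "S01", load = 0, rep = 1L) {
  fr <- seq_len(n_frames) - 1L
  y <- ifelse(fr <= split, -amplitude * fr / split,
              -amplitude * (1 - (fr - split) / (n_frames - 1L - split)))
  trajs <- lapply(c("barbell", "hip", "knee", "ankle"), function(m) {
    sc <- c(barbell = 1, hip = 0.5, knee = 0.15, ankle = 0.01)[[m]]
    marker_trajectory(m, fr, x = rep(0, n_frames), y = sc * y)
  })
  squat_execution(subject, load, rep, trajs)
}

# brute-force forward likelihood: sum over all N^T state paths of
# pi * prod A * prod B (direct evaluation of the marginal likelihood)
enumerate_loglik <- function(hmm, symbols) {
  N <- hmm$N
  Tn <- length(symbols)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- hmm$pi[s[1L]] * hmm$B[s[1L], symbols[1L]]
    if (Tn > 1L) for (t in 2L:Tn)
      p <- p * hmm$A[s[t - 1L], s[t]] * hmm$B[s[t], symbols[t]]
    total <- total + p
  }
  log(total)
}

# random valid linear-topology HMM (structure as init_linear_hmm, but with
# random row-stochastic parameters on the allowed support)
random_linear_hmm <- function(N, M) {
  A <- matrix(0, N, N)
  if (N > 1L) for (i in seq_len(N - 1L)) {
    p <- stats::runif(1, 0.05, 0.95)
    A[i, i] <- p; A[i, i + 1L] <- 1 - p
  }
  A[N, N] <- 1
  B <- matrix(stats::rgamma(N * M, 1), N, M)
  B <- B / rowSums(B)
  pi <- c(1, rep(0, N - 1L))
  squathmm:::new_dhmm(N, M, A, B, pi)
}

# long-format rating table from two verdict vectors
rating_table <- function(a, b, raters = c("r1", "r2")) {
  n <- length(a)
  rbind(data.frame(item = seq_len(n), rater = raters[1L], verdict = a),
        data.frame(item = seq_len(n), rater = raters[2L], verdict = b))
}

strong_effect_params <- function(seed, n_subjects = 10L)
  generator_params(n_subjects = n_subjects, seed = seed,
                   load_effect = list("0" = c(0, 0), "50" = c(2, 1),
                                      "75" = c(4, 2)))
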