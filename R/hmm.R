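## Discrete hidden Markov machinery: K-means vector quantization of 2D
## trajectories, linear (left-right) topology, Baum-Welch training,
## forward-algorithm likelihood.

## run expr with a private RNG stream; the caller's .Random.seed is untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build a vector-quantization codebook by K-means
#'
#' Clusters 2D ascent-phase coordinates with Lloyd's algorithm started from
#' k-means++ seeds drawn under \code{seed}. The returned centroids are ordered
#' by ascending y, then x, so the codebook (and every symbol sequence derived
#' from it) is deterministic for a given input and seed.
#'
#' @param coordinates numeric matrix (or data frame) with two columns (x, y)
#'   in cm; one row per frame.
#' @param M number of centroids (the discrete observation alphabet size).
#' @param seed integer seed for the k-means++ initialization.
#' @return Object of class \code{"codebook"}: list with \code{centroids}
#'   (M x 2 matrix) and \code{M}.
#' @export
build_codebook <- function(coordinates, M, seed = 0L) {
  pts <- as.matrix(coordinates)
  if (ncol(pts) != 2L || !is.numeric(pts) || !all(is.finite(pts)))
    stop("coordinates must be a finite numeric 2-column matrix", call. = FALSE)
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1", call. = FALSE)
  ndistinct <- nrow(unique(pts))
  if (ndistinct < M)
    stop("fewer distinct coordinates (", ndistinct, ") than codebook size ",
         M, "; lower M", call. = FALSE)
  if (M == 1L) {
    cent <- matrix(colMeans(pts), 1L, 2L)
  } else {
    init <- with_seed(seed, kmeanspp_centers(pts, M))
    km <- suppressWarnings(stats::kmeans(pts, centers = init,
                                         iter.max = 100L,
                                         algorithm = "Lloyd"))
    cent <- km$centers
  }
  ord <- order(cent[, 2L], cent[, 1L])
  cent <- cent[ord, , drop = FALSE]
  dimnames(cent) <- list(NULL, c("x", "y"))
  structure(list(centroids = cent, M = M), class = "codebook")
}

## k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
## each next center with probability proportional to squared distance to the
## nearest chosen center
kmeanspp_centers <- function(pts, M) {
  n <- nrow(pts)
  centers <- matrix(NA_real_, M, 2L)
  idx <- sample.int(n, 1L)
  centers[1L, ] <- pts[idx, ]
  d2 <- rowSums((pts - matrix(centers[1L, ], n, 2L, byrow = TRUE))^2)
  for (m in 2L:M) {
    if (all(d2 == 0)) {
      ## remaining mass degenerate: pick any not-yet-chosen distinct point
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[m, ] <- pts[idx, ]
    d2m <- rowSums((pts - matrix(centers[m, ], n, 2L, byrow = TRUE))^2)
    d2 <- pmin(d2, d2m)
  }
  ## Lloyd in stats::kmeans requires distinct centers
  if (anyDuplicated(centers)) {
    dup <- which(duplicated(centers))
    pool <- unique(pts)
    for (j in dup) {
      cand <- pool[!apply(pool, 1L, function(p)
        any(rowSums((centers - matrix(p, nrow(centers), 2L,
                                      byrow = TRUE))^2) == 0, na.rm = TRUE)), ,
        drop = FALSE]
      centers[j, ] <- cand[1L, ]
    }
  }
  centers
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> M = %d centroids (cm), y-range [%.2f, %.2f]\n",
              x$M, min(x$centroids[, 2L]), max(x$centroids[, 2L])))
  invisible(x)
}

#' Quantize a trajectory phase into observation symbols
#'
#' Maps each frame of the chosen phase to the index (1..M) of the nearest
#' codebook centroid in Euclidean distance; ties go to the lowest index.
#'
#' @param trajectory a \code{\link{marker_trajectory}} or a 2-column numeric
#'   matrix of coordinates.
#' @param codebook a \code{\link{build_codebook}} result.
#' @param phase integer sample indices to quantize (default: all frames);
#'   ignored when \code{trajectory} is already a matrix.
#' @return Integer vector of symbols in 1..M.
#' @export
quantize <- function(trajectory, codebook, phase = NULL) {
  stopifnot(inherits(codebook, "codebook"))
  if (inherits(trajectory, "marker_trajectory")) {
    if (is.null(phase)) phase <- seq_along(trajectory$frame)
    phase <- as.integer(phase)
    if (!length(phase) || any(phase < 1L) ||
        any(phase > length(trajectory$frame)))
      stop("empty or out-of-range phase", call. = FALSE)
    pts <- cbind(trajectory$x[phase], trajectory$y[phase])
  } else {
    pts <- as.matrix(trajectory)
    if (!nrow(pts)) stop("empty coordinate set", call. = FALSE)
  }
  cent <- codebook$centroids
  ## n x M squared distances; max.col(-d2, "first") gives lowest-index ties
  d2 <- outer(pts[, 1L], cent[, 1L], "-")^2 + outer(pts[, 2L], cent[, 2L], "-")^2
  max.col(-d2, ties.method = "first")
}

#' Initial linear-topology discrete HMM
#'
#' Builds a left-right discrete HMM with N states and M symbols: each state
#' transitions only to itself or to the next state (probability 0.5 each at
#' initialization; the last state self-loops with probability 1, there is no
#' return from the last state to the first), the chain starts in state 1
#' (\eqn{\pi = (1, 0, \ldots, 0)}), and emission rows are a seeded small
#' random perturbation of the uniform distribution — perturbed so Baum-Welch
#' can break symmetry between states.
#'
#' @param N number of hidden states (\eqn{\ge 1}).
#' @param M number of observation symbols (\eqn{\ge 1}).
#' @param seed integer seed for the emission perturbation.
#' @return Object of class \code{"dhmm"}: list with \code{N}, \code{M},
#'   \code{A} (N x N), \code{B} (N x M), \code{pi} (length N) and bookkeeping
#'   fields.
#' @export
init_linear_hmm <- function(N, M, seed = 0L) {
  N <- as.integer(N); M <- as.integer(M)
  if (N < 1L || M < 1L) stop("N and M must be >= 1", call. = FALSE)
  A <- matrix(0, N, N)
  if (N > 1L) {
    for (i in seq_len(N - 1L)) {
      A[i, i] <- 0.5
      A[i, i + 1L] <- 0.5
    }
  }
  A[N, N] <- 1
  B <- with_seed(seed, {
    raw <- matrix(1, N, M) + matrix(stats::runif(N * M, -0.05, 0.05), N, M)
    raw / rowSums(raw)
  })
  pi <- c(1, rep(0, N - 1L))
  new_dhmm(N, M, A, B, pi, seed = seed)
}

new_dhmm <- function(N, M, A, B, pi, seed = NA_integer_, trained = FALSE,
                     iterations = NULL) {
  hmm <- structure(list(N = N, M = M, A = A, B = B, pi = pi, seed = seed,
                        trained = trained, iterations = iterations),
                   class = "dhmm")
  validate_dhmm(hmm)
  hmm
}

validate_dhmm <- function(hmm, tol = 1e-9) {
  stopifnot(nrow(hmm$A) == hmm$N, ncol(hmm$A) == hmm$N,
            nrow(hmm$B) == hmm$N, ncol(hmm$B) == hmm$M,
            length(hmm$pi) == hmm$N)
  if (any(abs(rowSums(hmm$A) - 1) > tol)) stop("A rows must sum to 1")
  if (any(abs(rowSums(hmm$B) - 1) > tol)) stop("B rows must sum to 1")
  if (abs(sum(hmm$pi) - 1) > tol) stop("pi must sum to 1")
  if (hmm$N > 1L) {
    allowed <- diag(1, hmm$N)
    for (i in seq_len(hmm$N - 1L)) allowed[i, i + 1L] <- 1
    if (any(hmm$A[allowed == 0] != 0))
      stop("linear topology violated: transition outside {self, next}")
  }
  invisible(hmm)
}

#' @export
print.dhmm <- function(x, ...) {
  cat(sprintf("<dhmm> linear topology, N = %d states, M = %d symbols%s\n",
              x$N, x$M,
              if (isTRUE(x$trained))
                sprintf(" (Baum-Welch trained, %d iterations, logLik %.4f)",
                        nrow(x$iterations), x$iterations$loglik[nrow(x$iterations)])
              else " (untrained)"))
  invisible(x)
}

#' @export
summary.dhmm <- function(object, ...) {
  print(object)
  cat("Transition self-loop probabilities:\n")
  print(round(diag(object$A), 4))
  if (!is.null(object$iterations)) {
    cat("Training log-likelihood by iteration (first/last 3):\n")
    ll <- object$iterations$loglik
    show <- unique(c(seq_len(min(3L, length(ll))),
                     seq.int(max(1L, length(ll) - 2L), length(ll))))
    print(round(stats::setNames(ll[show], paste0("it", show)), 4))
  }
  invisible(object)
}

#' @export
logLik.dhmm <- function(object, ...) {
  if (is.null(object$iterations))
    stop("untrained model has no stored training log-likelihood", call. = FALSE)
  ll <- object$iterations$loglik[nrow(object$iterations)]
  ## free parameters: self-loop probs for N-1 states + N rows of M-1 emissions
  attr(ll, "df") <- (object$N - 1L) + object$N * (object$M - 1L)
  class(ll) <- "logLik"
  ll
}

#' Simulate observation sequences from a discrete HMM
#'
#' @param object a \code{dhmm}.
#' @param nsim number of sequences.
#' @param seed integer seed.
#' @param length_out length of each sequence.
#' @param ... unused.
#' @return List of integer symbol vectors (values in 1..M).
#' @export
simulate.dhmm <- function(object, nsim = 1, seed = 0L, length_out = 50L, ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(dummy) {
      s <- sample.int(object$N, 1L, prob = object$pi)
      out <- integer(length_out)
      for (t in seq_len(length_out)) {
        out[t] <- sample.int(object$M, 1L, prob = object$B[s, ])
        s <- sample.int(object$N, 1L, prob = object$A[s, ])
      }
      out
    })
  })
}

check_symbols <- function(hmm, symbols) {
  symbols <- as.integer(symbols)
  if (!length(symbols)) stop("empty symbol sequence", call. = FALSE)
  if (any(symbols < 1L) || any(symbols > hmm$M))
    stop("symbol outside 1..M", call. = FALSE)
  symbols
}

#' Forward-algorithm log-likelihood
#'
#' Computes \eqn{\log P(O \mid \lambda)} of a discrete observation sequence
#' under the model by the forward recursion in log space (log-sum-exp), so
#' long sequences cannot underflow. Returns \code{-Inf} when the sequence is
#' impossible under the model.
#'
#' @param hmm a \code{dhmm}.
#' @param symbols integer vector of observation symbols in 1..M.
#' @return Log-likelihood (scalar, possibly \code{-Inf}).
#' @export
forward_loglik <- function(hmm, symbols) {
  symbols <- check_symbols(hmm, symbols)
  logA <- log(hmm$A)
  logB <- log(hmm$B)
  alpha <- log(hmm$pi) + logB[, symbols[1L]]
  Tn <- length(symbols)
  if (Tn > 1L) {
    for (t in 2L:Tn) {
      ## alpha_j(t) = logsumexp_i(alpha_i + logA_ij) + logB_j(o_t)
      m <- matrix(alpha, hmm$N, hmm$N) + logA      # rows i, cols j
      alpha <- apply(m, 2L, logsumexp) + logB[, symbols[t]]
    }
  }
  logsumexp(alpha)
}

logsumexp <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(v - mx)))
}

#' Baum-Welch training of a discrete HMM
#'
#' Multi-sequence expectation-maximization re-estimation of the transition,
#' emission and initial probabilities. Expected counts from all sequences are
#' pooled before each re-estimation. Structural zeros of the linear topology
#' are preserved exactly (zero transition probabilities never become
#' positive). After each M step the emission matrix is floored at
#' \code{emission_floor} and row-renormalized so held-out sequences that use
#' unseen symbols remain scoreable. Training stops when the relative change
#' of the total log-likelihood falls below \code{tol} or after
#' \code{max_iter} iterations.
#'
#' @param hmm an initial \code{dhmm} (e.g. \code{\link{init_linear_hmm}}).
#' @param sequences list of integer symbol vectors (each in 1..M).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood change convergence threshold
#'   (default 1e-6).
#' @param emission_floor lower bound applied to emission probabilities after
#'   each update (default 1e-6).
#' @return A trained \code{dhmm}; element \code{iterations} is a data frame
#'   with the log-likelihood at each iteration and a \code{degenerate} flag
#'   marking iterations where a state with no expected occupancy had its
#'   emission row reset to uniform.
#' @export
baum_welch <- function(hmm, sequences, max_iter = 200L, tol = 1e-6,
                       emission_floor = 1e-6) {
  stopifnot(inherits(hmm, "dhmm"))
  if (!is.list(sequences)) sequences <- list(sequences)
  sequences <- lapply(sequences, check_symbols, hmm = hmm)
  N <- hmm$N; M <- hmm$M
  A <- hmm$A; B <- hmm$B; pi <- hmm$pi
  mask <- A > 0                      # structural support of the topology
  ll_trace <- numeric(0)
  degen_trace <- logical(0)
  prev_ll <- -Inf
  for (it in seq_len(max_iter)) {
    xi_d <- numeric(N)             # expected self-loop counts
    xi_u <- numeric(max(0L, N - 1L))   # expected forward-step counts
    B_num <- matrix(0, N, M)
    pi_num <- numeric(N)
    total_ll <- 0
    for (obs in sequences) {
      fb <- forward_backward(A, B, pi, obs)
      total_ll <- total_ll + fb$loglik
      if (!is.finite(fb$loglik)) next   # impossible sequence contributes nothing
      pi_num <- pi_num + fb$gamma[, 1L]
      rs <- rowsum(t(fb$gamma), group = obs)       # per-symbol occupancy
      sym <- as.integer(rownames(rs))
      B_num[, sym] <- B_num[, sym] + t(rs)
      xi_d <- xi_d + fb$xi_d
      if (N > 1L) xi_u <- xi_u + fb$xi_u
    }
    ll_trace <- c(ll_trace, total_ll)
    ## M step; the transition denominator is the expected count of leaving
    ## each state, which for the bidiagonal support is xi_d + xi_u
    degenerate <- FALSE
    A_new <- matrix(0, N, N)
    for (i in seq_len(N)) {
      out_i <- xi_d[i] + if (i < N) xi_u[i] else 0
      if (out_i > 0) {
        A_new[i, i] <- xi_d[i] / out_i
        if (i < N) A_new[i, i + 1L] <- xi_u[i] / out_i
      } else {
        ## state never occupied before the sequence end: uniform over allowed
        A_new[i, mask[i, ]] <- 1 / sum(mask[i, ])
        if (i < N) degenerate <- TRUE
      }
    }
    A_new[N, N] <- 1
    B_new <- B
    occ <- rowSums(B_num)
    for (i in seq_len(N)) {
      if (occ[i] > 0) B_new[i, ] <- B_num[i, ] / occ[i]
      else { B_new[i, ] <- 1 / M; degenerate <- TRUE }
    }
    B_new[B_new < emission_floor] <- emission_floor
    B_new <- B_new / rowSums(B_new)
    pi_new <- pi_num / sum(pi_num)
    ## structural zeros of pi (linear topology starts in state 1) stay zero
    pi_new[pi == 0] <- 0
    s <- sum(pi_new)
    pi_new <- if (s > 0) pi_new / s else pi
    A <- A_new; B <- B_new; pi <- pi_new
    degen_trace <- c(degen_trace, degenerate)
    if (is.finite(total_ll) && is.finite(prev_ll) &&
        abs(total_ll - prev_ll) <= tol * abs(prev_ll)) break
    prev_ll <- total_ll
  }
  new_dhmm(N, M, A, B, pi, seed = hmm$seed, trained = TRUE,
           iterations = data.frame(iteration = seq_along(ll_trace),
                                   loglik = ll_trace,
                                   degenerate = degen_trace))
}

## scaled forward-backward specialized to the linear (left-right) topology:
## A is bidiagonal, represented by its diagonal d and superdiagonal u, so
## every recursion step is O(N) vector work and the expected transition
## counts vectorize over time. Returns loglik, gamma (N x T), and the
## expected transition counts xi_d (self-loops) and xi_u (forward steps).
forward_backward <- function(A, B, pi, obs) {
  N <- nrow(A); Tn <- length(obs)
  d <- diag(A)
  u <- if (N > 1L) A[cbind(seq_len(N - 1L), 2L:N)] else numeric(0)
  Bobs <- B[, obs, drop = FALSE]                # N x T emission lookups
  if (N == 1L) dim(Bobs) <- c(1L, Tn)
  alpha <- matrix(0, N, Tn)
  scale <- numeric(Tn)
  a <- pi * Bobs[, 1L]
  scale[1L] <- sum(a)
  if (scale[1L] == 0) return(fb_impossible(N, Tn))
  alpha[, 1L] <- a / scale[1L]
  if (Tn > 1L) {
    for (t in 2L:Tn) {
      ap <- alpha[, t - 1L]
      a <- ap * d
      if (N > 1L) a[2L:N] <- a[2L:N] + ap[1L:(N - 1L)] * u
      a <- a * Bobs[, t]
      scale[t] <- sum(a)
      if (scale[t] == 0) return(fb_impossible(N, Tn))
      alpha[, t] <- a / scale[t]
    }
  }
  beta <- matrix(0, N, Tn)
  beta[, Tn] <- 1
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) {
      z <- Bobs[, t + 1L] * beta[, t + 1L]
      b <- d * z
      if (N > 1L) b[1L:(N - 1L)] <- b[1L:(N - 1L)] + u * z[2L:N]
      beta[, t] <- b / scale[t + 1L]
    }
  }
  gamma <- alpha * beta
  gamma <- sweep(gamma, 2L, colSums(gamma), "/")
  if (Tn > 1L) {
    ## z[j, t] = B_j(o_{t+1}) * beta_j(t+1) / scale(t+1), t = 1..T-1
    z <- (Bobs[, 2L:Tn, drop = FALSE] * beta[, 2L:Tn, drop = FALSE]) /
      matrix(scale[2L:Tn], N, Tn - 1L, byrow = TRUE)
    al <- alpha[, 1L:(Tn - 1L), drop = FALSE]
    xi_d <- d * rowSums(al * z)
    xi_u <- if (N > 1L)
      u * rowSums(al[1L:(N - 1L), , drop = FALSE] * z[2L:N, , drop = FALSE])
      else numeric(0)
  } else {
    xi_d <- numeric(N); xi_u <- numeric(max(0L, N - 1L))
  }
  list(loglik = sum(log(scale)), gamma = gamma, xi_d = xi_d, xi_u = xi_u)
}

fb_impossible <- function(N, Tn) {
  list(loglik = -Inf, gamma = matrix(0, N, Tn), xi_d = numeric(N),
       xi_u = numeric(max(0L, N - 1L)))
}

#' Serialize a discrete HMM (with optional codebook) to JSON
#'
#' Probabilities are written as decimal strings with 17 significant digits,
#' enough for a bit-exact double round trip.
#'
#' @param hmm a \code{dhmm}.
#' @param path output file; if \code{NULL}, the JSON string is returned.
#' @param codebook optional \code{codebook} stored alongside the model.
#' @return \code{path} invisibly, or the JSON string.
#' @export
write_dhmm_json <- function(hmm, path = NULL, codebook = NULL) {
  stopifnot(inherits(hmm, "dhmm"))
  fmt <- function(x) {
    d <- dim(x)
    s <- sprintf("%.17g", as.numeric(x))
    if (is.null(d)) s else matrix(s, d[1L], d[2L])
  }
  doc <- list(N = hmm$N, M = hmm$M, A = fmt(hmm$A), B = fmt(hmm$B),
              pi = fmt(hmm$pi), seed = hmm$seed,
              training_meta = hmm$iterations)
  if (!is.null(codebook)) doc$codebook <- fmt(codebook$centroids)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Deserialize a discrete HMM written by \code{\link{write_dhmm_json}}
#'
#' @param path JSON file path or JSON string.
#' @return List with elements \code{hmm} (a \code{dhmm}) and \code{codebook}
#'   (a \code{codebook} or \code{NULL}).
#' @export
read_dhmm_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  num <- function(x) {
    if (is.null(dim(x))) as.numeric(x)
    else matrix(as.numeric(x), nrow(x), ncol(x))
  }
  iters <- if (!is.null(doc$training_meta) && length(doc$training_meta))
    as.data.frame(doc$training_meta) else NULL
  hmm <- new_dhmm(as.integer(doc$N), as.integer(doc$M), num(doc$A), num(doc$B),
                  num(doc$pi), seed = doc$seed,
                  trained = !is.null(iters), iterations = iters)
  cb <- NULL
  if (!is.null(doc$codebook)) {
    cent <- num(doc$codebook)
    dimnames(cent) <- list(NULL, c("x", "y"))
    cb <- structure(list(centroids = cent, M = nrow(cent)), class = "codebook")
  }
  list(hmm = hmm, codebook = cb)
}
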