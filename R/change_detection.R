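## Intrasubject detection of load-induced movement-pattern change: per-load
## condition models (codebook + linear HMM), maximum-likelihood
## classification of executions, and the search for the minimum number of
## hidden states at which all executions are attributed to their own load.

## ascent-phase coordinates of one marker, re-zeroed to the ascent start so
## models compare movement shape, not absolute station position
ascent_coords <- function(execution, marker, reference_marker = "barbell") {
  if (!marker %in% names(execution$trajectories))
    stop("marker '", marker, "' absent from execution", call. = FALSE)
  if (is.null(execution$phase_split))
    execution <- split_phases(execution, reference_marker)
  idx <- ascent_indices(execution)
  tr <- execution$trajectories[[marker]]
  cbind(x = tr$x[idx] - tr$x[idx[1L]], y = tr$y[idx] - tr$y[idx[1L]])
}

#' Train a condition model for one subject, marker and load
#'
#' Builds the vector-quantization codebook from the pooled ascent-phase
#' coordinates of the training executions, quantizes each execution, and
#' trains a linear-topology discrete HMM on all resulting symbol sequences by
#' Baum-Welch — the per-condition reference against which other executions
#' are scored.
#'
#' @param executions list of \code{\link{squat_execution}}s of one condition.
#' @param marker marker to model.
#' @param N number of hidden states.
#' @param M codebook size (observation alphabet).
#' @param seed integer seed (k-means++ and emission initialization).
#' @param reference_marker marker defining the phase split.
#' @param codebook optional prebuilt \code{codebook} (e.g. one shared between
#'   conditions); built from the training executions when \code{NULL}.
#' @return Object of class \code{"condition_model"}: subject, marker, load,
#'   \code{codebook}, \code{hmm}, and the training sequences' symbols.
#' @export
train_condition_model <- function(executions, marker, N, M = 20L, seed = 0L,
                                  reference_marker = "barbell",
                                  codebook = NULL) {
  stopifnot(length(executions) >= 1L)
  coords <- lapply(executions, ascent_coords, marker = marker,
                   reference_marker = reference_marker)
  pooled <- do.call(rbind, coords)
  if (is.null(codebook)) codebook <- build_codebook(pooled, M, seed = seed)
  stopifnot(inherits(codebook, "codebook"))
  seqs <- lapply(coords, quantize, codebook = codebook)
  hmm <- baum_welch(init_linear_hmm(N, M, seed = seed), seqs)
  structure(list(subject_id = executions[[1L]]$subject_id,
                 marker_id = marker,
                 load_pct_bw = executions[[1L]]$load_pct_bw,
                 codebook = codebook, hmm = hmm, training_symbols = seqs),
            class = "condition_model")
}

#' @export
print.condition_model <- function(x, ...) {
  cat(sprintf("<condition_model> subject %s, %s marker, %g%%BW: M = %d, N = %d\n",
              x$subject_id, x$marker_id, x$load_pct_bw, x$codebook$M, x$hmm$N))
  invisible(x)
}

#' Classify an execution against competing condition models
#'
#' Each model quantizes the execution's ascent-phase coordinates with its own
#' codebook and scores the symbol sequence with the forward algorithm; the
#' execution is attributed to the condition whose model gives the maximum
#' log-likelihood. Exact ties go to the baseline (lowest-load) model and are
#' flagged.
#'
#' @param execution a \code{\link{squat_execution}}.
#' @param marker marker to score.
#' @param models list of \code{condition_model}s for the same marker.
#' @param reference_marker marker defining the phase split.
#' @return List with \code{label} (the winning load), \code{loglik} (named
#'   per-model log-likelihoods) and \code{tie}.
#' @export
classify_execution <- function(execution, marker, models,
                               reference_marker = "barbell") {
  stopifnot(length(models) >= 2L)
  if (!all(vapply(models, `[[`, character(1), "marker_id") == marker))
    stop("all models must target marker '", marker, "'", call. = FALSE)
  coords <- ascent_coords(execution, marker, reference_marker)
  loads <- vapply(models, `[[`, numeric(1), "load_pct_bw")
  ll <- vapply(models, function(m) {
    forward_loglik(m$hmm, quantize(coords, m$codebook))
  }, numeric(1))
  names(ll) <- as.character(loads)
  best <- max(ll)
  winners <- which(ll == best)
  tie <- length(winners) > 1L
  label <- loads[winners[which.min(loads[winners])]]
  list(label = label, loglik = ll, tie = tie)
}

#' Minimum-states search for load-change recognition
#'
#' For each candidate state count N (ascending), one condition model is
#' trained per load and every execution is attributed to a condition;
#' the search returns the first N at which the identification rate is 1.0 —
#' the minimum number of hidden states needed to recognize the difference
#' between baseline and loaded movement patterns. By default identification
#' follows the reference protocol: every execution is scored under models
#' trained on all executions of its own condition (resubstitution — the
#' three repetitions per condition are both the training base and the tested
#' material), with a codebook shared by both conditions so symbols are
#' comparable across models. \code{resubstitution = FALSE} instead assesses
#' identification leave-one-out: each execution is held out, the model of
#' its own condition is retrained on that condition's remaining executions
#' (the competing condition keeps all of its executions, but shares the
#' fold's codebook when \code{shared_codebook}), and the held-out execution
#' is classified. Leave-one-out is the honest out-of-sample protocol, but
#' with only three repetitions per condition it is biased toward the
#' competing (larger-sample) model; see the package vignette.
#'
#' @param baseline_execs,loaded_execs executions of the two conditions
#'   (at least 2 each for leave-one-out).
#' @param marker marker to model.
#' @param N_range ascending integer vector of candidate state counts.
#' @param M codebook size.
#' @param seed integer seed.
#' @param shared_codebook if TRUE (default), both conditions share one
#'   codebook built from the pooled coordinates of both training sets.
#' @param resubstitution score training executions directly (default, the
#'   reference protocol) instead of leave-one-out.
#' @param reference_marker marker defining the phase split.
#' @return Object of class \code{"change_report"}: subject, marker,
#'   \code{load_pair}, \code{anova_p} (NA here; filled by
#'   \code{\link{run_pipeline}}), \code{min_states} (or NA), the
#'   \code{identification_rate} achieved at \code{min_states} (or the best
#'   rate found), \code{rate_by_N}, and \code{per_execution_scores}.
#' @export
min_states_search <- function(baseline_execs, loaded_execs, marker,
                              N_range = 2:50, M = 20L, seed = 0L,
                              shared_codebook = TRUE,
                              resubstitution = TRUE,
                              reference_marker = "barbell") {
  N_range <- as.integer(N_range)
  stopifnot(length(N_range) >= 1L, !is.unsorted(N_range))
  if (!resubstitution &&
      (length(baseline_execs) < 2L || length(loaded_execs) < 2L))
    stop("leave-one-out needs at least 2 executions per condition",
         call. = FALSE)
  conds <- list(baseline = baseline_execs, loaded = loaded_execs)
  loads <- c(baseline_execs[[1L]]$load_pct_bw, loaded_execs[[1L]]$load_pct_bw)
  ## distinct-symbol support bounds usable N
  support <- min(vapply(conds, function(ex) {
    pooled <- do.call(rbind, lapply(ex, ascent_coords, marker = marker,
                                    reference_marker = reference_marker))
    nrow(unique(pooled))
  }, numeric(1)), M)
  train_fun <- function(execs, N, codebook = NULL) {
    train_condition_model(execs, marker, N, M, seed,
                          reference_marker = reference_marker,
                          codebook = codebook)
  }
  pooled_codebook <- function(execs) {
    pooled <- do.call(rbind, lapply(execs, ascent_coords, marker = marker,
                                    reference_marker = reference_marker))
    build_codebook(pooled, M, seed = seed)
  }
  rate_by_N <- stats::setNames(rep(NA_real_, length(N_range)),
                               as.character(N_range))
  best <- list(rate = -1, N = NA_integer_, scores = NULL)
  min_states <- NA_integer_
  for (N in N_range) {
    if (N > support) {
      warning("skipping N = ", N, ": exceeds distinct-symbol support (",
              support, ")", call. = FALSE)
      next
    }
    scores <- list()
    correct <- 0L
    total <- 0L
    cb_all <- if (shared_codebook) pooled_codebook(c(conds[[1L]], conds[[2L]]))
              else NULL
    full_models <- lapply(conds, train_fun, N = N, codebook = cb_all)
    for (ci in seq_along(conds)) {
      execs <- conds[[ci]]
      other <- full_models[[3L - ci]]
      for (ei in seq_along(execs)) {
        ## a fold's shared codebook excludes its held-out execution; the
        ## competing model keeps all its executions but shares that codebook
        oth <- other
        if (resubstitution) {
          own <- full_models[[ci]]
        } else if (shared_codebook) {
          cb_fold <- pooled_codebook(c(execs[-ei], conds[[3L - ci]]))
          own <- train_fun(execs[-ei], N, codebook = cb_fold)
          oth <- train_fun(conds[[3L - ci]], N, codebook = cb_fold)
        } else {
          own <- train_fun(execs[-ei], N)
        }
        models <- if (ci == 1L) list(own, oth) else list(oth, own)
        cl <- classify_execution(execs[[ei]], marker, models,
                                 reference_marker)
        hit <- cl$label == loads[ci]
        correct <- correct + hit
        total <- total + 1L
        scores[[length(scores) + 1L]] <- data.frame(
          condition = loads[ci], repetition = execs[[ei]]$repetition,
          loglik_baseline = cl$loglik[[1L]], loglik_loaded = cl$loglik[[2L]],
          assigned = cl$label, correct = hit, tie = cl$tie, N = N,
          stringsAsFactors = FALSE)
      }
    }
    rate <- correct / total
    rate_by_N[as.character(N)] <- rate
    if (rate > best$rate)
      best <- list(rate = rate, N = N, scores = do.call(rbind, scores))
    if (rate == 1) {
      min_states <- N
      break
    }
  }
  structure(list(subject_id = baseline_execs[[1L]]$subject_id,
                 marker_id = marker,
                 load_pair = loads,
                 anova_p = NA_real_,
                 min_states = min_states,
                 identification_rate = best$rate,
                 rate_by_N = rate_by_N[!is.na(rate_by_N)],
                 per_execution_scores = best$scores,
                 M = M, seed = seed,
                 protocol = if (resubstitution) "resubstitution"
                            else "leave-one-out"),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf("<change_report> subject %s, %s marker, %g vs %g %%BW\n",
              x$subject_id, x$marker_id, x$load_pair[1L], x$load_pair[2L]))
  if (is.finite(x$anova_p))
    cat(sprintf("  ANOVA gate p = %.4g\n", x$anova_p))
  if (!is.na(x$min_states))
    cat(sprintf("  minimum states for full recognition: N = %d (%s)\n",
                x$min_states, x$protocol))
  else
    cat(sprintf("  no N reached full recognition; best rate %.2f (%s)\n",
                x$identification_rate, x$protocol))
  invisible(x)
}

#' Run the full change-detection pipeline over a dataset
#'
#' For every subject, marker and baseline/loaded pair: (1) a per-subject
#' one-way ANOVA of the repetitions' maximum ascent displacements over the
#' two loads gates the case at level \code{alpha} — only subjects whose
#' displacement changed significantly are modelled; (2) each gated case runs
#' the minimum-states search. Deterministic given \code{seed}.
#'
#' @param dataset a \code{\link{squat_dataset}}.
#' @param markers markers to analyse (default knee and hip, the markers the
#'   displacement gate typically selects).
#' @param load_pairs list of \code{c(baseline, loaded)} load pairs.
#' @param N_range,M,seed,shared_codebook,resubstitution,reference_marker
#'   passed to \code{\link{min_states_search}}.
#' @param alpha ANOVA gate significance level.
#' @param p_adjust multiplicity correction applied to the gate p-values
#'   across subjects within each marker/pair ("none", the study convention,
#'   or any \code{stats::p.adjust} method such as "holm").
#' @return Object of class \code{"pipeline_result"}: list with
#'   \code{reports} (one \code{change_report} per subject/marker/pair, ANOVA
#'   p filled in; \code{gated} flag on each) and \code{summary} (data frame:
#'   subject, marker, pair, anova_p, gated, min_states,
#'   identification_rate).
#' @export
run_pipeline <- function(dataset, markers = c("knee", "hip"),
                         load_pairs = list(c(0, 50), c(0, 75)),
                         N_range = 2:50, M = 20L, seed = 0L,
                         alpha = 0.05, p_adjust = "none",
                         shared_codebook = TRUE, resubstitution = TRUE,
                         reference_marker = "barbell") {
  stopifnot(inherits(dataset, "squat_dataset"))
  disp <- displacement_table(dataset, reference_marker)
  keys <- dataset_keys(dataset)
  subjects <- sort(unique(keys$subject))
  reports <- list()
  for (marker in markers) {
    for (pair in load_pairs) {
      pvals <- stats::setNames(rep(NA_real_, length(subjects)), subjects)
      for (s in subjects) {
        d <- disp[disp$subject == s & disp$marker == marker &
                    disp$load_pct_bw %in% pair, ]
        pvals[s] <- tryCatch(
          oneway_anova(d$max_displacement_cm, d$load_pct_bw)$p,
          error = function(e) NA_real_)
      }
      p_adj <- stats::p.adjust(pvals, method = p_adjust)
      for (s in subjects) {
        gated <- is.finite(p_adj[s]) && p_adj[s] < alpha
        if (gated) {
          base_ex <- dataset$executions[keys$subject == s & keys$load == pair[1L]]
          load_ex <- dataset$executions[keys$subject == s & keys$load == pair[2L]]
          rep_s <- tryCatch(
            min_states_search(base_ex, load_ex, marker, N_range, M, seed,
                              shared_codebook, resubstitution,
                              reference_marker),
            error = function(e) {
              structure(list(subject_id = s, marker_id = marker,
                             load_pair = pair, anova_p = NA_real_,
                             min_states = NA_integer_,
                             identification_rate = NA_real_,
                             rate_by_N = numeric(0),
                             per_execution_scores = NULL, M = M, seed = seed,
                             protocol = "failed",
                             failure = conditionMessage(e)),
                        class = "change_report")
            })
        } else {
          rep_s <- structure(list(subject_id = s, marker_id = marker,
                                  load_pair = pair, anova_p = NA_real_,
                                  min_states = NA_integer_,
                                  identification_rate = NA_real_,
                                  rate_by_N = numeric(0),
                                  per_execution_scores = NULL, M = M,
                                  seed = seed, protocol = "not-gated"),
                             class = "change_report")
        }
        rep_s$anova_p <- unname(p_adj[s])
        rep_s$gated <- gated
        reports[[length(reports) + 1L]] <- rep_s
      }
    }
  }
  summary <- do.call(rbind, lapply(reports, function(r) {
    data.frame(subject = r$subject_id, marker = r$marker_id,
               pair = paste(r$load_pair, collapse = "-"),
               anova_p = r$anova_p, gated = r$gated,
               min_states = if (is.na(r$min_states)) NA_integer_
                            else r$min_states,
               identification_rate = r$identification_rate,
               stringsAsFactors = FALSE)
  }))
  structure(list(reports = reports, summary = summary,
                 config = list(markers = markers, load_pairs = load_pairs,
                               N_range = N_range, M = M, seed = seed,
                               alpha = alpha, p_adjust = p_adjust)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pipeline_result> %d cases (%d gated by ANOVA at alpha = %g)\n",
              nrow(s), sum(s$gated), x$config$alpha))
  invisible(x)
}

#' @export
summary.pipeline_result <- function(object, ...) {
  print(object)
  print(object$summary, digits = 4)
  invisible(object$summary)
}

#' Wide recognition summary (markers x pairs by subjects)
#'
#' Pivots a pipeline result into the study design's reporting layout: one row
#' per marker and load pair, one column per subject, each cell giving the
#' gate p-value and the minimum state count (empty when the subject was not
#' gated). \code{ipc_threshold}, when given, appends the fraction of gated
#' subjects whose minimum state count exceeds that threshold (an
#' interpretation of per-cohort "identified-percentage" reporting; flagged as
#' such in the column name).
#'
#' @param result a \code{pipeline_result}.
#' @param ipc_threshold optional integer state-count threshold.
#' @return Data frame in wide layout.
#' @export
recognition_summary <- function(result, ipc_threshold = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  s <- result$summary
  subjects <- sort(unique(s$subject))
  rows <- list()
  for (marker in unique(s$marker)) {
    for (pair in unique(s$pair)) {
      d <- s[s$marker == marker & s$pair == pair, ]
      cells <- vapply(subjects, function(sub) {
        r <- d[d$subject == sub, ]
        if (!nrow(r) || !isTRUE(r$gated)) return("")
        sprintf("p=%.3f n=%s", r$anova_p,
                ifelse(is.na(r$min_states), "-", r$min_states))
      }, character(1))
      row <- data.frame(marker = marker, pair = pair,
                        t(cells), stringsAsFactors = FALSE)
      names(row)[-(1:2)] <- subjects
      if (!is.null(ipc_threshold)) {
        g <- d[d$gated & !is.na(d$min_states), ]
        row$frac_gated_above_threshold <-
          if (nrow(g)) mean(g$min_states > ipc_threshold) else NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
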