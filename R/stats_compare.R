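## Statistical layer: normality screening, per-subject one-way ANOVA with
## Tukey HSD over loads, and human-vs-model agreement (percent agreement,
## Cohen's kappa).

#' Kolmogorov-Smirnov normality check
#'
#' Tests departure from normality with the reference normal fitted by the
#' sample mean and SD. Because the parameters are estimated, the default
#' p-value uses the Lilliefors correction; \code{method = "ks"} gives the
#' plain one-sample KS p-value against the moment-matched normal (anti-
#' conservative, provided for comparison).
#'
#' @param values numeric vector with nonzero variance; at least 3 values
#'   (the Lilliefors correction needs 5).
#' @param method \code{"lilliefors"} (default) or \code{"ks"}.
#' @return List with \code{statistic} (the KS D, in [0, 1]), \code{p} and
#'   \code{method}.
#' @export
ks_normality <- function(values, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 3L)
    stop("need at least 3 finite values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  if (method == "lilliefors" && length(values) < 5L)
    stop("the Lilliefors-corrected test needs at least 5 values", call. = FALSE)
  if (method == "lilliefors") {
    ht <- nortest::lillie.test(values)
  } else {
    ht <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  }
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       method = method)
}

#' One-way fixed-effects ANOVA with Tukey HSD post hoc
#'
#' Classical one-way ANOVA of a response over a grouping factor (here:
#' maximum ascent displacement over barbell load), followed by Tukey's
#' honestly-significant-difference comparisons over all group pairs using
#' the studentized range distribution.
#'
#' @param values numeric response vector.
#' @param groups grouping labels, same length (coerced to factor).
#' @return Object of class \code{"anova_result"}: list with \code{F},
#'   \code{p}, \code{df} (c(between, within)), \code{groups} (per-group n and
#'   mean) and \code{tukey} (data frame: pair, diff, lwr, upr, p_adj).
#' @examples
#' oneway_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
oneway_anova <- function(values, groups) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 values", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  gm <- stats::aggregate(values, list(group = groups),
                         function(v) c(n = length(v), mean = mean(v)))
  structure(list(F = tab["groups", "F value"],
                 p = tab["groups", "Pr(>F)"],
                 df = c(between = tab["groups", "Df"],
                        within = tab["Residuals", "Df"]),
                 groups = data.frame(group = gm$group, n = gm$x[, "n"],
                                     mean = gm$x[, "mean"]),
                 tukey = tukey),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df[["between"]], x$df[["within"]], x$F, x$p))
  cat("Tukey HSD:\n")
  print(x$tukey, digits = 4)
  invisible(x)
}

## validate a long rating table and extract two raters' aligned verdicts
align_raters <- function(ratings, rater_a, rater_b) {
  stopifnot(all(c("item", "rater", "verdict") %in% names(ratings)))
  if (!nrow(ratings)) stop("empty rating table", call. = FALSE)
  for (r in c(rater_a, rater_b))
    if (!r %in% ratings$rater) stop("rater '", r, "' absent", call. = FALSE)
  a <- ratings[ratings$rater == rater_a, ]
  b <- ratings[ratings$rater == rater_b, ]
  items <- sort(unique(ratings$item))
  if (!all(items %in% a$item) || !all(items %in% b$item))
    stop("all raters must rate all items", call. = FALSE)
  list(a = a$verdict[match(items, a$item)],
       b = b$verdict[match(items, b$item)], items = items)
}

#' Percent agreement between two raters
#'
#' @param ratings long-format data frame with columns \code{item},
#'   \code{rater}, \code{verdict}; every rater must rate every item.
#' @param rater_a,rater_b rater names.
#' @return Percentage (0-100) of items with identical verdicts.
#' @export
percent_agreement <- function(ratings, rater_a, rater_b) {
  al <- align_raters(ratings, rater_a, rater_b)
  100 * mean(al$a == al$b)
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)}, with
#' expected agreement \eqn{p_e} from the product of marginal proportions.
#' The p-value tests \eqn{H_0: \kappa = 0} with the large-sample normal
#' approximation \eqn{z = \kappa / SE_0} (Fleiss), or by exact permutation of
#' one rater's labels when \code{method = "permutation"} (all permutations
#' enumerated Monte-Carlo style with \code{n_perm} draws).
#'
#' @inheritParams percent_agreement
#' @param method \code{"normal"} (default) or \code{"permutation"}.
#' @param n_perm permutation count for \code{method = "permutation"}.
#' @param seed seed for the permutation draw.
#' @return List with \code{kappa}, \code{p}, \code{p_o}, \code{p_e} and
#'   \code{undefined} (TRUE, with \code{kappa = NaN}, when both raters give a
#'   single identical category so \eqn{p_e = 1}).
#' @export
cohens_kappa <- function(ratings, rater_a, rater_b,
                         method = c("normal", "permutation"),
                         n_perm = 10000L, seed = 0L) {
  method <- match.arg(method)
  al <- align_raters(ratings, rater_a, rater_b)
  if (length(al$items) < 2L) stop("need at least 2 items", call. = FALSE)
  kap <- kappa_from_verdicts(al$a, al$b)
  if (kap$undefined)
    return(list(kappa = NaN, p = NA_real_, p_o = kap$p_o, p_e = kap$p_e,
                undefined = TRUE))
  if (method == "normal") {
    p <- kap$p_normal
  } else {
    obs <- kap$kappa
    p <- with_seed(seed, {
      ge <- vapply(seq_len(n_perm), function(dummy) {
        k <- kappa_from_verdicts(al$a, sample(al$b))$kappa
        isTRUE(abs(k) >= abs(obs) - 1e-12)
      }, logical(1))
      (sum(ge) + 1) / (n_perm + 1)
    })
  }
  list(kappa = kap$kappa, p = p, p_o = kap$p_o, p_e = kap$p_e,
       undefined = FALSE)
}

kappa_from_verdicts <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  a <- factor(a, levels = lev); b <- factor(b, levels = lev)
  n <- length(a)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  pa <- rowSums(tab); pb <- colSums(tab)
  p_e <- sum(pa * pb)
  if (p_e >= 1 - 1e-12 && p_o >= 1 - 1e-12)
    return(list(kappa = NaN, p_o = p_o, p_e = p_e, undefined = TRUE,
                p_normal = NA_real_))
  kappa <- if (p_o >= 1 - 1e-12) 1 else (p_o - p_e) / (1 - p_e)
  ## Fleiss large-sample SE of kappa under H0: kappa = 0
  se0 <- sqrt((p_e + p_e^2 - sum(pa * pb * (pa + pb))) / (n * (1 - p_e)^2))
  z <- kappa / se0
  p_normal <- 2 * stats::pnorm(-abs(z))
  list(kappa = kappa, p_o = p_o, p_e = p_e, undefined = FALSE,
       p_normal = p_normal)
}

#' Binarize model change-detection outcomes into rater verdicts
#'
#' Maps each subject/marker/load-pair ANOVA outcome of a pipeline run to a
#' verdict ("changed" when the gate p-value is below \code{alpha}, else
#' "unchanged"), yielding a rating table row set for the rater named
#' \code{rater}. Human evaluators' verdicts on the same items can then be
#' bound to the same table for \code{\link{percent_agreement}} and
#' \code{\link{cohens_kappa}}.
#'
#' @param reports list of change reports from \code{\link{run_pipeline}}.
#' @param alpha significance level (default 0.05).
#' @param rater rater name for the model (default "model").
#' @return Long-format rating data frame (item, rater, verdict).
#' @export
model_verdicts <- function(reports, alpha = 0.05, rater = "model") {
  rows <- lapply(reports, function(r) {
    data.frame(item = paste(r$subject_id, r$marker_id,
                            paste(r$load_pair, collapse = "-"), sep = "|"),
               rater = rater,
               verdict = if (is.finite(r$anova_p) && r$anova_p < alpha)
                 "changed" else "unchanged",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
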