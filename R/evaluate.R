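#' Mann-Whitney AUC
#'
#' Probability that a random case scores above a random control, with ties
#' counted half - the exact area under the empirical ROC curve.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Labels, `"case"`/`"control"` or 0/1.
#' @return AUC in \[0, 1\].
#' @export
mw_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels != 0))
  as.integer(as.character(labels) == "case")
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/n, each
#' with an exact Clopper-Pearson 95% confidence interval.
#'
#' @param tp,fn,tn,fp Non-negative integer cell counts.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return List of class `confusion_metrics` with the counts and, per
#'   metric, the point estimate and CI (all as proportions).
#' @export
confusion_metrics <- function(tp, fn, tn, fp, conf_level = 0.95) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  est <- function(x, n) {
    ci <- clopper_pearson(x, n, conf_level)
    list(estimate = if (n > 0) x / n else NA_real_,
         lower = ci[1], upper = ci[2])
  }
  structure(list(counts = counts,
                 sensitivity = est(tp, tp + fn),
                 specificity = est(tn, tn + fp),
                 accuracy = est(tp + tn, sum(counts)),
                 conf_level = conf_level),
            class = "confusion_metrics")
}

# Exact binomial (Clopper-Pearson) interval via the beta quantile form.
clopper_pearson <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  a <- (1 - conf_level) / 2
  lower <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower, upper)
}

#' Evaluate classifier scores at the Youden-optimal operating point
#'
#' Sweeps every distinct score as a classification threshold (predict case
#' when `score >= threshold`), computes the full ROC curve, the
#' Mann-Whitney AUC, and selects the threshold maximising Youden's
#' J = sensitivity + specificity - 1; ties go to the lowest qualifying
#' threshold (favouring sensitivity, the natural choice for a screening
#' aid). The confusion matrix and Clopper-Pearson intervals are reported at
#' that threshold.
#'
#' @param scores Numeric scores, higher = more case-like; must be finite.
#' @param labels `"case"`/`"control"` or 0/1 labels; both classes required.
#' @param conf_level Confidence level for the intervals.
#'
#' @return List of class `model_report`: `roc` (threshold, sensitivity,
#'   specificity), `auc`, `youden_threshold`, `j`, `confusion` (a
#'   [confusion_metrics()]), and `n`.
#' @export
evaluate_scores <- function(scores, labels, conf_level = 0.95) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")

  thr <- sort(unique(scores))
  # predicted positive iff score >= t; sweep from the lowest score
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & y == 0) / n0, numeric(1))
  roc <- data.frame(threshold = c(thr, Inf),
                    sensitivity = c(sens, 0), specificity = c(spec, 1))

  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  best <- best[which.min(roc$threshold[best])]
  t_star <- roc$threshold[best]
  cm <- confusion_metrics(tp = sum(scores >= t_star & y == 1),
                          fn = sum(scores < t_star & y == 1),
                          tn = sum(scores < t_star & y == 0),
                          fp = sum(scores >= t_star & y == 0),
                          conf_level = conf_level)
  structure(list(roc = roc, auc = mw_auc(scores, y),
                 youden_threshold = t_star, j = max(j), confusion = cm,
                 n = length(y), n_cases = n1),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  pct <- function(e) sprintf("%.1f%% (95%% CI %.1f-%.1f%%)",
                             100 * e$estimate, 100 * e$lower, 100 * e$upper)
  cat("Holdout evaluation (n =", x$n, ",", x$n_cases, "cases)\n")
  cat(sprintf("  AUC %.3f; Youden J %.3f at threshold %.4g\n",
              x$auc, x$j, x$youden_threshold))
  cat("  sensitivity", pct(x$confusion$sensitivity), "\n")
  cat("  specificity", pct(x$confusion$specificity), "\n")
  cat("  accuracy   ", pct(x$confusion$accuracy), "\n")
  invisible(x)
}

# DeLong structural components: per-case and per-control placements.
delong_components <- function(scores, y) {
  cases <- scores[y == 1]
  ctrls <- scores[y == 0]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(cases, function(s) mean(psi(s, ctrls)), numeric(1))
  v01 <- vapply(ctrls, function(s) mean(psi(cases, s)), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' Stratified AUC with a DeLong-type comparison against the overall ROC
#'
#' For each stratum containing both classes, computes the stratum AUC and a
#' two-sided p-value for its difference from the overall AUC. The variance
#' of the difference uses DeLong structural components; because the stratum
#' subjects also enter the overall AUC, the covariance between the two
#' estimates is estimated from the shared subjects' placement values.
#' Strata missing a class are flagged (`NA` AUC) rather than computed.
#'
#' @param scores Numeric scores.
#' @param labels `"case"`/`"control"` or 0/1 labels.
#' @param strata Factor of stratum membership (e.g. sex or age bands).
#'
#' @return `data.frame`: stratum, n, n_cases, auc, p_vs_overall, flag.
#' @export
stratified_performance <- function(scores, labels, strata) {
  y <- as_binary_labels(labels)
  strata <- as.factor(strata)
  overall <- delong_components(scores, y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  var_o <- var(overall$v10) / n1 + var(overall$v01) / n0

  rows <- lapply(levels(strata), function(s) {
    in_s <- strata == s
    ys <- y[in_s]
    base <- data.frame(stratum = s, n = sum(in_s), n_cases = sum(ys == 1),
                       auc = NA_real_, p_vs_overall = NA_real_,
                       flag = NA_character_, stringsAsFactors = FALSE)
    if (length(unique(ys)) < 2) {
      base$flag <- "single_class"
      return(base)
    }
    str <- delong_components(scores[in_s], ys)
    base$auc <- str$auc
    diff <- str$auc - overall$auc
    if (abs(diff) < 1e-12) {
      base$p_vs_overall <- 1
      return(base)
    }
    m1 <- sum(ys == 1)
    m0 <- sum(ys == 0)
    var_s <- var(str$v10) / m1 + var(str$v01) / m0
    # overall placements restricted to the stratum's subjects
    o10 <- overall$v10[in_s[y == 1]]
    o01 <- overall$v01[in_s[y == 0]]
    cov_cases <- if (m1 > 1) cov(str$v10, o10) / n1 else 0
    cov_ctrls <- if (m0 > 1) cov(str$v01, o01) / n0 else 0
    var_diff <- var_s + var_o - 2 * (cov_cases + cov_ctrls)
    if (!is.finite(var_diff) || var_diff <= 0) {
      base$p_vs_overall <- 1
    } else {
      base$p_vs_overall <- 2 * pnorm(-abs(diff) / sqrt(var_diff))
    }
    base
  })
  do.call(rbind, rows)
}

#' Fingerprint a data set for leakage auditing
#'
#' MD5 of the serialised object; recorded when a holdout set is created and
#' checked again at evaluation time to assert the rows were never modified.
#'
#' @param x Any R object.
#' @return Character MD5 digest.
#' @export
data_fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
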