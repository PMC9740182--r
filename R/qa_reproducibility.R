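#' Replicate-agreement report for duplicate strands
#'
#' Compares the feature vectors of two strands from the same subject by the
#' symmetric percent difference `100 * |f1 - f2| / mean(|f1|, |f2|)` and
#' summarises the fraction of features agreeing within +/-10%, the QA bar
#' for duplicate hair measurements. Features where both values are
#' essentially zero (mean absolute value below `zero_tol`) have no defined
#' percent difference and are excluded from the denominator but listed.
#'
#' @param features_a,features_b Named numeric vectors (or one-row data
#'   frames) with identical feature names.
#' @param within_pct Agreement band in percent (default 10).
#' @param zero_tol Absolute tolerance below which both values count as zero.
#'
#' @return List of class `agreement_report`: `percent_diff` (named vector),
#'   `fraction_within`, `within_pct`, `worst` (most discordant features) and
#'   `zero_features`.
#' @export
replicate_agreement <- function(features_a, features_b, within_pct = 10,
                                zero_tol = 1e-9) {
  a <- unlist(features_a)
  b <- unlist(features_b)
  if (!identical(names(a), names(b)))
    stop("feature columns differ between the two replicates")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  denom <- (abs(a) + abs(b)) / 2
  zero <- denom < zero_tol
  pd <- 100 * abs(a - b)[!zero] / denom[!zero]
  worst <- sort(pd, decreasing = TRUE)
  structure(list(percent_diff = pd,
                 fraction_within = if (length(pd)) mean(pd <= within_pct)
                 else NA_real_,
                 within_pct = within_pct,
                 worst = head(worst, 10L),
                 zero_features = names(denom)[zero]),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Replicate agreement: %.1f%% of %d features within +/-%g%%\n",
    100 * x$fraction_within, length(x$percent_diff), x$within_pct))
  if (length(x$zero_features))
    cat("  excluded near-zero features:", length(x$zero_features), "\n")
  invisible(x)
}
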