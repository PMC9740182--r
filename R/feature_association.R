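#' Within-batch centring/scaling followed by global z-scoring
#'
#' Each feature is centred and scaled to unit variance within each batch
#' (removing multiplicative instrument drift that survives ratio
#' normalisation), then re-standardised globally. Features constant within
#' any batch cannot be scaled there and are set wholly missing with a
#' warning. A single batch reduces to plain z-scoring.
#'
#' @param table Subjects-by-features `data.frame` (e.g. [feature_table()]).
#' @param batch Batch label per subject (same order as rows).
#'
#' @return The corrected table; `provenance` attribute is preserved.
#' @export
batch_correct_and_zscore <- function(table, batch) {
  if (length(batch) != nrow(table))
    stop("batch labels must match table rows")
  batch <- as.factor(batch)
  small <- names(which(base::table(batch) < 3))
  if (length(small))
    stop("batch(es) with fewer than 3 subjects: ",
         paste(small, collapse = ", "))
  out <- table
  bad <- character(0)
  for (j in seq_along(out)) {
    x <- out[[j]]
    for (b in levels(batch)) {
      idx <- which(batch == b & !is.na(x))
      if (length(idx) == 0) next
      s <- sd(x[idx])
      if (!is.finite(s) || s == 0) {
        bad <- c(bad, colnames(out)[j])
        x[] <- NA_real_
        break
      }
      x[idx] <- (x[idx] - mean(x[idx])) / s
    }
    if (!all(is.na(x))) {
      gs <- sd(x, na.rm = TRUE)
      if (is.finite(gs) && gs > 0)
        x <- (x - mean(x, na.rm = TRUE)) / gs
    }
    out[[j]] <- x
  }
  if (length(bad))
    warning("feature(s) constant within a batch set to missing: ",
            paste(unique(bad), collapse = ", "), call. = FALSE)
  attr(out, "provenance") <- attr(table, "provenance")
  out
}

#' Feature-wide association scan
#'
#' Fits, per feature, a logistic regression of diagnosis on the feature
#' adjusted for sex and age (`diagnosis ~ feature + sex + age_months`) and
#' reports the Wald statistics of the feature coefficient, with
#' Benjamini-Hochberg FDR adjustment across all cleanly fitted features.
#' Features showing separation (non-finite or exploding standard errors) are
#' flagged and excluded from the FDR denominator.
#'
#' @param table Normalised subjects-by-features table (rownames = subject
#'   ids).
#' @param subjects Subject metadata `data.frame` with `subject_id`,
#'   `diagnosis` (`"case"`/`"control"`), `sex`, `age_months`.
#' @param fdr_alpha Significance threshold on the FDR-adjusted q-value.
#'
#' @return `data.frame` with one row per feature: `feature_id`, `pathway`,
#'   `metric`, `beta`, `se`, `p`, `q`, `significant`, `direction`, `flag`.
#' @export
associate <- function(table, subjects, fdr_alpha = 0.05) {
  idx <- match(rownames(table), subjects$subject_id)
  if (anyNA(idx))
    stop("subjects table lacks metadata for: ",
         paste(rownames(table)[is.na(idx)], collapse = ", "))
  meta <- subjects[idx, ]
  y <- as.integer(meta$diagnosis == "case")
  if (length(unique(y)) < 2) stop("diagnosis must contain both classes")
  sex <- factor(meta$sex)
  age <- meta$age_months

  prov <- attr(table, "provenance")
  n_feat <- ncol(table)
  beta <- se <- p <- rep(NA_real_, n_feat)
  flag <- rep(NA_character_, n_feat)
  for (j in seq_len(n_feat)) {
    x <- table[[j]]
    ok <- !is.na(x)
    if (sum(ok) < 8 || length(unique(y[ok])) < 2 || sd(x[ok]) == 0) {
      flag[j] <- "unusable"
      next
    }
    fit <- suppressWarnings(
      glm(y[ok] ~ x[ok] + sex[ok] + age[ok], family = binomial()))
    cf <- summary(fit)$coefficients
    if (!"x[ok]" %in% rownames(cf)) {
      flag[j] <- "dropped"
      next
    }
    b <- cf["x[ok]", 1]
    s <- cf["x[ok]", 2]
    if (!is.finite(b) || !is.finite(s) || s > 50 || !fit$converged) {
      flag[j] <- "separation"
      next
    }
    beta[j] <- b
    se[j] <- s
    p[j] <- cf["x[ok]", 4]
  }
  q <- rep(NA_real_, n_feat)
  tested <- is.na(flag)
  q[tested] <- p.adjust(p[tested], method = "BH")
  out <- data.frame(
    feature_id = colnames(table),
    pathway = if (!is.null(prov))
      prov$pathway[match(colnames(table), prov$feature_id)] else NA,
    metric = if (!is.null(prov))
      prov$metric[match(colnames(table), prov$feature_id)] else NA,
    beta = beta, se = se, p = p, q = q,
    significant = !is.na(q) & q < fdr_alpha,
    direction = sign(beta), flag = flag, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-pathway association summary (forest-plot style)
#'
#' Aggregates an association scan by elemental pathway: number of
#' FDR-significant features, the split of their effect signs, and the
#' smallest q-value, plus the plot-ready long table of standardised effects.
#'
#' @param rows Output of [associate()].
#'
#' @return List with `summary` (per-pathway data.frame, sorted by `n_sig`)
#'   and `effects` (long table of per-feature estimates).
#' @export
forest_summary <- function(rows) {
  sp <- split(rows, rows$pathway)
  summ <- do.call(rbind, lapply(sp, function(d) {
    sig <- d[which(d$significant), , drop = FALSE]
    data.frame(pathway = d$pathway[1], n_features = nrow(d),
               n_sig = nrow(sig),
               n_sig_pos = sum(sig$direction > 0, na.rm = TRUE),
               n_sig_neg = sum(sig$direction < 0, na.rm = TRUE),
               min_q = if (all(is.na(d$q))) NA_real_ else
                 min(d$q, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(-summ$n_sig, summ$min_q), ]
  rownames(summ) <- NULL
  effects <- rows[!is.na(rows$beta),
                  c("feature_id", "pathway", "metric", "beta", "se", "q",
                    "significant")]
  list(summary = summ, effects = effects)
}
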