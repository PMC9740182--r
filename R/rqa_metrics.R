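#' Quantify a (cross-)recurrence matrix
#'
#' Computes the canonical twelve-feature recurrence quantification set from
#' exhaustive diagonal and vertical line-length histograms:
#' recurrence rate (`rr`), determinism (`det`), mean diagonal line length
#' (`mean_l`), longest diagonal (`l_max`), divergence (`div = 1/l_max`),
#' diagonal line-length entropy (`entr`, nats), laminarity (`lam`), trapping
#' time (`tt`), longest vertical (`v_max`), vertical line-length entropy
#' (`v_entr`), `ratio_det_rr` and `trend` (slope of recurrence density
#' against diagonal displacement). Together these describe the prevalence,
#' duration, timing and complexity of stable and periodic states.
#'
#' Degenerate matrices yield the defined degenerate values (all-zero
#' histogram: det = 0, mean_l = 0, l_max = 0, div = 0, entr = 0, and the
#' vertical analogues), never errors.
#'
#' @param x A `recurrence_result` or a plain binary matrix (then assumed to
#'   have no Theiler exclusion).
#' @param lmin Minimal diagonal line length counted as deterministic
#'   (default 2).
#' @param vmin Minimal vertical line length counted as laminar (default 2).
#' @param min_diag_cells Diagonals with fewer cells are excluded from the
#'   trend regression (default 10, stabilising the slope).
#'
#' @return Named numeric vector with the 12 features.
#' @export
rqa_quantify <- function(x, lmin = 2L, vmin = 2L, min_diag_cells = 10L) {
  if (inherits(x, "recurrence_result")) {
    m <- x$matrix
    theiler <- x$theiler_window
  } else {
    m <- as.matrix(x)
    if (!all(m %in% c(0, 1))) stop("matrix must be binary")
    storage.mode(m) <- "integer"
    theiler <- 0L
  }
  h <- line_histograms_cpp(m)
  n_rec <- sum(h$diag_lengths)  # every recurrent point sits on one diag run
  n_elig <- if (inherits(x, "recurrence_result")) x$n_eligible else
    length(m)
  rr <- if (n_elig > 0) n_rec / n_elig else 0

  dl <- h$diag_lengths
  dsel <- dl[dl >= lmin]
  det <- if (n_rec > 0) sum(dsel) / n_rec else 0
  mean_l <- if (length(dsel)) mean(dsel) else 0
  l_max <- if (length(dl)) max(dl) else 0L
  div <- if (l_max >= 1) 1 / l_max else 0
  entr <- line_entropy(dsel)

  vl <- h$vert_lengths
  vsel <- vl[vl >= vmin]
  n_vrec <- sum(vl)
  lam <- if (n_vrec > 0) sum(vsel) / n_vrec else 0
  tt <- if (length(vsel)) mean(vsel) else 0
  v_max <- if (length(vl)) max(vl) else 0L
  v_entr <- line_entropy(vsel)

  # trend: slope of per-displacement recurrence density against |offset|,
  # over diagonals long enough to estimate a density
  keep <- h$offset_cells >= min_diag_cells & abs(h$offset) >= theiler
  trend <- 0
  if (sum(keep) >= 2) {
    disp <- abs(h$offset[keep])
    dens <- h$offset_count[keep] / h$offset_cells[keep]
    vv <- stats::var(disp)
    if (is.finite(vv) && vv > 0)
      trend <- stats::cov(disp, dens) / vv
  }

  c(rr = rr, det = det, mean_l = mean_l, l_max = as.numeric(l_max),
    div = div, entr = entr, lam = lam, tt = tt,
    v_max = as.numeric(v_max), v_entr = v_entr,
    ratio_det_rr = if (rr > 0) det / rr else 0, trend = trend)
}

# Shannon entropy (nats) of the length distribution of a set of lines.
line_entropy <- function(lengths) {
  if (!length(lengths)) return(0)
  p <- tabulate(lengths)
  p <- p[p > 0] / length(lengths)
  -sum(p * log(p))
}

#' RQA pipeline parameters
#'
#' Bundle of embedding-selection and recurrence settings used by
#' [feature_table()]: the recurrence rate is fixed at 10% per matrix, the
#' Theiler window removes only the line of identity in auto-recurrence,
#' delays come from the first AMI minimum and dimensions from the Kennel
#' false-nearest-neighbour criterion.
#'
#' @param target_rr Recurrence rate every matrix is calibrated to.
#' @param lmin,vmin Minimal diagonal/vertical line lengths.
#' @param theiler_window Excluded band half-width for auto-recurrence.
#' @param max_tau Largest delay scanned by [select_delay()] (`NULL` =
#'   automatic).
#' @param max_m,rtol,atol,fnn_threshold [select_dimension()] settings.
#'
#' @return List of class `rqa_params`.
#' @export
rqa_params <- function(target_rr = 0.10, lmin = 2L, vmin = 2L,
                       theiler_window = 1L, max_tau = NULL, max_m = 10L,
                       rtol = 10, atol = 2, fnn_threshold = 0.05) {
  structure(list(target_rr = target_rr, lmin = as.integer(lmin),
                 vmin = as.integer(vmin),
                 theiler_window = as.integer(theiler_window),
                 max_tau = max_tau, max_m = as.integer(max_m), rtol = rtol,
                 atol = atol, fnn_threshold = fnn_threshold),
            class = "rqa_params")
}

rqa_metric_names <- function() {
  c("rr", "det", "mean_l", "l_max", "div", "entr", "lam", "tt",
    "v_max", "v_entr", "ratio_det_rr", "trend")
}

#' Subjects-by-features table of RQA/CRQA metrics
#'
#' For every subject, each element's sulfur-ratio series is delay-embedded
#' with its own estimated parameters and quantified (12 recurrence features);
#' every unordered element pair is additionally cross-embedded (each series
#' keeps its own delay, the shared dimension is the maximum of the two) and
#' quantified from the cross-recurrence matrix. A 15-element panel thus
#' yields 15 + 105 = 120 matrices and 1,440 features per subject.
#'
#' Features of a series whose embedding fails (e.g. constant ratios) are
#' recorded as `NA` with the reason in the embedding log; subjects with more
#' than `max_failed_fraction` failed features are excluded with a warning.
#'
#' @param profiles List of [strand_profile()] objects.
#' @param panel Elements to analyse (default: all channels of the first
#'   profile).
#' @param params An [rqa_params()] bundle.
#' @param max_failed_fraction Subject exclusion threshold (default 0.2).
#' @param embedding Optional precomputed embedding log (`data.frame` with
#'   `subject_id`, `element`, `tau`, `m`) reused instead of re-estimating,
#'   e.g. to quantify a replicate strand with the parameters calibrated on
#'   the subject's primary strand.
#'
#' @return `data.frame` (rownames = subject ids, one column per feature,
#'   named `<pathway>_<metric>` with pathway `Zn` or `Zn.Cu`) with
#'   attributes `provenance` (feature_id, pathway, metric) and
#'   `embedding_log` (subject_id, element, tau, m, flag).
#' @export
feature_table <- function(profiles, panel = NULL, params = rqa_params(),
                          max_failed_fraction = 0.2, embedding = NULL) {
  if (is.null(panel)) panel <- colnames(profiles[[1]]$channels)
  pairs <- if (length(panel) > 1) combn(panel, 2) else
    matrix(character(0), 2, 0)
  pathways <- c(panel, apply(pairs, 2, paste, collapse = "."))
  metrics <- rqa_metric_names()
  feat_ids <- as.vector(t(outer(pathways, metrics, paste, sep = "_")))
  provenance <- data.frame(
    feature_id = feat_ids,
    pathway = rep(pathways, each = length(metrics)),
    metric = rep(metrics, length(pathways)), stringsAsFactors = FALSE)

  rows <- vector("list", length(profiles))
  logs <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    res <- subject_features(profiles[[i]], panel, pairs, params, embedding)
    rows[[i]] <- res$features[feat_ids]
    logs[[i]] <- res$log
  }
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- vapply(profiles, `[[`, "", "subject_id")
  colnames(tab) <- feat_ids

  failed <- rowMeans(is.na(tab))
  if (any(failed > max_failed_fraction)) {
    warning("excluding subject(s) with > ", 100 * max_failed_fraction,
            "% failed features: ",
            paste(rownames(tab)[failed > max_failed_fraction],
                  collapse = ", "), call. = FALSE)
    keep <- failed <= max_failed_fraction
    tab <- tab[keep, , drop = FALSE]
  }
  attr(tab, "provenance") <- provenance
  attr(tab, "embedding_log") <- do.call(rbind, logs)
  tab
}

# Features and embedding log for one subject.
subject_features <- function(profile, panel, pairs, params,
                             embedding = NULL) {
  missing_el <- setdiff(panel, colnames(profile$channels))
  if (length(missing_el))
    stop("subject ", profile$subject_id, " lacks channels: ",
         paste(missing_el, collapse = ", "))
  ratios <- ratio_matrix(profile)
  metrics <- rqa_metric_names()

  emb <- setNames(vector("list", length(panel)), panel)
  states <- setNames(vector("list", length(panel)), panel)
  log <- data.frame(subject_id = profile$subject_id, element = panel,
                    tau = NA_integer_, m = NA_integer_,
                    flag = NA_character_, stringsAsFactors = FALSE)
  for (e in seq_along(panel)) {
    el <- panel[e]
    fixed <- NULL
    if (!is.null(embedding)) {
      hit <- embedding$subject_id == profile$subject_id &
        embedding$element == el
      if (any(hit) && !is.na(embedding$tau[hit][1]))
        fixed <- embedding_params(embedding$tau[hit][1],
                                  embedding$m[hit][1],
                                  params$theiler_window)
    }
    p <- if (!is.null(fixed)) {
      fixed$flag <- NA_character_
      fixed
    } else tryCatch(
      estimate_embedding(ratios[, el], max_tau = params$max_tau,
                         max_m = params$max_m, rtol = params$rtol,
                         atol = params$atol,
                         fnn_threshold = params$fnn_threshold,
                         theiler_window = params$theiler_window),
      error = function(err) conditionMessage(err))
    if (is.character(p)) {
      log$flag[e] <- p
    } else {
      emb[[el]] <- p
      states[[el]] <- embed_series(ratios[, el], p)
      log$tau[e] <- p$tau
      log$m[e] <- p$m
      if (!is.na(p$flag)) log$flag[e] <- p$flag
    }
  }

  feats <- list()
  for (el in panel) {
    v <- if (is.null(emb[[el]])) rep(NA_real_, length(metrics)) else
      tryCatch(rqa_quantify(
        recurrence_matrix(states[[el]], params$target_rr,
                          params$theiler_window, emb[[el]]),
        lmin = params$lmin, vmin = params$vmin),
        error = function(err) rep(NA_real_, length(metrics)))
    feats[paste(el, metrics, sep = "_")] <- v
  }
  if (ncol(pairs) > 0) {
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]
      b <- pairs[2, k]
      pw <- paste(a, b, sep = ".")
      if (is.null(emb[[a]]) || is.null(emb[[b]])) {
        v <- rep(NA_real_, length(metrics))
      } else {
        m_shared <- max(emb[[a]]$m, emb[[b]]$m)
        pa <- embedding_params(emb[[a]]$tau, m_shared, 0L)
        pb <- embedding_params(emb[[b]]$tau, m_shared, 0L)
        v <- tryCatch(rqa_quantify(
          cross_recurrence_matrix(embed_series(ratios[, a], pa),
                                  embed_series(ratios[, b], pb),
                                  params$target_rr, pa, pb),
          lmin = params$lmin, vmin = params$vmin),
          error = function(err) rep(NA_real_, length(metrics)))
      }
      feats[paste(pw, metrics, sep = "_")] <- v
    }
  }
  list(features = unlist(feats), log = log)
}
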