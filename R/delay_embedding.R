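#' Average mutual information between a series and its lagged copy
#'
#' Equal-width 2-D histogram estimator: bin edges are taken from the full
#' series range with `bins` bins per axis (default `ceiling(n^(1/3))`, at
#' least 4), and the mutual information of the joint bin distribution of
#' `(x[t], x[t + lag])` is returned in nats.
#'
#' @param x Numeric series.
#' @param lag Positive integer lag.
#' @param bins Number of histogram bins per axis.
#'
#' @return Mutual information (nats).
#' @export
ami <- function(x, lag, bins = NULL) {
  n <- length(x)
  if (lag < 1 || lag >= n) stop("lag must lie in [1, length(x) - 1]")
  rng <- range(x)
  if (diff(rng) <= 0) stop("constant series: mutual information undefined")
  if (is.null(bins)) bins <- max(4L, ceiling(n^(1 / 3)))
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  ix <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  a <- ix[seq_len(n - lag)]
  b <- ix[(lag + 1):n]
  joint <- tabulate(a + bins * (b - 1L), nbins = bins * bins) / (n - lag)
  pj <- matrix(joint, bins, bins)
  px <- rowSums(pj)
  py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
}

#' Select the embedding delay by mutual-information minimisation
#'
#' Scans AMI over lags `1..max_tau` and returns the first *prominent* local
#' minimum: a lag whose AMI is below its neighbours and after which the curve
#' rises by at least three times the curve's median successive wiggle before
#' it ever drops lower. The prominence requirement makes the rule robust to
#' the small parity oscillations the histogram estimator shows on strongly
#' periodic series; a prominent minimum must also be a running minimum and
#' must lie at least the same margin below the lag-1 AMI, so the chance dips
#' of a structureless (e.g. white-noise) scan never qualify.
#' If no prominent minimum exists the first plain local
#' minimum is returned, and if the curve never rises at all, the argmin
#' (a global minimum attained at the end of the scan range is usually
#' spurious, hence the preference for early minima).
#'
#' @param x Numeric series; must be non-constant and of length >= 4 * max_tau.
#' @param max_tau Largest lag scanned (default `min(60, floor(n/4))`).
#' @param bins Histogram bins, passed to [ami()].
#'
#' @return Integer delay with attribute `ami` (the scanned AMI curve).
#' @export
select_delay <- function(x, max_tau = NULL, bins = NULL) {
  n <- length(x)
  if (is.null(max_tau)) max_tau <- max(1L, min(60L, floor(n / 4)))
  if (n < 4 * max_tau)
    stop("series too short for max_tau = ", max_tau,
         " (need length >= ", 4 * max_tau, ")")
  if (diff(range(x)) <= 0) stop("constant series: delay undefined")
  curve <- vapply(seq_len(max_tau), function(l) ami(x, l, bins), numeric(1))
  structure(first_ami_minimum(curve), ami = curve)
}

# First prominent local minimum of an AMI curve (see select_delay).
first_ami_minimum <- function(curve) {
  k <- length(curve)
  if (k == 1L) return(1L)
  is_min <- logical(k)
  is_min[1] <- curve[1] < curve[2]
  if (k > 2)
    for (t in 2:(k - 1))
      is_min[t] <- curve[t] < curve[t - 1] && curve[t] <= curve[t + 1]
  wiggle <- stats::median(abs(diff(curve)))
  need <- 3 * wiggle
  prominent <- function(t) {
    if (t == k) return(FALSE)
    rest <- curve[(t + 1):k]
    below <- which(rest < curve[t])
    upto <- if (length(below)) rest[seq_len(below[1] - 1)] else rest
    length(upto) > 0 && max(upto) - curve[t] >= need
  }
  deep <- curve <= curve[1] - need  # pronounced structure below lag-1 AMI
  cand <- which(is_min & deep & curve <= cummin(curve))
  for (t in cand) if (prominent(t)) return(as.integer(t))
  cand <- which(is_min)
  if (length(cand)) return(as.integer(cand[1]))
  as.integer(which.min(curve))
}

#' Select the embedding dimension by false nearest neighbours
#'
#' Kennel criterion: for each dimension `m`, each point's nearest neighbour in
#' the m-dimensional embedding is tested with the distance-ratio threshold
#' `rtol` and the attractor-size threshold `atol` (relative to the series sd).
#' The smallest `m` whose false-neighbour fraction falls to or below
#' `fnn_threshold` is returned; if the threshold is never reached within the
#' dimensions the series length supports, `max_m` is returned with attribute
#' `flag = "fnn_not_converged"`.
#'
#' @param x Numeric series.
#' @param tau Embedding delay.
#' @param max_m Largest dimension considered.
#' @param rtol,atol Kennel thresholds (canonical defaults 10 and 2).
#' @param fnn_threshold Acceptance fraction (default 0.05).
#'
#' @return Integer dimension with attributes `fnn` (fractions by m) and
#'   `flag` (`NA` or `"fnn_not_converged"`).
#' @export
select_dimension <- function(x, tau, max_m = 10L, rtol = 10, atol = 2,
                             fnn_threshold = 0.05) {
  n <- length(x)
  if (tau < 1) stop("tau must be a positive integer")
  if (n - tau < 10)
    stop("series too short for FNN at tau = ", tau)
  fr <- fnn_fractions_cpp(as.numeric(x), as.integer(tau), as.integer(max_m),
                          rtol, atol, fnn_threshold)
  ok <- which(!is.na(fr) & fr <= fnn_threshold)
  if (length(ok)) {
    structure(as.integer(ok[1]), fnn = fr, flag = NA_character_)
  } else {
    structure(as.integer(max_m), fnn = fr, flag = "fnn_not_converged")
  }
}

#' Embedding parameter bundle
#'
#' @param tau Delay (samples), >= 1.
#' @param m Embedding dimension, >= 1.
#' @param theiler_window Half-width of the excluded band around the line of
#'   identity: pairs with `|i - j| < theiler_window` are ignored; 1 removes
#'   only the line of identity, 0 removes nothing.
#'
#' @return List of class `embedding_params`.
#' @export
embedding_params <- function(tau, m, theiler_window = 1L) {
  if (tau < 1 || m < 1 || theiler_window < 0)
    stop("invalid embedding parameters")
  structure(list(tau = as.integer(tau), m = as.integer(m),
                 theiler_window = as.integer(theiler_window)),
            class = "embedding_params")
}

#' Delay-embed a series
#'
#' Row `i` of the result is `(x[i], x[i + tau], ..., x[i + (m-1) tau])`; the
#' embedded length is `n - (m - 1) * tau`.
#'
#' @param x Numeric series.
#' @param params An [embedding_params()] (or a list with `tau` and `m`).
#'
#' @return Numeric matrix of embedded state vectors.
#' @export
embed_series <- function(x, params) {
  tau <- params$tau
  m <- params$m
  n <- length(x)
  n_emb <- n - (m - 1L) * tau
  if (n_emb < 1) stop("series too short to embed: n = ", n,
                      ", tau = ", tau, ", m = ", m)
  out <- matrix(0, n_emb, m)
  for (k in seq_len(m)) out[, k] <- x[(1 + (k - 1L) * tau):(n_emb + (k - 1L) * tau)]
  out
}

# Estimate (tau, m) for one series; returns embedding_params plus flags.
estimate_embedding <- function(x, max_tau = NULL, max_m = 10L, rtol = 10,
                               atol = 2, fnn_threshold = 0.05,
                               theiler_window = 1L) {
  tau <- select_delay(x, max_tau)
  m <- select_dimension(x, tau, max_m, rtol, atol, fnn_threshold)
  p <- embedding_params(tau, m, theiler_window)
  p$flag <- attr(m, "flag")
  p
}
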