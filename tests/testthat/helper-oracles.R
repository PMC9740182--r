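# Independent brute-force oracles used to validate the package's optimised
# implementations. These deliberately share no code with the package: plain
# loops, stats::dist, base::table, lm().

# exhaustive diagonal/vertical line enumeration and the 12 RQA metrics
oracle_rqa <- function(mat, lmin = 2, vmin = 2, min_diag_cells = 10,
                       n_eligible = length(mat)) {
  n <- nrow(mat)
  m <- ncol(mat)
  diag_lengths <- integer(0)
  offs <- integer(0); cnts <- integer(0); cels <- integer(0)
  for (off in (-(n - 1)):(m - 1)) {
    cells <- integer(0)
    for (i in seq_len(n)) {
      j <- i + off
      if (j >= 1 && j <= m) cells <- c(cells, mat[i, j])
    }
    run <- 0
    for (v in c(cells, 0)) {
      if (v == 1) run <- run + 1
      else if (run > 0) { diag_lengths <- c(diag_lengths, run); run <- 0 }
    }
    offs <- c(offs, off); cnts <- c(cnts, sum(cells))
    cels <- c(cels, length(cells))
  }
  vert_lengths <- integer(0)
  for (j in seq_len(m)) {
    run <- 0
    for (v in c(mat[, j], 0)) {
      if (v == 1) run <- run + 1
      else if (run > 0) { vert_lengths <- c(vert_lengths, run); run <- 0 }
    }
  }
  n_rec <- sum(mat)
  ent <- function(l) {
    if (!length(l)) return(0)
    p <- as.numeric(table(l)) / length(l)
    -sum(p * log(p))
  }
  dsel <- diag_lengths[diag_lengths >= lmin]
  vsel <- vert_lengths[vert_lengths >= vmin]
  l_max <- if (length(diag_lengths)) max(diag_lengths) else 0
  v_max <- if (length(vert_lengths)) max(vert_lengths) else 0
  keep <- cels >= min_diag_cells
  trend <- 0
  if (sum(keep) >= 2) {
    df <- data.frame(d = abs(offs[keep]), r = cnts[keep] / cels[keep])
    if (var(df$d) > 0) trend <- unname(coef(lm(r ~ d, df))[2])
  }
  c(rr = n_rec / n_eligible,
    det = if (n_rec > 0) sum(dsel) / n_rec else 0,
    mean_l = if (length(dsel)) mean(dsel) else 0,
    l_max = l_max,
    div = if (l_max >= 1) 1 / l_max else 0,
    entr = ent(dsel),
    lam = if (n_rec > 0) sum(vsel) / n_rec else 0,
    tt = if (length(vsel)) mean(vsel) else 0,
    v_max = v_max,
    v_entr = ent(vsel),
    ratio_det_rr = if (n_rec > 0) (sum(dsel) / n_rec) / (n_rec / n_eligible)
    else 0,
    trend = trend)
}

# histogram AMI via base::table on cut() factors
oracle_ami <- function(x, lag, bins) {
  n <- length(x)
  br <- seq(min(x), max(x), length.out = bins + 1)
  br[1] <- br[1] - 1e-9
  f <- cut(x, br, labels = FALSE)
  joint <- table(factor(f[1:(n - lag)], 1:bins),
                 factor(f[(lag + 1):n], 1:bins)) / (n - lag)
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (i in 1:bins) for (j in 1:bins)
    if (joint[i, j] > 0)
      s <- s + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
  as.numeric(s)
}

# the delay-selection rule, re-implemented plainly over a given AMI curve
oracle_delay_rule <- function(curve) {
  k <- length(curve)
  if (k == 1) return(1L)
  mins <- c(curve[1] < curve[2],
            if (k > 2) sapply(2:(k - 1), function(t)
              curve[t] < curve[t - 1] && curve[t] <= curve[t + 1])
            else NULL, FALSE)
  need <- 3 * median(abs(diff(curve)))
  for (t in which(mins)) {
    if (curve[t] > curve[1] - need) next
    if (any(curve[1:t] < curve[t])) next
    rest <- curve[(t + 1):k]
    lower <- which(rest < curve[t])
    upto <- if (length(lower)) rest[seq_len(lower[1] - 1)] else rest
    if (length(upto) && max(upto) - curve[t] >= need) return(as.integer(t))
  }
  if (any(mins)) return(as.integer(which(mins)[1]))
  as.integer(which.min(curve))
}

# Kennel FNN fraction for a single m, via stats::dist on the embedding
oracle_fnn_fraction <- function(x, tau, m, rtol = 10, atol = 2) {
  n <- length(x)
  np <- n - m * tau
  if (np < 2) return(NA_real_)
  emb <- sapply(0:(m - 1), function(k) x[(1 + k * tau):(np + k * tau)])
  if (m == 1) emb <- matrix(emb, ncol = 1)
  dm <- as.matrix(dist(emb))
  diag(dm) <- Inf
  sigma <- sd(x)
  floor_d <- 1e-8 * sigma
  nf <- 0
  for (i in seq_len(np)) {
    j <- which.min(dm[i, ])
    d <- max(dm[i, j], floor_d)
    extra <- abs(x[i + m * tau] - x[j + m * tau])
    if (extra / d > rtol || sqrt(d^2 + extra^2) / sigma > atol) nf <- nf + 1
  }
  nf / np
}

# Benjamini-Hochberg step-up from first principles
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- rep(NA_real_, n)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  q[o] <- pmin(adj, 1)
  q
}

# random binary matrix with tunable density
random_binary_matrix <- function(n, m = n, density = 0.2) {
  matrix(as.integer(runif(n * m) < density), n, m)
}

# a standard noiseless test tone: period 40 samples, length 660
sine_signal <- function(n = 660, period = 40) sin(2 * pi * (0:(n - 1)) / period)
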