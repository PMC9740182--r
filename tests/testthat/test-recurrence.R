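test_that("fixed-rate thresholding calibrates the recurrence rate", {
  set.seed(2)
  x <- sin(2 * pi * (0:659) / 25) + rnorm(660, 0, 0.3)
  r <- recurrence_matrix(embed_series(x, embedding_params(6, 3)))
  expect_true(r$achieved_rr >= 0.095 && r$achieved_rr <= 0.105)
  expect_identical(r$kind, "auto")
  # symmetry of auto-recurrence
  expect_identical(r$matrix, t(r$matrix))
  # Theiler window 1 removes exactly the line of identity
  expect_true(all(diag(r$matrix) == 0))
  # stored rate matches a recount from the matrix
  elig <- abs(row(r$matrix) - col(r$matrix)) >= 1
  expect_equal(sum(r$matrix[elig]) / sum(elig), r$achieved_rr)
})

test_that("identical states recur and the saturated limit is all ones", {
  set.seed(5)
  st <- matrix(rnorm(40), 20, 2)
  st[15, ] <- st[3, ]  # duplicated state far from the diagonal
  r <- recurrence_matrix(st, target_rr = 0.1, theiler_window = 1)
  expect_equal(r$matrix[15, 3], 1L)
  r1 <- recurrence_matrix(st, target_rr = 1, theiler_window = 0)
  expect_true(all(r1$matrix == 1L))
  expect_error(recurrence_matrix(matrix(1, 15, 2)), "zero")
})

test_that("cross-recurrence of a series with itself equals auto-recurrence", {
  set.seed(9)
  x <- sin(2 * pi * (0:299) / 22) + rnorm(300, 0, 0.2)
  st <- embed_series(x, embedding_params(5, 3))
  cr <- cross_recurrence_matrix(st, st)
  au <- recurrence_matrix(st, theiler_window = 0)
  expect_identical(cr$matrix, au$matrix)
  expect_true(all(diag(cr$matrix) == 1L))  # identity line included
  expect_error(cross_recurrence_matrix(st, st[, 1:2]), "mismatch")
})

test_that("a lagged copy displaces the main cross-recurrence diagonal", {
  set.seed(13)
  # aperiodic smooth signal so only one displaced diagonal is dense
  x <- as.numeric(stats::filter(rnorm(400), rep(1 / 15, 15), circular = TRUE))
  lag <- 15
  y <- c(x[(lag + 1):400], x[1:lag])  # circular shift
  sa <- embed_series(x, embedding_params(10, 2))
  sb <- embed_series(y, embedding_params(10, 2))
  cr <- cross_recurrence_matrix(sa, sb)
  # locate the densest diagonal by brute force on the distance structure
  n <- nrow(sa); m <- nrow(sb)
  offs <- -(n - 1):(m - 1)
  dens <- sapply(offs, function(off) {
    i <- max(1, 1 - off):min(n, m - off)
    if (length(i) < 50) return(0)  # ignore short wrap-around stubs
    mean(cr$matrix[cbind(i, i + off)])
  })
  best_off <- offs[which.max(dens)]
  expect_equal(best_off, -lag)
})

test_that("optimised recurrence path equals a naive double loop", {
  set.seed(21)
  for (i in 1:5) {
    x <- sin(2 * pi * (0:149) / runif(1, 10, 30)) + rnorm(150, 0, 0.3)
    st <- embed_series(x, embedding_params(3, 2))
    r <- recurrence_matrix(st, 0.1, 1)
    # naive: full distance loop, quantile threshold, explicit masking
    n <- nrow(st)
    d <- matrix(0, n, n)
    for (a in 1:n) for (b in 1:n) d[a, b] <- sqrt(sum((st[a, ] - st[b, ])^2))
    elig <- sort(d[abs(row(d) - col(d)) >= 1])
    eps <- elig[ceiling(0.1 * length(elig))]
    naive <- matrix(0L, n, n)
    naive[d <= eps & abs(row(d) - col(d)) >= 1] <- 1L
    expect_identical(r$matrix, naive)
    expect_equal(r$epsilon, eps)
  }
})
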