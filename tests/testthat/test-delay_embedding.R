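test_that("embedding matrix follows the delay-coordinate definition", {
  expect_equal(embed_series(1:5, embedding_params(1, 2)),
               cbind(1:4, 2:5))
  expect_equal(embed_series(1:7, embedding_params(1, 1)), cbind(1:7))
  x <- rnorm(660)
  emb <- embed_series(x, embedding_params(10, 3))
  expect_equal(nrow(emb), 640)
  # every embedded coordinate appears verbatim in the source series
  expect_true(all(emb %in% x))
  expect_equal(emb[5, ], c(x[5], x[15], x[25]))
  expect_error(embed_series(1:5, embedding_params(3, 3)), "too short")
})

test_that("delay selection finds the quarter period of a clean tone", {
  x <- sine_signal()
  expect_identical(as.integer(select_delay(x)), 10L)
  set.seed(11)
  expect_identical(as.integer(select_delay(x + rnorm(660, 0, 0.2))), 10L)
  expect_error(select_delay(rep(1, 660)), "constant")
  expect_error(select_delay(rnorm(20), max_tau = 10), "too short")
})

test_that("white noise yields a small delay and unconverged FNN", {
  set.seed(1)
  x <- runif(660)
  expect_lte(as.integer(select_delay(x)), 3L)
  m <- select_dimension(x, select_delay(x))
  expect_identical(as.integer(m), 10L)
  expect_identical(attr(m, "flag"), "fnn_not_converged")
})

test_that("dimension selection recovers m = 2 for the clean tone", {
  x <- sine_signal()
  m <- select_dimension(x, 10L)
  expect_identical(as.integer(m), 2L)
  expect_true(is.na(attr(m, "flag")))
  fnn <- attr(m, "fnn")
  expect_gt(fnn[1], 0.05)
  expect_lte(fnn[2], 0.05)
})

test_that("dimension search succeeds at the minimal supportable length", {
  # length exactly (max_m - 1) * tau + 10 supports the boundary embedding
  tau <- 3L
  max_m <- 4L
  n <- (max_m - 1) * tau + 10
  set.seed(8)
  x <- sin(2 * pi * (0:(n - 1)) / 6) + rnorm(n, 0, 0.05)
  m <- select_dimension(x, tau, max_m = max_m)
  expect_true(as.integer(m) >= 1 && as.integer(m) <= max_m)
})

test_that("delay and dimension are invariant under affine transforms", {
  set.seed(4)
  for (i in 1:5) {
    x <- sin(2 * pi * (0:499) / runif(1, 20, 30)) + rnorm(500, 0, 0.1)
    y <- 3 * x + 7
    expect_identical(as.integer(select_delay(x)), as.integer(select_delay(y)))
    tau <- select_delay(x)
    expect_identical(as.integer(select_dimension(x, tau)),
                     as.integer(select_dimension(y, tau)))
  }
})

test_that("AMI and FNN agree with independent brute-force implementations", {
  set.seed(17)
  for (i in 1:6) {
    n <- 300
    x <- if (i %% 2 == 0) runif(n) else
      sin(2 * pi * (0:(n - 1)) / runif(1, 15, 45)) + rnorm(n, 0, 0.2)
    bins <- max(4L, ceiling(n^(1 / 3)))
    for (lag in c(1, 5, 11))
      expect_equal(ami(x, lag, bins), oracle_ami(x, lag, bins),
                   tolerance = 1e-10)
    tau <- as.integer(select_delay(x))
    curve <- sapply(1:max(1L, min(60L, floor(n / 4))),
                    function(l) oracle_ami(x, l, bins))
    expect_identical(tau, oracle_delay_rule(curve))
    for (m in 1:3)
      expect_equal(
        fnn_fractions_cpp(x, tau, 3L, 10, 2, -1)[m],
        oracle_fnn_fraction(x, tau, m), tolerance = 1e-12)
  }
})
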