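make_feature_df <- function(x) {
  df <- as.data.frame(x)
  rownames(df) <- sprintf("S%03d", seq_len(nrow(df)))
  df
}

make_subjects <- function(n, diagnosis = rep(c("case", "control"), length.out = n)) {
  data.frame(subject_id = sprintf("S%03d", 1:n), diagnosis = diagnosis,
             sex = rep(c("male", "female"), length.out = n),
             age_months = rep(c(1.2, 2.7, 1.9, 3.3, 2.1), length.out = n),
             site = "site1", batch = "B1", stringsAsFactors = FALSE)
}

test_that("batch correction centres and scales within batches", {
  set.seed(1)
  batch <- rep(c("A", "B"), each = 10)
  f <- c(rnorm(10, 5, 1), rnorm(10, 50, 1))
  tab <- make_feature_df(cbind(f1 = f))
  out <- batch_correct_and_zscore(tab, batch)
  # the huge location difference between batches is removed entirely
  for (b in c("A", "B")) {
    expect_equal(mean(out$f1[batch == b]), 0, tolerance = 1e-10)
    expect_equal(sd(out$f1[batch == b]), 1, tolerance = 0.05)
  }
  expect_equal(sd(out$f1), 1, tolerance = 1e-10)
  expect_equal(sd(out$f1[batch == "A"]), sd(out$f1[batch == "B"]),
               tolerance = 1e-10)
  # single batch reduces to a plain z-score
  one <- batch_correct_and_zscore(tab, rep("A", 20))
  expect_equal(one$f1, as.numeric(scale(f)), tolerance = 1e-10)
  # constant-within-batch features become missing, not infinite
  tab2 <- make_feature_df(cbind(f1 = f, f2 = c(rep(1, 10), rnorm(10))))
  expect_warning(out2 <- batch_correct_and_zscore(tab2, batch), "constant")
  expect_true(all(is.na(out2$f2)))
  expect_false(anyNA(out2$f1))
  expect_error(batch_correct_and_zscore(tab, rep(c("A", "B", "C"), c(18, 1, 1))),
               "fewer than 3")
})

test_that("association scan recovers a planted effect and duplicates agree", {
  set.seed(42)
  n <- 120
  subj <- make_subjects(n, sample(rep(c("case", "control"), n / 2)))
  y <- subj$diagnosis == "case"
  x_signal <- rnorm(n) + 1.2 * y
  x_null <- matrix(rnorm(n * 30), n)
  tab <- make_feature_df(cbind(sig = x_signal, dup = x_signal, x_null))
  rows <- associate(tab, subj)
  expect_equal(nrow(rows), 32)
  i_sig <- which(rows$feature_id == "sig")
  i_dup <- which(rows$feature_id == "dup")
  expect_identical(rows$beta[i_sig], rows$beta[i_dup])
  expect_identical(rows$p[i_sig], rows$p[i_dup])
  expect_true(rows$significant[i_sig])
  expect_gt(rows$beta[i_sig], 0)
  expect_true(all(rows$q >= rows$p, na.rm = TRUE))
})

test_that("p-values are invariant to affine rescaling of a feature", {
  set.seed(7)
  n <- 80
  subj <- make_subjects(n, sample(rep(c("case", "control"), n / 2)))
  x <- rnorm(n) + 0.8 * (subj$diagnosis == "case")
  t1 <- make_feature_df(cbind(f = x))
  t2 <- make_feature_df(cbind(f = 1000 * x - 3))
  r1 <- associate(batch_correct_and_zscore(t1, subj$batch), subj)
  r2 <- associate(batch_correct_and_zscore(t2, subj$batch), subj)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-9)
})

test_that("BH adjustment matches a from-scratch step-up reference", {
  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # and the scan uses exactly that adjustment
  n <- 60
  subj <- make_subjects(n, sample(rep(c("case", "control"), n / 2)))
  tab <- make_feature_df(matrix(rnorm(n * 15), n,
                                dimnames = list(NULL, paste0("f", 1:15))))
  rows <- associate(tab, subj)
  expect_equal(rows$q, oracle_bh(rows$p), tolerance = 1e-12)
})

test_that("separated features are flagged and left out of the FDR set", {
  n <- 40
  subj <- make_subjects(n, rep(c("case", "control"), each = n / 2))
  sep <- c(rnorm(n / 2, 10), rnorm(n / 2, -10))  # perfect separation
  tab <- make_feature_df(cbind(sep = sep, ok = rnorm(n)))
  rows <- associate(tab, subj)
  expect_identical(rows$flag[rows$feature_id == "sep"], "separation")
  expect_true(is.na(rows$q[rows$feature_id == "sep"]))
  expect_false(is.na(rows$q[rows$feature_id == "ok"]))
})

test_that("permuted labels rarely produce FDR discoveries", {
  set.seed(5)
  n <- 100
  tab <- make_feature_df(matrix(rnorm(n * 50), n,
                                dimnames = list(NULL, paste0("f", 1:50))))
  hits <- 0
  for (i in 1:40) {
    subj <- make_subjects(n, sample(rep(c("case", "control"), n / 2)))
    hits <- hits + sum(associate(tab, subj)$significant)
  }
  expect_lt(hits / 40, 0.5)  # virtually no discoveries under the null
})

test_that("pathway summaries count and orient significant features", {
  rows <- data.frame(
    feature_id = paste0("f", 1:6),
    pathway = c("Zn", "Zn", "Zn", "Cu", "Cu", "Cu.Li"),
    metric = "det",
    beta = c(-1, -2, 0.5, 1, 2, -1), se = 1,
    p = c(0.001, 0.002, 0.5, 0.6, 0.7, 0.8),
    q = c(0.01, 0.02, 0.7, 0.8, 0.9, 0.9),
    significant = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    direction = sign(c(-1, -2, 0.5, 1, 2, -1)),
    flag = NA_character_, stringsAsFactors = FALSE)
  fs <- forest_summary(rows)
  expect_equal(fs$summary$pathway[1], "Zn")
  expect_equal(fs$summary$n_sig[1], 2)
  expect_equal(fs$summary$n_sig_neg[1], 2)
  expect_equal(fs$summary$n_sig_pos[1], 0)
  expect_true(all(fs$summary$n_sig[-1] == 0))
})
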