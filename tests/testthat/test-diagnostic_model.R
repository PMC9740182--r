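test_that("train/holdout split sizes follow round-half-up arithmetic", {
  ids <- sprintf("S%03d", 1:486)
  labels <- rep(c("case", "control"), c(175, 311))
  sp <- split_subjects(ids, labels, 0.8, seed = 3)
  expect_equal(length(sp$train_ids), 389)
  expect_equal(length(sp$holdout_ids), 97)
  expect_length(intersect(sp$train_ids, sp$holdout_ids), 0)
  expect_setequal(c(sp$train_ids, sp$holdout_ids), ids)

  sp10 <- split_subjects(sprintf("x%d", 1:10), rep("case", 10), 0.8, 1)
  expect_equal(length(sp10$train_ids), 8)
  expect_equal(length(sp10$holdout_ids), 2)

  sp2 <- split_subjects(ids, labels, 0.8, seed = 3)
  expect_identical(sp$train_ids, sp2$train_ids)
  expect_error(split_subjects(ids[1:5], labels[1:5]), "at least 10")
})

test_that("screening ranks by training-set association only", {
  set.seed(12)
  n <- 60
  subj <- data.frame(subject_id = sprintf("S%03d", 1:n),
                     diagnosis = sample(rep(c("case", "control"), n / 2)),
                     sex = rep(c("male", "female"), n / 2),
                     age_months = runif(n, 1, 3), batch = "B1")
  y <- subj$diagnosis == "case"
  x <- cbind(good1 = rnorm(n) + 2 * y, good2 = rnorm(n) - 2 * y,
             matrix(rnorm(n * 20), n, dimnames = list(NULL, paste0("z", 1:20))))
  tab <- as.data.frame(x)
  rownames(tab) <- subj$subject_id
  sel <- screen_features(tab, subj, k = 2)
  expect_setequal(sel, c("good1", "good2"))
  expect_identical(screen_features(tab, subj, k = ncol(tab)) |> sort(),
                   sort(colnames(tab)))  # k = all is the identity subset
  expect_error(screen_features(tab, subj, k = 99), "exceeds")
})

test_that("tuning returns a valid deterministic model even at budget 1", {
  set.seed(31)
  n <- 90
  x <- matrix(rnorm(n * 8), n)
  y <- as.integer(runif(n) < plogis(1.5 * x[, 1] - x[, 2]))
  m1 <- tune_and_fit(x, y, folds = 3, budget = 1, seed = 5)
  expect_s3_class(m1, "tuned_model")
  expect_equal(nrow(m1$history), 1)
  s1 <- predict_scores(m1, x)
  expect_true(all(is.finite(s1)) && all(s1 >= 0 & s1 <= 1))

  m2 <- tune_and_fit(x, y, folds = 3, budget = 1, seed = 5)
  expect_identical(predict_scores(m2, x), s1)
  expect_error(tune_and_fit(x, rep(1L, n), folds = 3, budget = 1), "single-class")
  expect_error(tune_and_fit(x[1:10, ], y[1:10], folds = 5, budget = 1),
               "at least")
})

test_that("surrogate-guided search improves on or matches its random start", {
  set.seed(77)
  n <- 120
  x <- matrix(rnorm(n * 6), n)
  y <- as.integer(runif(n) < plogis(2 * x[, 1] + x[, 2] * x[, 3]))
  m <- tune_and_fit(x, y, folds = 3, budget = 8, seed = 11)
  expect_equal(nrow(m$history), 8)
  expect_gte(max(m$history$auc), m$history$auc[1])
  expect_equal(m$best_cv_auc, max(m$history$auc))
})

test_that("confusion metrics reproduce hand arithmetic with exact CIs", {
  cm <- confusion_metrics(tp = 27, fn = 1, tn = 52, fp = 17)
  expect_equal(cm$sensitivity$estimate, 27 / 28)
  expect_equal(cm$specificity$estimate, 52 / 69)
  expect_equal(cm$accuracy$estimate, 79 / 97)
  bt <- binom.test(27, 28)$conf.int
  expect_equal(cm$sensitivity$lower, bt[1], tolerance = 1e-9)
  expect_equal(cm$sensitivity$upper, bt[2], tolerance = 1e-9)
  expect_true(cm$accuracy$lower <= cm$accuracy$estimate &&
                cm$accuracy$estimate <= cm$accuracy$upper)
})

test_that("evaluation selects the Youden-optimal threshold", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  labels <- c("case", "case", "control", "case", "control", "control")
  rep_ <- evaluate_scores(scores, labels)
  expect_equal(rep_$j, max(rep_$roc$sensitivity + rep_$roc$specificity - 1))
  expect_equal(
    rep_$confusion$counts[["tp"]] / 3 + rep_$confusion$counts[["tn"]] / 3 - 1,
    rep_$j)
  # perfect separation
  perf <- evaluate_scores(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perf$auc, 1)
  expect_equal(perf$j, 1)
  expect_error(evaluate_scores(c(1, 2), c("case", "case")), "both classes")
  expect_error(evaluate_scores(c(1, NA), c("case", "control")), "finite")
})

test_that("AUC is the Mann-Whitney statistic and is rank-invariant", {
  set.seed(8)
  y <- rep(c(1, 0), each = 40)
  s <- c(rnorm(40, 1), rnorm(40))
  a <- mw_auc(s, y)
  # brute force over all case-control pairs
  brute <- mean(outer(s[y == 1], s[y == 0], ">") +
                  0.5 * outer(s[y == 1], s[y == 0], "=="))
  expect_equal(a, brute)
  expect_equal(mw_auc(plogis(3 * s - 1), y), a)  # monotone transform
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("near-chance AUC arises for label-independent scores", {
  set.seed(10)
  y <- rep(c(1, 0), each = 300)
  s <- runif(600)
  expect_lt(abs(mw_auc(s, y) - 0.5), 0.08)
})

test_that("stratified AUC comparison is calibrated in its degenerate cases", {
  set.seed(23)
  n <- 120
  y <- rep(c("case", "control"), each = n / 2)
  s <- rnorm(n) + (y == "case")
  # stratum equal to the whole sample: p = 1 by construction
  whole <- stratified_performance(s, y, rep("all", n))
  expect_equal(whole$p_vs_overall, 1)
  expect_equal(whole$auc, mw_auc(s, y))
  # two identical strata: identical AUCs, p approximately 1
  s2 <- c(s, s)
  y2 <- c(y, y)
  g2 <- rep(c("a", "b"), each = n)
  two <- stratified_performance(s2, y2, g2)
  expect_equal(two$auc[1], two$auc[2])
  expect_true(all(two$p_vs_overall > 0.99))
  # a single-class stratum is flagged, not computed
  g3 <- ifelse(y == "case", "only_cases", "mixed")
  g3[1:10] <- "mixed"
  res <- stratified_performance(s, y, g3)
  expect_identical(res$flag[res$stratum == "only_cases"], "single_class")
  expect_true(is.na(res$auc[res$stratum == "only_cases"]))
})

test_that("holdout fingerprints detect any modification", {
  x <- data.frame(a = 1:5, b = rnorm(5))
  h1 <- data_fingerprint(x)
  expect_identical(h1, data_fingerprint(x))
  x$b[3] <- x$b[3] + 1e-9
  expect_false(identical(h1, data_fingerprint(x)))
})
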