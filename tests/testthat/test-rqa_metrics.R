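test_that("saturated and line-free matrices give the limiting metric values", {
  q <- rqa_quantify(matrix(1L, 50, 50))
  expect_equal(unname(q["rr"]), 1)
  # the two corner cells are singleton diagonals, below lmin by definition
  expect_equal(unname(q["det"]), (2500 - 2) / 2500)
  expect_equal(unname(q["lam"]), 1)
  expect_equal(unname(q["l_max"]), 50)

  # recurrent points only at isolated, non-adjacent cells
  iso <- matrix(0L, 9, 9)
  iso[cbind(c(1, 4, 7, 3), c(5, 1, 3, 9))] <- 1L
  qi <- rqa_quantify(iso)
  expect_equal(unname(qi["det"]), 0)
  expect_equal(unname(qi["lam"]), 0)
  expect_equal(unname(qi["mean_l"]), 0)
  expect_equal(unname(qi["entr"]), 0)

  # fully empty matrix: degenerate values, no error
  q0 <- rqa_quantify(matrix(0L, 8, 8))
  expect_true(all(q0 == 0))
})

test_that("a handcrafted matrix reproduces exact line arithmetic", {
  # one diagonal line of length 3, one of length 2, four isolated points
  m <- matrix(0L, 8, 8)
  m[cbind(1:3, 2:4)] <- 1L          # length-3 diagonal
  m[cbind(5:6, 1:2)] <- 1L          # length-2 diagonal
  m[cbind(c(1, 3, 8, 8), c(7, 6, 1, 5))] <- 1L
  stopifnot(sum(m) == 9)
  q <- rqa_quantify(m)
  expect_equal(unname(q["det"]), 5 / 9)
  expect_equal(unname(q["mean_l"]), 2.5)
  expect_equal(unname(q["l_max"]), 3)
  expect_equal(unname(q["div"]), 1 / 3)
  expect_equal(unname(q["entr"]), log(2))  # histogram {2:1, 3:1}
  expect_equal(q[names(q) != "trend"],
               oracle_rqa(m)[names(q) != "trend"])
})

test_that("metrics equal the brute-force enumerator on random matrices", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    m <- random_binary_matrix(n, sample(8:30, 1), runif(1, 0.05, 0.5))
    expect_equal(rqa_quantify(m), oracle_rqa(m), tolerance = 1e-12)
  }
})

test_that("periodic signals are more deterministic than noise", {
  x <- sine_signal()
  qs <- rqa_quantify(recurrence_matrix(embed_series(x, embedding_params(10, 2))))
  set.seed(14)
  y <- runif(660)
  qn <- rqa_quantify(recurrence_matrix(embed_series(y, embedding_params(2, 3))))
  expect_gt(qs[["det"]], 0.95)
  expect_gt(qs[["det"]], qn[["det"]])
  expect_gt(qs[["mean_l"]], qn[["mean_l"]])
})

test_that("quantifying cross(x, x) equals quantifying auto(x) without a Theiler window", {
  set.seed(6)
  x <- sin(2 * pi * (0:299) / 20) + rnorm(300, 0, 0.25)
  st <- embed_series(x, embedding_params(5, 2))
  expect_equal(rqa_quantify(cross_recurrence_matrix(st, st)),
               rqa_quantify(recurrence_matrix(st, theiler_window = 0)))
})

test_that("feature table has the pathway-by-metric layout and is deterministic", {
  cfg <- cohort_config(n_subjects = 4, n_elements = 3, seed = 19)
  coh <- generate_cohort(cfg)
  ft <- feature_table(coh$profiles)
  expect_equal(ncol(ft), (3 + 3) * 12)  # 3 elements + 3 pairs, 12 metrics
  expect_equal(nrow(ft), 4)
  prov <- attr(ft, "provenance")
  expect_equal(nrow(prov), ncol(ft))
  expect_setequal(unique(prov$pathway),
                  c("Zn", "Cu", "Li", "Zn.Cu", "Zn.Li", "Cu.Li"))
  log <- attr(ft, "embedding_log")
  expect_equal(nrow(log), 4 * 3)
  expect_true(all(!is.na(log$tau)))

  ft2 <- feature_table(coh$profiles)
  expect_identical(ft, ft2)

  # a 2-element panel gives 2 RQA + 1 CRQA pathways = 36 features
  ft3 <- feature_table(coh$profiles, panel = c("Zn", "Cu"))
  expect_equal(ncol(ft3), 36)
})

test_that("determinism and mean line length fall as the case effect grows", {
  dets <- c(); mls <- c()
  for (es in c(0, 0.4, 0.8)) {
    d <- c(); l <- c()
    for (s in 1:6) {
      cfg <- cohort_config(n_subjects = 4, case_fraction = 0.5,
                           n_elements = 1, perturbed_elements = "Zn",
                           effect_size = es, seed = 100 + s)
      coh <- generate_cohort(cfg)
      case_ids <- coh$subjects$subject_id[coh$subjects$diagnosis == "case"]
      for (sid in case_ids) {
        r <- ratio_matrix(coh$profiles[[sid]])[, "Zn"]
        q <- rqa_quantify(recurrence_matrix(
          embed_series(r, embedding_params(select_delay(r), 3))))
        d <- c(d, q[["det"]]); l <- c(l, q[["mean_l"]])
      }
    }
    dets <- c(dets, mean(d)); mls <- c(mls, mean(l))
  }
  # mean line length responds over the whole grid; determinism saturates at
  # small attenuations in the low-noise regime, so only its endpoint drop is
  # asserted
  expect_true(all(diff(mls) < 0))
  expect_lt(dets[3], dets[1])
})
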