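test_that("Cliff's delta matches the exhaustive pair-count oracle", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 3, 4)), -5 / 9)
  expect_equal(cliffs_delta(c(5, 1, 9), c(5, 1, 9)), 0)
  expect_equal(cliffs_delta(10:12, 1:3), 1)
  expect_equal(cliffs_delta(1:3, 10:12), -1)
  # property sweep against an explicit double loop
  oracle <- function(a, b) {
    s <- 0
    for (x in a) for (y in b) s <- s + sign(x - y)
    s / (length(a) * length(b))
  }
  set.seed(11)
  for (i in 1:100) {
    a <- sample(-5:5, sample(2:12, 1), replace = TRUE)
    b <- sample(-5:5, sample(2:12, 1), replace = TRUE)
    expect_identical(cliffs_delta(a, b), oracle(a, b))
    expect_identical(cliffs_delta(a, b), -cliffs_delta(b, a))
    expect_lte(abs(cliffs_delta(a, b)), 1)
  }
  expect_error(cliffs_delta(numeric(0), 1:3), "empty")
})

test_that("effect labels reproduce the questionnaire-table mapping", {
  # the ten printed deltas and their labels (blank rows are negligible)
  printed <- data.frame(
    delta = c(-0.4, -0.1, 0.0, -0.1, -0.3, 0.3, -0.4, 0.3, -0.5, 0.1),
    label = c("medium", "negligible", "negligible", "negligible", "small",
              "small", "medium", "small", "medium", "negligible")
  )
  expect_identical(effect_label(printed$delta), printed$label)
  expect_identical(effect_label(0.7), "large")
  expect_identical(effect_label(-1), "large")
  # thresholds are configurable
  expect_identical(effect_label(0.5, cuts = c(0.147, 0.33, 0.474)), "large")
})

test_that("the signed-rank statistic matches an independent implementation", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    x <- rnorm(n); y <- rnorm(n, mean = 0.4)
    mine <- wilcoxon_signed_rank(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                         correct = FALSE))
    # same p under the plain normal approximation; statistic is min(W+, W-)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    d <- x - y; d <- d[d != 0]; ne <- length(d)
    expect_equal(mine$statistic,
                 min(unname(ref$statistic),
                     ne * (ne + 1) / 2 - unname(ref$statistic)))
  }
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "degenerate")
})

test_that("compare_paired gates on normality and matches reference tests", {
  set.seed(31)
  x <- rnorm(30); y <- rnorm(30, mean = 0.8)
  res <- compare_paired(x, y, force_test = "t")
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_identical(res$test_name, "paired_t")
  # heavy-tailed margins trip the Shapiro gate into the Wilcoxon branch
  set.seed(32)
  xe <- rexp(30)^2; ye <- rexp(30)^2 + 0.5
  res2 <- compare_paired(xe, ye)
  expect_identical(res2$test_name, "wilcoxon_signed_rank")
  expect_true(any(attr(res2, "shapiro") < 0.05))
  # clean Gaussians stay in the t branch
  set.seed(33)
  xg <- rnorm(40); yg <- rnorm(40, 0.3)
  expect_identical(compare_paired(xg, yg)$test_name, "paired_t")
  expect_error(compare_paired(rep(1, 10), rep(1, 10)), "degenerate")
})

test_that("compare_paired holds its size and power at the study sample size", {
  nrep <- 200
  rej_null <- rej_shift <- 0
  for (i in 1:nrep) {
    set.seed(1000 + i)
    x <- rnorm(34); y0 <- rnorm(34); y1 <- rnorm(34, mean = 1)
    rej_null <- rej_null + (compare_paired(x, y0)$p_value < 0.05)
    rej_shift <- rej_shift + (compare_paired(x, y1)$p_value < 0.05)
  }
  expect_gt(rej_shift / nrep, 0.95) # 1 sd shift, n = 34
  expect_gt(rej_null / nrep, 0.01)
  expect_lt(rej_null / nrep, 0.10)
})

test_that("baseline correction is exact, linear and demands complete triples", {
  df <- data.frame(participant = rep(1:2, each = 3),
                   condition = rep(c("human", "no_coupling", "coupling"), 2),
                   time_pressed_s = c(10, 5, 20, 7, 7, 7))
  bc <- baseline_correct(df)
  expect_equal(bc$coupling_minus_human, c(10, 0))
  expect_equal(bc$no_coupling_minus_human, c(-5, 0))
  # adding a constant to all conditions leaves differences unchanged
  df2 <- df; df2$time_pressed_s <- df2$time_pressed_s + 11.5
  expect_equal(baseline_correct(df2)[, -1], bc[, -1])
  expect_error(baseline_correct(df[-1, ]), "all three conditions")
})

test_that("questionnaire analysis flags injected effects and only those", {
  eff <- zero_effects(); eff[9, "coupling"] <- 2
  hits9 <- hits_other <- 0
  nrep <- 60
  for (i in 1:nrep) {
    q <- generate_questionnaire(34, eff, sd = 0.5, seed = i)
    res <- analyze_questionnaire(q)
    hits9 <- hits9 + (res$p_value[res$question == 9] < 0.05)
    hits_other <- hits_other + sum(res$p_value[res$question != 9] < 0.05,
                                   na.rm = TRUE)
  }
  expect_gte(hits9 / nrep, 0.95)
  expect_lt(hits_other / (nrep * 9), 0.10)
  # schema mirrors the published table: medians, statistic, p, delta, label
  res <- analyze_questionnaire(generate_questionnaire(34, eff, seed = 1))
  expect_named(res, c("question", "median_a", "median_b", "statistic",
                      "p_value", "delta", "label"))
  expect_identical(res$question, 1:10)
  # incomplete pairing is rejected
  q <- generate_questionnaire(10, seed = 1)
  drop <- q$participant == 1 & q$condition == "no_coupling" & q$question == 1
  expect_error(analyze_questionnaire(q[!drop, ]), "paired")
})

test_that("sync-times analysis runs both stages in order and survives degeneracy", {
  st <- generate_sync_times(seed = 7)
  res <- analyze_sync_times(st)
  nm <- names(res)[vapply(res, inherits, TRUE, what = "stat_result")]
  expect_identical(nm, c("shapiro_human", "shapiro_no_coupling",
                         "shapiro_coupling", "wilcoxon_raw",
                         "shapiro_coupling_minus_human",
                         "shapiro_no_coupling_minus_human",
                         "paired_t_baseline"))
  expect_true(all(vapply(nm, function(k) {
    p <- res[[k]]$p_value
    is.na(p) || (p >= 0 && p <= 1)
  }, TRUE)))
  expect_equal(nrow(res$differences), 34)
  # identical times across conditions: flagged null results, no error
  flat <- data.frame(participant = rep(1:10, each = 3),
                     condition = rep(c("human", "no_coupling", "coupling"),
                                     10),
                     time_pressed_s = rep(30, 30))
  res2 <- analyze_sync_times(flat)
  expect_identical(res2$wilcoxon_raw$note, "degenerate")
  expect_identical(res2$paired_t_baseline$note, "degenerate")
  expect_true(is.na(res2$paired_t_baseline$p_value))
})

test_that("a baseline-masked effect is found more often after correction", {
  # participants differ wildly in button habit (including pressers at the
  # ceiling); the condition effect is small relative to that baseline noise
  s1 <- s2 <- 0
  nrep <- 80
  for (i in 1:nrep) {
    st <- generate_sync_times(seed = 500 + i)
    res <- analyze_sync_times(st)
    s1 <- s1 + (!is.na(res$wilcoxon_raw$p_value) &&
                  res$wilcoxon_raw$p_value < 0.05)
    s2 <- s2 + (!is.na(res$paired_t_baseline$p_value) &&
                  res$paired_t_baseline$p_value < 0.05)
  }
  expect_gte(s2, s1 * 0.8) # the t stage is at least as sensitive
  expect_gt(s2 / nrep, 0.3) # and detects the injected effect regularly
})
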