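test_that("absolute-agreement ICC matches an independent ANOVA route", {
  set.seed(60)
  for (i in 1:25) {
    k <- sample(2:4, 1); n <- sample(3:12, 1)
    # real column (object) variance keeps both denominators well conditioned
    m <- matrix(stats::rnorm(k * n), k, n) +
      rep(stats::rnorm(n, sd = 2), each = k)
    r <- icc_a1(m)
    # independent oracle: mean squares from lm()'s ANOVA decomposition
    df <- data.frame(y = as.vector(m),
                     meas = factor(rep(seq_len(k), n)),
                     obj = factor(rep(seq_len(n), each = k)))
    a <- stats::anova(stats::lm(y ~ meas + obj, df))
    ms <- a$`Mean Sq`
    expect_equal(c(r$ms_rows, r$ms_cols, r$ms_error), unname(ms),
                 tolerance = 1e-10)
    oracle <- (ms[2] - ms[3]) /
      (ms[2] + (k - 1) * ms[3] + (k / n) * (ms[1] - ms[3]))
    expect_equal(r$value, unname(oracle), tolerance = 1e-10)
    # printed-sign variant flips the measurement term
    oracle_p <- (ms[2] - ms[3]) /
      (ms[2] + (k - 1) * ms[3] - (k / n) * (ms[1] - ms[3]))
    expect_equal(r$value_alt, unname(oracle_p), tolerance = 1e-10)
  }
})

test_that("ICC limiting cases and invariances hold", {
  expect_equal(icc_a1(rbind(1:6, 1:6))$value, 1)
  set.seed(61)
  vals <- replicate(200, icc_a1(matrix(stats::rnorm(2 * 50), 2, 50))$value)
  expect_lt(abs(mean(vals)), 0.05)  # null case
  m <- matrix(stats::rnorm(8), 2, 4)
  expect_equal(icc_a1(m + 7)$value, icc_a1(m)$value, tolerance = 1e-12)
  shifted <- m; shifted[1, ] <- shifted[1, ] + 1
  expect_lt(icc_a1(shifted)$value, icc_a1(m)$value)
  expect_error(icc_a1(matrix(1, 1, 5)), ">= 2")
  expect_error(icc_a1(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
  deg <- icc_a1(matrix(2, 3, 3))
  expect_equal(deg$value, 1)
  expect_true(isTRUE(attr(deg, "degenerate")))
})

test_that("whole-image between-session ICC is symmetric and banded", {
  set.seed(62)
  d <- c(10, 10, 10)
  mask <- array(TRUE, d)
  a <- array(stats::rnorm(1000), d)
  b <- a + array(stats::rnorm(1000, sd = 0.4), d)
  r_ab <- icc_between(a, b, mask)
  r_ba <- icc_between(b, a, mask)
  expect_equal(r_ab$value, r_ba$value, tolerance = 1e-12)
  expect_equal(icc_between(a, a, mask)$value, 1)
  indep <- icc_between(a, array(stats::rnorm(1000), d), mask)
  expect_lt(abs(indep$value), 0.1)
  ex <- array(FALSE, d); ex[1:5, , ] <- TRUE
  r_ex <- icc_between(a, b, mask, exclude = ex)
  expect_equal(r_ex$n_cols, 500L)
  expect_error(icc_between(a, b, mask, exclude = mask), "empty")
  expect_equal(as.character(icc_band(c(0.1, 0.3, 0.5, 0.75, 0.9))),
               c("poor", "fair", "moderate", "good", "excellent"))
})

test_that("voxelwise ICC maps recover planted variance components", {
  set.seed(63)
  d <- c(8, 8, 4)
  mask <- array(TRUE, d)
  n_sub <- 20; sigma_b <- 1; sigma_w <- 1
  maps <- lapply(1:2, function(meas) lapply(1:n_sub, function(s) NULL))
  subj_effect <- array(stats::rnorm(prod(d) * n_sub, sd = sigma_b),
                       c(prod(d), n_sub))
  for (meas in 1:2) for (s in 1:n_sub)
    maps[[meas]][[s]] <- array(subj_effect[, s] +
                                 stats::rnorm(prod(d), sd = sigma_w), d)
  res <- icc_within_map(maps, mask)
  expect_true(all(res$valid_mask))
  expect_equal(stats::median(res$values),
               sigma_b^2 / (sigma_b^2 + sigma_w^2), tolerance = 0.05)
  # identical measurements give ICC 1 everywhere
  same <- list(maps[[1]], maps[[1]])
  res1 <- icc_within_map(same, mask)
  expect_true(all(abs(res1$values - 1) < 1e-12))
})

test_that("image similarity equals direct correlation and flags constants", {
  set.seed(64)
  d <- c(9, 9, 9)
  mask <- array(TRUE, d)
  a <- array(stats::rnorm(prod(d)), d)
  b <- array(stats::rnorm(prod(d)), d)
  expect_equal(image_similarity(a, a, mask), 1)
  expect_equal(image_similarity(a, -a, mask), -1)
  expect_equal(image_similarity(a, b, mask),
               stats::cor(as.vector(a), as.vector(b)), tolerance = 1e-12)
  expect_warning(sim <- image_similarity(array(1, d), a, mask), "constant")
  expect_true(is.na(sim))
  # ICC-based reading available
  expect_equal(image_similarity(a, a, mask, method = "icc"), 1)
})

test_that("Friedman test matches the rank formula and detects monotone effects", {
  expect_equal(friedman_test(matrix(1:10, 10, 3)),
               list(statistic = 0, p_value = 1, df = 2L))
  m3 <- matrix(c(1, 2, 3, 2, 3, 1, 1, 3, 2), 3, 3, byrow = TRUE)
  # hand-computed rank formula on a tie-free matrix
  R <- t(apply(m3, 1, rank))
  n <- 3; k <- 3
  stat_hand <- 12 / (n * k * (k + 1)) * sum((colSums(R) - n * (k + 1) / 2)^2)
  expect_equal(friedman_test(m3)$statistic, stat_hand, tolerance = 1e-12)
  set.seed(65)
  mono <- matrix(stats::rnorm(30, sd = 0.2), 10, 3) +
    outer(rep(1, 10), c(0, 1, 2))
  expect_lt(friedman_test(mono)$p_value, 0.01)
})
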