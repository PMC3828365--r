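test_that("beta onset is the first session with a detection", {
  expect_equal(beta_onset_age(c(9, 13, 17, 22), c(FALSE, FALSE, TRUE, TRUE)),
               17)
  expect_true(is.na(beta_onset_age(c(9, 13), c(FALSE, FALSE))))
  # no persistence requirement: an isolated early detection dates the onset
  expect_equal(beta_onset_age(c(9, 13, 17), c(TRUE, FALSE, TRUE)), 9)
  expect_error(beta_onset_age(numeric(0), logical(0)),
               class = "betasleep_input_size_error")
  expect_error(beta_onset_age(c(9, 9), c(TRUE, TRUE)),
               class = "betasleep_format_error")
})

test_that("precedence summarizes onset differences as specified", {
  onsets <- data.frame(mouse_id = c("m1", "m2"),
                       beta_onset_weeks = c(10, 12))
  clasping <- rbind(
    clasping_record("m1", c(10, 16, 20), c(FALSE, TRUE, TRUE)),
    clasping_record("m2", c(10, 16, 20), c(FALSE, FALSE, TRUE)))
  ps <- precedence_summary(onsets, clasping)
  expect_equal(ps$per_mouse$precedence_weeks, c(6, 8))
  expect_equal(ps$mean, 7)
  expect_equal(ps$sem, sd(c(6, 8)) / sqrt(2))
  expect_equal(ps$n_beta_first, 2)
  expect_equal(ps$n_clasp_first, 0)

  # exact ties count as neither
  tie <- precedence_summary(
    data.frame(mouse_id = c("m1", "m2"), beta_onset_weeks = c(16, 20)),
    clasping)
  expect_equal(tie$mean, 0)
  expect_equal(tie$n_beta_first + tie$n_clasp_first, 0)

  expect_error(precedence_summary(
    data.frame(mouse_id = "m9", beta_onset_weeks = 10), clasping),
    class = "betasleep_join_error")
})

test_that("the 2x2 chi-square matches the Pearson formula and its oracle", {
  full <- chi_square_2x2(matrix(c(10, 0, 0, 8), 2, byrow = TRUE))
  expect_identical(full$statistic, 18)
  expect_identical(full$df, 1L)
  expect_lt(full$p, 1e-4)

  expect_equal(chi_square_2x2(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(c(6, 4, 2, 8), 2,
                                     byrow = TRUE))$statistic,
               10 / 3, tolerance = 1e-12)

  # independent oracle: stats::chisq.test without continuity correction
  for (seed in 1:5) {
    withr::with_seed(seed, m <- matrix(rpois(4, 10) + 1, 2))
    ours <- chi_square_2x2(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }

  # invariance to transposition and row/column swaps
  m <- matrix(c(7, 3, 2, 9), 2)
  s0 <- chi_square_2x2(m)$statistic
  expect_equal(chi_square_2x2(t(m))$statistic, s0)
  expect_equal(chi_square_2x2(m[2:1, ])$statistic, s0)
  expect_equal(chi_square_2x2(m[, 2:1])$statistic, s0)

  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "betasleep_degenerate_table_error")
})

test_that("two-way ANOVA reproduces hand-computed balanced sums of squares", {
  y <- c(1, 2, 3, 4, 5, 6, 2, 4, 6, 5, 7, 9)
  A <- rep(c("a1", "a2"), each = 6)
  B <- rep(rep(c("b1", "b2"), each = 3), 2)

  grand <- mean(y)
  ma <- tapply(y, A, mean); mb <- tapply(y, B, mean)
  mc <- tapply(y, interaction(A, B), mean)
  ss_a <- 6 * sum((ma - grand)^2)
  ss_b <- 6 * sum((mb - grand)^2)
  cellm <- ave(y, A, B)
  ss_ab <- sum((cellm - ave(y, A) - ave(y, B) + grand)^2)
  ss_e <- sum((y - cellm)^2)
  f_hand <- c(ss_a / 1, ss_b / 1, ss_ab / 1) / (ss_e / 8)

  tab <- two_way_anova(y, A, B)
  expect_equal(tab$F, f_hand, tolerance = 1e-10)
  expect_equal(tab$df1, c(1, 1, 1))
  expect_equal(tab$df2, rep(8, 3))

  # balanced designs: Type II coincides with sequential (Type I) sums
  seq_tab <- anova(lm(y ~ a * b, data = data.frame(y = y, a = A, b = B)))
  expect_equal(tab$F, seq_tab$`F value`[1:3], tolerance = 1e-10)

  # no variance: all F are zero
  zero <- two_way_anova(rep(4, 12), A, B)
  expect_equal(zero$F, rep(0, 3))
  expect_equal(zero$p, rep(1, 3))
})

test_that("unbalanced ANOVA equals the nested-model RSS comparison", {
  withr::with_seed(14, {
    A <- sample(c("g1", "g2"), 40, replace = TRUE, prob = c(0.6, 0.4))
    B <- sample(c("s1", "s2", "s3"), 40, replace = TRUE)
    y <- rnorm(40) + (A == "g2") * 0.8 + (B == "s3") * 0.5
  })
  dat <- data.frame(y, A = factor(A), B = factor(B))
  rss <- function(f) sum(stats::resid(lm(f, data = dat))^2)
  full <- rss(y ~ A * B)
  df2 <- nrow(dat) - nlevels(dat$A) * nlevels(dat$B)
  ss <- c(A = rss(y ~ B) - rss(y ~ A + B),
          B = rss(y ~ A) - rss(y ~ A + B),
          AB = rss(y ~ A + B) - full)
  df1 <- c(1, 2, 2)
  f_ref <- (ss / df1) / (full / df2)
  p_ref <- stats::pf(f_ref, df1, df2, lower.tail = FALSE)

  tab <- two_way_anova(dat$y, dat$A, dat$B)
  expect_equal(tab$F, unname(f_ref), tolerance = 1e-8)
  expect_equal(tab$p, unname(p_ref), tolerance = 1e-8)
  expect_equal(tab$df1, df1, ignore_attr = TRUE)
  expect_equal(tab$df2, rep(df2, 3))
})

test_that("degenerate ANOVA designs are rejected", {
  expect_error(two_way_anova(1:6, rep("a", 6), rep(c("x", "y"), 3)),
               class = "betasleep_design_error")
  expect_error(
    two_way_anova(1:6, c("a", "a", "a", "b", "b", "b"),
                  c("x", "x", "y", "x", "x", "x")),  # empty cell b:y
    class = "betasleep_design_error")
})
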