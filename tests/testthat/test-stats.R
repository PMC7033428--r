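test_that("an exact line is recovered immediately", {
  x <- seq(0, 100, by = 5)
  fit <- huber_rlm(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-8)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_true(all(fit$weights > 0 & fit$weights <= 1))
})

test_that("on clean data the robust fit matches OLS", {
  # bounded noise that never leaves the quadratic region of the Huber
  # loss: the IRLS fixed point is exactly the least-squares solution
  set.seed(70)
  x <- runif(60, 0, 7200)
  y <- 0.6 + 1e-5 * x + 0.05 * sin(1:60)
  fit <- huber_rlm(x, y)
  ols <- coef(lm(y ~ x))
  expect_equal(fit$slope, unname(ols[2]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-6)
  expect_true(all(fit$weights == 1))
  # with the Huber threshold at infinity, exactly OLS on any data
  set.seed(71)
  y2 <- 0.6 + 1e-5 * x + rnorm(60, sd = 0.05)
  fit_inf <- huber_rlm(x, y2, tuning_c = Inf)
  ols2 <- coef(lm(y2 ~ x))
  expect_equal(fit_inf$slope, unname(ols2[2]), tolerance = 1e-8)
  expect_equal(fit_inf$intercept, unname(ols2[1]), tolerance = 1e-8)
})

test_that("a gross outlier is downweighted and the slope protected", {
  set.seed(72)
  x <- seq(1, 100)
  y <- 0.5 + 0.01 * x + rnorm(100, sd = 0.1)
  y[50] <- 30 # gross outlier
  rob <- huber_rlm(x, y)
  ols <- coef(lm(y ~ x))
  expect_lt(rob$weights[50], 1)
  expect_lt(min(rob$weights), 0.05)
  expect_lt(abs(rob$slope - 0.01), abs(unname(ols[2]) - 0.01))
})

test_that("the IRLS solution agrees with an established robust fitter", {
  set.seed(73)
  x <- runif(80, 0, 100)
  y <- 1 + 0.05 * x + rnorm(80, sd = 0.5)
  y[c(10, 40)] <- y[c(10, 40)] + 20
  fit <- huber_rlm(x, y)
  mass <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345,
                    scale.est = "MAD", maxit = 100)
  expect_equal(fit$slope, unname(coef(mass)[2]), tolerance = 1e-3)
  expect_equal(fit$intercept, unname(coef(mass)[1]), tolerance = 1e-2)
})

test_that("trend fitting rejects degenerate inputs", {
  expect_error(huber_rlm(rep(1, 10), rnorm(10)), "constant")
  expect_error(huber_rlm(1:2, c(1, 2)), "at least 3")
})

test_that("delay summaries report order statistics and the robust trend", {
  ev <- event_table(c(10, 20, 30), c(10.4, 20.5, 30.6))
  s <- summarize_delays(ev)
  expect_equal(s$min_s, 0.4)
  expect_equal(s$median_s, 0.5)
  expect_equal(s$max_s, 0.6)
  expect_equal(s$n_epochs, 3)
  expect_equal(s$sd_s, sd(c(0.4, 0.5, 0.6)))

  # constant delays: zero sd and zero slope
  ev2 <- event_table(c(10, 20, 30), c(10.5, 20.5, 30.5))
  s2 <- summarize_delays(ev2)
  expect_equal(s2$sd_s, 0)
  expect_equal(s2$slope_s_per_s, 0)
})

test_that("a planted slow drift in delay is recovered", {
  slopes <- vapply(1:50, function(s) {
    set.seed(700 + s)
    x <- sort(runif(48, 0, 7200))
    y <- 0.55 + 1e-5 * x + rnorm(48, sd = 0.05)
    huber_rlm(x, y)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1e-5), 0.2e-5)
})

test_that("one-way ANOVA matches explicit sum-of-squares arithmetic", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  res <- anova_oneway(groups)
  # brute-force sums of squares
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                           numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  F_hand <- (ss_between / 2) / (ss_within / 6)
  expect_equal(res$F, F_hand, tolerance = 1e-9)
  expect_equal(res$p, pf(F_hand, 2, 6, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
})

test_that("with two groups the ANOVA F equals the squared pooled t", {
  set.seed(74)
  a <- rnorm(15)
  b <- rnorm(20, mean = 0.3)
  res <- anova_oneway(list(a = a, b = b))
  t_pooled <- t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(res$F, unname(t_pooled)^2, tolerance = 1e-9)
})

test_that("ANOVA is invariant to shift and scale of the observations", {
  set.seed(75)
  groups <- list(a = rnorm(10), b = rnorm(12, 0.5), c = rnorm(9, 1))
  f0 <- anova_oneway(groups)$F
  expect_equal(anova_oneway(lapply(groups, function(g) g + 5))$F, f0,
               tolerance = 1e-9)
  expect_equal(anova_oneway(lapply(groups, function(g) 3 * g))$F, f0,
               tolerance = 1e-9)
  # identical groups: F = 0, p = 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- anova_oneway(same)
  expect_equal(res$F, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  expect_error(anova_oneway(list(a = c(1, 1), b = c(2, 2))), "undefined")
  expect_error(anova_oneway(list(a = c(1, 2))), "2 groups")
})

test_that("pairwise t-tests match the direct formula on a hand fixture", {
  a <- c(1, 2, 3, 4)
  b <- c(3, 4, 5, 6)
  P <- pairwise_ttests(list(a = a, b = b))
  # equal sizes and equal variances: Welch reduces to the pooled test
  sp2 <- (var(a) + var(b)) / 2
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(-abs(t_hand), df = 6)
  expect_equal(P["a", "b"], p_hand, tolerance = 1e-9)
  expect_equal(P["b", "a"], P["a", "b"])
  expect_true(is.na(P["a", "a"]))
})

test_that("paired mode handles matched and degenerate samples", {
  a <- c(1, 2, 3, 4)
  P <- pairwise_ttests(list(a = a, b = a), paired = TRUE)
  expect_equal(P["a", "b"], 1) # all differences zero -> p = 1 by convention
  expect_error(pairwise_ttests(list(a = a, b = c(1, 2)), paired = TRUE),
               "equal group lengths")
  set.seed(76)
  x <- rnorm(20); y <- x + rnorm(20, 0.5, 0.1)
  P2 <- pairwise_ttests(list(x = x, y = y), paired = TRUE)
  expect_equal(P2["x", "y"], t.test(x, y, paired = TRUE)$p.value)
})

test_that("a Holm correction can be applied to the p-value table", {
  set.seed(77)
  groups <- list(a = rnorm(10), b = rnorm(10, 2), c = rnorm(10, 4))
  raw <- pairwise_ttests(groups)
  adj <- pairwise_ttests(groups, p_adjust = "holm")
  up <- upper.tri(raw)
  expect_equal(adj[up], p.adjust(raw[up], "holm"))
})

test_that("the null t-test rejects at the nominal 5% rate", {
  set.seed(78)
  rejections <- vapply(1:500, function(i) {
    a <- rnorm(200); b <- rnorm(200)
    pairwise_ttests(list(a = a, b = b))["a", "b"] < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})
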