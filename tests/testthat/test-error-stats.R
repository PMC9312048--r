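test_that("bias is signed observed-minus-expected; inaccuracy its magnitude", {
  expect_equal(compute_error(90, 90), list(bias = 0, inaccuracy = 0))
  expect_equal(compute_error(92.5, 90), list(bias = 2.5, inaccuracy = 2.5))
  expect_equal(compute_error(88, 90), list(bias = -2, inaccuracy = 2))
  # vectorized, and inaccuracy = |bias| always
  set.seed(2)
  obs <- rnorm(100); expd <- rnorm(100)
  e <- compute_error(obs, expd)
  expect_equal(e$inaccuracy, abs(e$bias))
  expect_error(compute_error(NA_real_, 1), class = "tdm_config_error")
})

test_that("cube-root transform is signed, monotone and sign-preserving", {
  expect_equal(cube_root_transform(0), 0)
  expect_equal(cube_root_transform(1), 1)
  expect_equal(cube_root_transform(-8), -2)
  expect_equal(cube_root_transform(27), 3)
  set.seed(5)
  x <- sort(rnorm(500, sd = 10))
  y <- cube_root_transform(x)
  expect_true(all(diff(y) >= 0))
  expect_equal(sign(y), sign(x))
})

test_that("extreme-outlier filter applies 3xIQR fences with interpolated quartiles", {
  # hand quartiles for {1,2,3,4,100}: Q1 = 2, Q3 = 4, IQR = 2, fence 10
  r <- remove_extreme_outliers(c(1, 2, 3, 4, 100))
  expect_equal(r$removed, 100)
  expect_equal(r$kept, c(1, 2, 3, 4))
  expect_equal(unname(r$fences), c(-4, 10))
  # constant data: IQR 0, fences collapse onto the constant, nothing removed
  expect_length(remove_extreme_outliers(rep(7, 10))$removed, 0)
  # data inside the fences: identity
  x <- c(10, 11, 12, 13, 14)
  expect_equal(remove_extreme_outliers(x)$kept, x)
  # idempotence: filtering twice equals filtering once
  set.seed(9)
  y <- c(rnorm(50), 40, -35)
  once <- remove_extreme_outliers(y)$kept
  expect_equal(remove_extreme_outliers(once)$kept, once)
  expect_error(remove_extreme_outliers(c(1, 2, 3)), class = "tdm_data_error")
})

test_that("grouped summaries report n, mean and n-1 sd per group", {
  d <- data.frame(mode = c("a", "a", "a", "b"),
                  round = c(1, 1, 1, 1),
                  v = c(1, 2, 3, 10))
  s <- summarize_errors(d, "v", "mode")
  expect_equal(s$n, c(3L, 1L))
  expect_equal(s$mean, c(2, 10))
  expect_equal(s$sd, c(1, NA))  # sd({1,2,3}) = 1 by hand; singleton NA
  # grouping a simulated study by mode gives exactly three rows
  study <- simulate_study(n_images = 2, seed = 4)
  s3 <- summarize_errors(study$records, "inaccuracy_length", "mode")
  expect_identical(nrow(s3), 3L)
  expect_error(summarize_errors(d, "nope", "mode"), class = "tdm_config_error")
})

test_that("one-way repeated-measures F equals the squared paired t", {
  set.seed(31)
  n <- 12
  y1 <- rnorm(n); y2 <- rnorm(n, mean = 0.4)
  a <- rm_anova(c(y1, y2), subject = rep(1:n, 2), f1 = rep(c("A", "B"), each = n))
  tt <- t.test(y1, y2, paired = TRUE)
  expect_equal(a$F[a$effect == "factor1"], unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p[a$effect == "factor1"], tt$p.value, tolerance = 1e-9)
  expect_equal(a$df1[a$effect == "factor1"], 1)
  expect_equal(a$df2[a$effect == "factor1"], n - 1)
})

test_that("two-way repeated-measures F matches a brute-force SS decomposition", {
  set.seed(17)
  ns <- 8; na <- 3; nb <- 2
  d <- expand.grid(subject = 1:ns, A = 1:na, B = 1:nb)
  d$y <- rnorm(nrow(d)) + 0.5 * d$A + 0.3 * d$A * d$B
  fit <- rm_anova(d$y, d$subject, d$A, d$B)

  # independent oracle: cell-mean sums of squares from first principles
  gm <- mean(d$y)
  mA <- tapply(d$y, d$A, mean); mB <- tapply(d$y, d$B, mean)
  mS <- tapply(d$y, d$subject, mean)
  mAB <- tapply(d$y, list(d$A, d$B), mean)
  mAS <- tapply(d$y, list(d$A, d$subject), mean)
  mBS <- tapply(d$y, list(d$B, d$subject), mean)
  ssA <- ns * nb * sum((mA - gm)^2)
  ssB <- ns * na * sum((mB - gm)^2)
  ssAB <- ns * sum((mAB - rep(mA, nb) - rep(mB, each = na) + gm)^2)
  ssAS <- nb * sum(sweep(sweep(mAS, 1, mA), 2, mS - gm)^2)
  ssBS <- na * sum(sweep(sweep(mBS, 1, mB), 2, mS - gm)^2)
  sstot <- sum((d$y - gm)^2)
  ssS <- na * nb * sum((mS - gm)^2)
  ssABS <- sstot - ssA - ssB - ssAB - ssS - ssAS - ssBS

  FA <- (ssA / (na - 1)) / (ssAS / ((na - 1) * (ns - 1)))
  FB <- (ssB / (nb - 1)) / (ssBS / ((nb - 1) * (ns - 1)))
  FAB <- (ssAB / ((na - 1) * (nb - 1))) / (ssABS / ((na - 1) * (nb - 1) * (ns - 1)))
  expect_equal(fit$F[fit$effect == "factor1"], FA, tolerance = 1e-8)
  expect_equal(fit$F[fit$effect == "factor2"], FB, tolerance = 1e-8)
  expect_equal(fit$F[fit$effect == "factor1:factor2"], FAB, tolerance = 1e-8)
  expect_true(all(fit$F >= 0))

  # incomplete design is rejected
  expect_error(rm_anova(d$y[-1], d$subject[-1], d$A[-1], d$B[-1]),
               class = "tdm_data_error")
})

test_that("a condition-free effect yields F = 0 and the null F test is calibrated", {
  # values identical across conditions (varying only by subject): zero effect
  a0 <- rm_anova(rep(1:6, 2), subject = rep(1:6, 2), f1 = rep(c("A", "B"), each = 6))
  expect_equal(a0$F[a0$effect == "factor1"], 0)

  # null rejection rate at alpha = 0.05 over 1000 simulated designs
  set.seed(99)
  n_sim <- 1000
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    y <- rnorm(24)
    a <- rm_anova(y, subject = rep(1:8, 3), f1 = rep(1:3, each = 8))
    rej[i] <- a$p[a$effect == "factor1"] < 0.05
  }
  rate <- mean(rej)
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_gte(rate, 0.05 - 2 * se)
  expect_lte(rate, 0.05 + 2 * se)
})

test_that("Holm adjustment reproduces the step-down table and its guarantees", {
  expect_equal(pairwise_holm(0.2), 0.2)
  expect_equal(pairwise_holm(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(3)
  p <- runif(20)
  adj <- pairwise_holm(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(pairwise_holm(c(0.1, 1.2)), class = "tdm_config_error")
})
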