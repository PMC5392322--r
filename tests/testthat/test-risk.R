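test_that("logistic fitting matches closed forms and recovers truth", {
  set.seed(1)
  y <- rbinom(400, 1, 0.34)
  co <- data.frame(node_binary = y)
  m0 <- fit_logistic(co, character())
  expect_equal(m0$intercept, qlogis(mean(y)), tolerance = 1e-8)

  n <- 20000
  x1 <- rnorm(n); x2 <- rnorm(n)
  co2 <- data.frame(x1 = x1, x2 = x2,
                    node_binary = rbinom(n, 1, plogis(-0.5 + 1 * x1 -
                                                        0.5 * x2)))
  m <- fit_logistic(co2, c("x1", "x2"))
  expect_lt(abs(m$coefficients["x1"] - 1.0), 0.06)
  expect_lt(abs(m$coefficients["x2"] + 0.5), 0.06)
  # covariance is symmetric positive definite
  expect_equal(m$vcov, t(m$vcov))
  expect_true(all(eigen(m$vcov)$values > 0))
})

test_that("logistic fitting rejects degenerate designs", {
  co <- data.frame(x = rnorm(50), node_binary = rep(1, 50))
  expect_error(fit_logistic(co, "x"), "single class")
  co2 <- data.frame(x = rep(2, 50),
                    node_binary = rbinom(50, 1, 0.5))
  expect_error(fit_logistic(co2, "x"), "constant")
  expect_error(fit_logistic(data.frame(node_binary = c(0, 1)), character()),
               "10 patients")
  # complete separation is reported, not silently returned
  co3 <- data.frame(x = c(rep(0, 25), rep(1, 25)),
                    node_binary = c(rep(0, 25), rep(1, 25)))
  expect_error(suppressWarnings(fit_logistic(co3, "x")), "separation")
})

test_that("forward selection enters at the LR threshold deterministically", {
  set.seed(7)
  n <- 300
  x <- rnorm(n)
  co <- data.frame(x = x, node_binary = rbinom(n, 1, plogis(0.25 * x)))
  # exact LR p-value of the single candidate
  d0 <- glm(node_binary ~ 1, binomial, co)$deviance
  d1 <- glm(node_binary ~ x, binomial, co)$deviance
  p <- pchisq(d0 - d1, 1, lower.tail = FALSE)
  sel_in <- forward_select(co, "x", entry_p = p + 1e-9)
  sel_out <- forward_select(co, "x", entry_p = p - 1e-9)
  expect_identical(sel_in$variables, "x")
  expect_identical(sel_out$variables, character())
})

test_that("forward selection finds signal and resists noise", {
  set.seed(21)
  hits <- 0; noise_in <- 0; null_empty <- 0
  n_rep <- 40
  for (r in 1:n_rep) {
    n <- 600
    co <- data.frame(s = rnorm(n), matrix(rnorm(n * 5), n,
                                          dimnames = list(NULL,
                                                          paste0("z", 1:5))))
    co$node_binary <- rbinom(n, 1, plogis(1.5 * co$s))
    m <- forward_select(co, c(paste0("z", 1:5), "s"))
    hits <- hits + ("s" %in% m$variables)
    noise_in <- noise_in + sum(grepl("^z", m$variables))
    # all-noise candidates stay out most of the time
    m0 <- forward_select(co, paste0("z", 1:3))
    null_empty <- null_empty + (length(m0$variables) == 0)
  }
  expect_equal(hits, n_rep)
  expect_lte(noise_in / n_rep, 0.05 * 5 * 2.5)  # generous familywise bound
  expect_gte(null_empty / n_rep, 0.80)
})

test_that("AUC equals the pair-counting oracle and honors invariances", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1.0)
  set.seed(3)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)  # coarse: force ties
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(labels, scores)$auc, mean(pairs))
    # invariance under a strictly monotone transform
    expect_equal(roc_auc(labels, exp(2 * scores))$auc, mean(pairs))
  }
  set.seed(4)
  null <- roc_auc(rbinom(10000, 1, 0.4), rnorm(10000))
  expect_lt(abs(null$auc - 0.5), 0.02)
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("DeLong intervals bracket the AUC", {
  set.seed(5)
  co <- cohort_with_target_auc(500, 0.8, seed = 5)
  r <- roc_auc(co$node_binary, co$score)
  expect_lte(r$ci_low, r$auc)
  expect_gte(r$ci_high, r$auc)
  expect_gt(r$ci_high - r$ci_low, 0)
})

test_that("cross-validation recovers generative truth and is reproducible", {
  co <- cohort_with_target_auc(5000, 0.83, seed = 10)
  cv1 <- cross_validated_auc(co, "score", k = 10, seed = 2)
  expect_lt(abs(cv1$auc - 0.83), 0.03)
  cv2 <- cross_validated_auc(co, "score", k = 10, seed = 2)
  expect_identical(cv1$auc, cv2$auc)
  expect_identical(attr(cv1, "folds"), attr(cv2, "folds"))
  expect_error(cross_validated_auc(co[1:30, ], "score", k = 25),
               "smaller k")
})

test_that("cross-validation exposes the optimism of apparent AUC", {
  set.seed(33)
  n <- 1000
  co <- data.frame(matrix(rnorm(n * 20), n,
                          dimnames = list(NULL, paste0("z", 1:20))))
  co$node_binary <- rbinom(n, 1, 0.4)
  vars <- paste0("z", 1:20)
  m <- fit_logistic(co, vars)
  apparent <- roc_auc(co$node_binary, predict(m))$auc
  cv <- cross_validated_auc(co, vars, k = 10, seed = 1)$auc
  expect_lt(abs(cv - 0.5), 0.05)
  expect_gt(apparent, cv)
})

test_that("Hosmer-Lemeshow detects miscalibration and passes calibrated fits", {
  set.seed(8)
  n <- 10000
  x <- rnorm(n)
  p_true <- plogis(-0.5 + x)
  y <- rbinom(n, 1, p_true)
  fit <- glm(y ~ x, binomial)
  hl_ok <- hosmer_lemeshow(y, fitted(fit))
  expect_equal(unname(hl_ok$parameter), 8)
  # a +1 logit shift is overwhelmingly rejected
  hl_bad <- hosmer_lemeshow(y, plogis(qlogis(p_true) + 1))
  expect_lt(hl_bad$p.value, 0.001)
  # balanced coin-flip outcome at constant 0.5: chi2 near zero
  set.seed(9)
  yy <- sample(rep(0:1, 500))
  hl_const <- suppressWarnings(hosmer_lemeshow(yy, rep(0.5, 1000)))
  expect_lt(unname(hl_const$statistic), 1e-10)
  expect_error(hosmer_lemeshow(yy, rep(0.5, 1000), g = 2), "at least 3")
})

test_that("calibration curves are faithful for calibrated predictions", {
  set.seed(12)
  n <- 10000
  p <- plogis(rnorm(n, -0.7, 1.2))
  y <- rbinom(n, 1, p)
  cc <- calibration_curve(y, p)
  expect_equal(nrow(cc), 10)
  sl <- coef(lm(observed_fraction ~ mean_predicted, cc))[2]
  expect_gt(sl, 0.9); expect_lt(sl, 1.1)
  expect_true(all(cc$ci_low <= cc$observed_fraction &
                    cc$observed_fraction <= cc$ci_high))
  # constant predictions collapse to one bin; empty input returns no rows
  expect_equal(nrow(calibration_curve(y, rep(0.3, n))), 1)
  expect_equal(nrow(calibration_curve(integer(), numeric())), 0)
})
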