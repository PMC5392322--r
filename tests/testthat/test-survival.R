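test_that("tertile assignment cuts at interpolated terciles with shared ties", {
  expect_identical(assign_tertiles(1:9), rep(1:3, each = 3L))
  # tied values straddling a cut share a tertile
  v <- c(1, 2, 5, 5, 5, 5, 8, 9, 10)
  t5 <- unique(assign_tertiles(v)[v == 5])
  expect_length(t5, 1)
  expect_error(assign_tertiles(c(1, 1, 2)), "3 distinct")
  # group sizes near n/3 for continuous data
  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(300)
    expect_true(all(abs(table(assign_tertiles(x)) - 100) <= 1))
  }
})

test_that("Kaplan-Meier matches the empirical and hand-computed estimates", {
  # no censoring: curve is 1 - ECDF at event times
  t <- c(1, 2, 3, 4, 5)
  km <- kaplan_meier(t, rep(1, 5))
  expect_equal(km$curves$surv, 1 - (1:5) / 5)
  # all censored: flat at 1
  km2 <- kaplan_meier(t, rep(0, 5))
  expect_true(all(km2$curves$surv == 1))
  # mixed six-patient set against the hand-worked product-limit table
  km3 <- kaplan_meier(c(1, 2, 2, 3, 4, 5), c(1, 0, 1, 1, 0, 1))
  ev <- km3$curves[km3$curves$n_event > 0, ]
  expect_equal(ev$surv, c(5 / 6, 5 / 6 * 4 / 5, 5 / 6 * 4 / 5 * 2 / 3, 0),
               tolerance = 1e-12)
  # at-risk counts at the landmark times
  expect_equal(km3$at_risk$n_risk[km3$at_risk$time == 0], 6)
  expect_equal(km3$at_risk$n_risk[km3$at_risk$time == 3], 3)
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("log-rank is exact under duplication and errors on degenerate input", {
  set.seed(16)
  t <- rexp(40); e <- rbinom(40, 1, 0.7)
  dup <- logrank(c(t, t), c(e, e), rep(c("a", "b"), each = 40))
  expect_lt(dup$chi2, 1e-10)
  expect_equal(dup$df, 1)
  expect_error(logrank(t, e, rep("a", 40)), "2 groups")
  expect_error(logrank(t, rep(0, 40), rep(c("a", "b"), 20)), "one event")
})

test_that("log-rank has power against a strong two-group hazard contrast", {
  set.seed(17)
  rejected <- 0
  for (r in 1:40) {
    g <- rep(0:1, each = 150)
    t <- rexp(300, rate = 0.1 * 3^g)
    cens <- runif(300, 0, 15)
    lr <- logrank(pmin(t, cens), as.integer(t <= cens), g)
    rejected <- rejected + (lr$p < 0.01)
  }
  expect_gte(rejected / 40, 0.95)
})

test_that("Cox fits recover simulated hazard ratios", {
  set.seed(18)
  n <- 10000
  x <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.1 * 2^x)
  cens <- runif(n, 0, 12)
  co <- data.frame(x = x, os_time = pmin(t, cens),
                   os_event = as.integer(t <= cens))
  fit <- cox_fit(co, "x")
  expect_gt(fit$terms$hr[1], 1.9); expect_lt(fit$terms$hr[1], 2.1)
  expect_true(fit$terms$ci_low[1] < fit$terms$hr[1])
  expect_true(fit$terms$ci_high[1] > fit$terms$hr[1])
  # null covariate
  co$z <- rnorm(n)
  fz <- cox_fit(co, "z")
  expect_gt(fz$terms$hr[1], 0.95); expect_lt(fz$terms$hr[1], 1.05)
})

test_that("Efron tie handling matches a grid-maximized partial likelihood", {
  # five patients, one tied death time
  tt <- c(1, 1, 2, 3, 4); ee <- c(1, 1, 1, 0, 1); x <- c(2, 0, 1, 1, 0)
  co <- data.frame(x = x, os_time = tt, os_event = ee)
  efron_ll <- function(beta) {
    eta <- exp(beta * x)
    ll <- 0
    for (ut in unique(tt[ee == 1])) {
      risk <- tt >= ut
      died <- tt == ut & ee == 1
      d <- sum(died)
      ll <- ll + sum(beta * x[died])
      for (l in seq_len(d) - 1)
        ll <- ll - log(sum(eta[risk]) - l / d * sum(eta[died]))
    }
    ll
  }
  grid <- seq(-4, 4, by = 1e-3)
  beta_star <- grid[which.max(vapply(grid, efron_ll, 0))]
  fit <- cox_fit(co, "x", ties = "efron")
  expect_equal(unname(log(fit$terms$hr[1])), beta_star, tolerance = 2e-3)
  # Breslow differs on tied data, and is exposed as an option
  fb <- cox_fit(co, "x", ties = "breslow")
  expect_false(isTRUE(all.equal(fb$terms$hr[1], fit$terms$hr[1])))
})

test_that("Cox log-HR is equivariant under covariate scaling", {
  set.seed(19)
  n <- 500
  co <- data.frame(x = rnorm(n))
  t <- rexp(n, 0.1 * exp(0.5 * co$x))
  co$os_time <- pmin(t, 8); co$os_event <- as.integer(t <= 8)
  b1 <- log(cox_fit(co, "x")$terms$hr[1])
  co$x <- co$x / 10
  b2 <- log(cox_fit(co, "x")$terms$hr[1])
  expect_equal(b2, 10 * b1, tolerance = 1e-6)
})

test_that("conditional forward elimination keeps signal and drops noise", {
  set.seed(20)
  both <- 0; null_empty <- 0
  n_rep <- 25
  for (r in 1:n_rep) {
    n <- 700
    co <- data.frame(a = rnorm(n), b = rnorm(n),
                     z1 = rnorm(n), z2 = rnorm(n), z3 = rnorm(n))
    t <- rexp(n, 0.08 * exp(0.7 * co$a + 0.7 * co$b))
    cens <- runif(n, 0, 20)
    co$os_time <- pmin(t, cens); co$os_event <- as.integer(t <= cens)
    m <- cox_forward(co, c("z1", "a", "z2", "b", "z3"))
    both <- both + all(c("a", "b") %in% m$variables)
    m0 <- cox_forward(co, c("z1", "z2", "z3"))
    null_empty <- null_empty + (length(m0$variables) == 0)
  }
  expect_gte(both / n_rep, 0.90)
  expect_gte(null_empty / n_rep, 0.80)
})

test_that("forward elimination entry boundary follows the LR p-value", {
  set.seed(22)
  n <- 400
  co <- data.frame(x = rnorm(n))
  t <- rexp(n, 0.1 * exp(0.15 * co$x))
  co$os_time <- pmin(t, 10); co$os_event <- as.integer(t <= 10)
  ll0 <- survival::coxph(survival::Surv(os_time, os_event) ~ 1,
                         data = co)$loglik[1]
  ll1 <- survival::coxph(survival::Surv(os_time, os_event) ~ x,
                         data = co)$loglik[2]
  p <- pchisq(2 * (ll1 - ll0), 1, lower.tail = FALSE)
  expect_identical(cox_forward(co, "x", entry_p = p + 1e-9)$variables, "x")
  expect_length(cox_forward(co, "x", entry_p = p - 1e-9)$variables, 0)
})

test_that("selection is invariant to candidate order with distinct p-values", {
  set.seed(23)
  n <- 800
  co <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  t <- rexp(n, 0.08 * exp(0.6 * co$a + 0.3 * co$b))
  co$os_time <- pmin(t, 15); co$os_event <- as.integer(t <= 15)
  m1 <- cox_forward(co, c("a", "b", "c"))
  m2 <- cox_forward(co, c("c", "b", "a"))
  expect_setequal(m1$variables, m2$variables)
})

test_that("bud-size sweep recovers a small-island-only hazard signal", {
  set.seed(24)
  n <- 2000
  # per-patient region tables: hazard rides only on the small-island count
  small <- rnbinom(n, mu = 6, size = 2)
  big <- rnbinom(n, mu = 6, size = 2)
  tables <- lapply(seq_len(n), function(i) {
    areas <- c(runif(small[i], 200, 900), runif(big[i], 2000, 3500))
    labeled_regions_from_areas(if (length(areas)) areas else 2000)
  })
  names(tables) <- sprintf("pt_%04d", seq_len(n))
  sw <- sweep_bud_definitions(tables, n_range = c(2, 5, 8, 12, 16, 20))
  t_ev <- rexp(n, 0.05 * exp(0.25 * scale(small)))
  cohort <- data.frame(id = names(tables),
                       os_time = pmin(t_ev, 10),
                       os_event = as.integer(t_ev <= 10))
  res <- suppressWarnings(budsize_prognosis_sweep(sw, cohort))
  ok <- !res$per_n$skipped
  expect_gte(sum(ok), 4)
  # prognostic value decays as big islands dilute the count
  expect_lt(res$trend$slope, 0)
  expect_lt(res$trend$p, 0.05)
  # HR per tertile at small definitions exceeds that at large ones
  hr <- res$per_n$hr_per_tertile
  expect_gt(hr[ok][1], hr[ok][sum(ok)])
})

test_that("sweep rows degrade gracefully for degenerate definitions", {
  set.seed(25)
  tables <- lapply(1:60, function(i)
    labeled_regions_from_areas(runif(3, 2000, 3800)))
  names(tables) <- paste0("p", 1:60)
  sw <- sweep_bud_definitions(tables, n_range = c(1, 15))
  co <- data.frame(id = names(tables), os_time = rexp(60),
                   os_event = rbinom(60, 1, 0.5))
  # n = 1: every count is zero -> tertiles impossible -> flagged, skipped
  res <- suppressWarnings(budsize_prognosis_sweep(sw, co))
  expect_true(res$per_n$skipped[res$per_n$n_cells == 1])
  expect_warning(budsize_prognosis_sweep(sw, co), "tertiles")
  # a single usable definition yields a row but no trend
  sw15 <- sweep_bud_definitions(tables, n_range = 15)
  res2 <- suppressWarnings(budsize_prognosis_sweep(sw15, co))
  expect_equal(nrow(res2$per_n), 1)
  expect_null(res2$trend)
})
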