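sim_logistic_choices <- function(w0, wG, wL, n = 256, seed = 1,
                                 spec = group_design_spec("narrow", seed = seed)) {
  d <- gen_group_design(spec)[seq_len(n), ]
  p <- plogis(w0 + wG * d$gain - wL * d$loss)
  withr::with_seed(seed + 500, dplyr::mutate(d, accept = rbinom(n, 1, p)))
}

test_that("the choice logistic recovers known generating weights", {
  truth <- c(w0 = 0, wG = 0.2, wL = 0.3)
  hits <- vapply(1:20, function(s) {
    d <- sim_logistic_choices(0, 0.2, 0.3, seed = s)
    fit <- fit_choice_logistic(d)
    se <- sqrt(diag(fit$vcov))
    all(abs(fit$coefficients - truth) <= 2 * se)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("missing responses are dropped and small samples refused", {
  d <- sim_logistic_choices(0, 0.2, 0.3, seed = 2)
  d$accept[1:20] <- NA
  fit <- fit_choice_logistic(d)
  expect_equal(fit$nobs, 236)
  expect_error(fit_choice_logistic(d[1:12, ]), "usable trials")
})

test_that("degenerate and separable choice data fall back to the ridge prior", {
  d <- sim_logistic_choices(0, 0.2, 0.3, seed = 3)
  d_all <- dplyr::mutate(d, accept = 1)
  fit_all <- fit_choice_logistic(d_all)
  expect_true(fit_all$degenerate)
  expect_true(fit_all$ridged)

  # deterministic sign(EV) chooser: separable; ridge keeps wG ~ wL, lambda ~ 0
  d_det <- dplyr::mutate(d, accept = as.integer(ev > 0))
  fit_det <- fit_choice_logistic(d_det)
  expect_true(fit_det$ridged)
  expect_lt(abs(fit_det$lambda), 0.15)
})

test_that("the loss-aversion index is a log sensitivity ratio, temperature-invariant", {
  fit <- fit_choice_logistic(sim_logistic_choices(0.1, 0.25, 0.5, seed = 4))
  expect_equal(fit$lambda, log(fit$coefficients["wL"] / fit$coefficients["wG"]),
               ignore_attr = TRUE)
  # exact identities on planted coefficients
  f2 <- fit
  f2$coefficients <- c(w0 = 0, wG = 0.2, wL = 0.4)
  f2$lambda <- log(2)
  expect_equal(loss_aversion_index(f2), log(2))
  # scaling all coefficients by a positive temperature leaves lambda unchanged
  f3 <- f2
  f3$coefficients <- 3.7 * f2$coefficients
  f3$lambda <- unname(log(f3$coefficients["wL"] / f3$coefficients["wG"]))
  expect_equal(loss_aversion_index(f3), loss_aversion_index(f2))
  # behaviorally: agents differing only in temperature give matching lambda
  lam <- vapply(1:8, function(s) {
    c(fit_choice_logistic(sim_logistic_choices(0, 0.2, 0.3, seed = s))$lambda,
      fit_choice_logistic(sim_logistic_choices(0, 0.4, 0.6, seed = s + 100))$lambda)
  }, numeric(2))
  expect_lt(abs(mean(lam[1, ]) - mean(lam[2, ])), 0.1)
  # non-positive sensitivity: flagged missing
  f4 <- f2; f4$coefficients["wG"] <- 0; f4$lambda <- NA_real_
  f4$lambda_reason <- "non-positive sensitivity"
  expect_true(is.na(loss_aversion_index(f4)))
})

test_that("balanced accuracy matches its confusion-matrix definition", {
  expect_equal(balanced_accuracy(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 100)
  # TP=3 FN=1 TN=2 FP=2 -> (0.75 + 0.5)/2 = 62.5
  p <- c(0.9, 0.9, 0.9, 0.1, 0.9, 0.9, 0.1, 0.1)
  g <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(balanced_accuracy(p, g), 62.5)
  # predictions independent of choices hover at chance
  withr::with_seed(9, {
    ba <- replicate(200, balanced_accuracy(runif(100), rbinom(100, 1, 0.5)))
    expect_lt(abs(mean(ba) - 50), 2)
  })
  # single observed class: flagged accuracy on the present class
  ba1 <- balanced_accuracy(c(0.9, 0.8), c(1, 1))
  expect_equal(as.numeric(ba1), 100)
  expect_true(attr(ba1, "one_class"))
})

test_that("sliding windows partition 256 trials into 16 fits", {
  d <- sim_logistic_choices(0, 0.3, 0.38, seed = 5)
  win <- sliding_window_loss_aversion(d)
  expect_equal(nrow(win), 16)
  expect_error(sliding_window_loss_aversion(d, window = 4), "unidentifiable")
  expect_warning(sliding_window_loss_aversion(d[1:250, ]), "dropped")
})

test_that("stationary agents show no window trend; programmed drift is detected", {
  # stationary: regression of lambda on window index is non-significant for
  # most subjects at alpha = .05
  withr::with_seed(31, {
    pvals <- vapply(1:25, function(s) {
      d <- sim_logistic_choices(0, 0.3, 0.4, seed = 1000 + s)
      win <- sliding_window_loss_aversion(d)
      ok <- is.finite(win$lambda)
      summary(lm(lambda ~ window, win[ok, ]))$coefficients[2, 4]
    }, numeric(1))
    expect_gt(mean(pvals > 0.05), 0.8)
  })
  # drifting agents: the cohort-mean window trend of the loss-aversion
  # series is positive in most replicate cohorts
  withr::with_seed(32, {
    det <- replicate(8, {
      slopes <- vapply(1:20, function(s) {
        spec <- group_design_spec("narrow", seed = sample.int(1e6, 1))
        ag <- drifting_logistic_agent(0, 0.3, 0.25, 0.41)
        ch <- simulate_choices(ag, gen_group_design(spec),
                               seed = sample.int(1e6, 1))
        win <- sliding_window_loss_aversion(ch)
        ok <- is.finite(win$lambda)
        unname(coef(lm(lambda ~ window, win[ok, ]))[2])
      }, numeric(1))
      mean(slopes, na.rm = TRUE) > 0
    })
    expect_gt(mean(det), 0.8)
  })
})

test_that("EV-decile curves behave on constructed agents", {
  d <- sim_logistic_choices(0, 0.3, 0.3, seed = 6)
  # always-accept: every decile at 100%
  curve1 <- ev_decile_curve(dplyr::mutate(d, accept = 1))
  expect_equal(curve1$accept_rate, rep(1, nrow(curve1)))
  # sigmoid(EV) agent: middle deciles near 50%, curve roughly monotone
  withr::with_seed(33, {
    d2 <- dplyr::mutate(d, accept = rbinom(dplyr::n(), 1, plogis(ev)))
  })
  curve2 <- ev_decile_curve(d2)
  mid <- curve2$accept_rate[which.min(abs(curve2$ev_mid))]
  expect_lt(abs(mid - 0.5), 0.2)
  iso <- isoreg(curve2$ev_mid, curve2$accept_rate)
  expect_lt(mean((iso$yf - curve2$accept_rate)^2), 0.01)
  # deterministic monotone agent: exactly non-decreasing
  curve3 <- ev_decile_curve(dplyr::mutate(d, accept = as.integer(ev > 1)))
  expect_true(all(diff(curve3$accept_rate) >= 0))
})

test_that("the group F test squares the pooled t statistic", {
  x <- c(1.2, 0.8, 1.1, 0.9); y <- c(0.4, 0.6, 0.2)
  ft <- group_f_test(x, y)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(ft$f, unname(tt$statistic)^2)
  expect_equal(ft$p, tt$p.value)
  expect_equal(ft$df2, 5L)
  # property over random inputs
  withr::with_seed(41, {
    for (i in 1:10) {
      a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1))
      expect_equal(group_f_test(a, b)$f,
                   unname(t.test(a, b, var.equal = TRUE)$statistic)^2)
    }
  })
  # identical groups: F = 0; the study's group sizes give dof 101
  expect_equal(group_f_test(c(1, 1, 1), c(1, 1))$zero_variance, TRUE)
  expect_equal(group_f_test(rnorm(54), rnorm(49))$df2, 101L)
})

test_that("the common-EV mask is the designs' range intersection", {
  narrow <- gen_group_design(group_design_spec("narrow"))
  wide <- gen_group_design(group_design_spec("wide"))
  expect_equal(range(narrow$ev), c(-7.5, 7.5))
  expect_equal(range(wide$ev), c(-5, 17.5))
  ev <- c(0, -7, 10, -5, 7.5)
  m <- common_ev_mask(ev, narrow, wide)
  expect_equal(m, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_error(common_ev_mask(ev, c(-2, -1), c(1, 2)), "intersect")
})

test_that("tidy and glance expose the logistic fit in broom style", {
  fit <- fit_choice_logistic(sim_logistic_choices(0, 0.25, 0.3, seed = 7))
  td <- tidy(fit)
  expect_setequal(td$term, c("w0", "wG", "wL"))
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 256)
  expect_gt(gl$balanced_accuracy, 60)
})
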