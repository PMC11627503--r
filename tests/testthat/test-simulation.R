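test_that("factorial designs cover every gain/loss combination equally often", {
  cond <- range_condition(1, 1, n_levels = 16)
  d <- make_factorial_design(cond, seed = 1)
  expect_equal(nrow(d), 256)
  expect_equal(nrow(dplyr::distinct(d, gain, loss)), 256)
  expect_equal(d$ev, (d$gain - d$loss) / 2)

  d2 <- make_factorial_design(range_condition(1, 1, n_levels = 2), seed = 1)
  expect_equal(nrow(d2), 4)
  expect_setequal(paste(d2$gain, d2$loss), c("0 0", "0 1", "1 0", "1 1"))

  # determinism: same seed, same order; different seed, same multiset
  da <- make_factorial_design(cond, seed = 7)
  db <- make_factorial_design(cond, seed = 7)
  dc <- make_factorial_design(cond, seed = 8)
  expect_identical(da, db)
  expect_false(identical(da$gain, dc$gain))
  expect_equal(dplyr::arrange(da, gain, loss)[, c("gain", "loss")],
               dplyr::arrange(dc, gain, loss)[, c("gain", "loss")])

  expect_error(range_condition(1, 1, n_trials = 100), "multiple")
  expect_error(range_condition(0.5, 0.5, gain_lo = 0.6), "lo < hi")
})

test_that("readout training reaches EV where it is exactly representable", {
  # one unit's response equals EV on the grid: minimum-norm puts weight 1 there
  cond <- range_condition(1, 1, n_levels = 4)
  grid <- tidyr::expand_grid(gain = seq(0, 1, length.out = 4),
                             loss = seq(0, 1, length.out = 4))
  # the minimum-norm contract, checked on planted features: the feature
  # equal to EV gets weight one, the rest zero
  Z <- withr::with_seed(4, rbind(runif(16), (grid$gain - grid$loss) / 2, runif(16)))
  sv <- svd(t(Z))
  w <- sv$v %*% (crossprod(sv$u, (grid$gain - grid$loss) / 2) / sv$d)
  expect_equal(drop(w), c(0, 1, 0), tolerance = 1e-8)

  # EV arithmetic: G=20, L=5 (dollar scale) targets 7.5
  expect_equal((20 - 5) / 2, 7.5)

  # random default-size networks fit EV well on the full grid
  r2 <- vapply(1:20, function(s) {
    n <- vs_network(seed = s)
    attr(train_readout_to_ev(n, condition_grid_for_test()), "readout_r2")
  }, numeric(1))
  expect_gt(mean(r2), 0.95)
})

test_that("run_condition is reproducible and degenerate under static plasticity", {
  cond <- range_condition(0.5, 0.5, n_levels = 4)
  r1 <- run_condition(cond, plasticity_params(), n_runs = 2, seed = 3)
  r2 <- run_condition(cond, plasticity_params(), n_runs = 2, seed = 3)
  expect_equal(r1[[1]]$Z, r2[[1]]$Z)
  expect_equal(r1[[2]]$net$C, r2[[2]]$net$C)

  rs <- run_condition(cond, plasticity_params(0, 0), n_runs = 2, seed = 3)
  expect_identical(rs[[1]]$Z, rs[[1]]$Z0)
  expect_identical(rs[[1]]$net$C, rs[[1]]$net0$C)
})

test_that("EV-binned curves recover affine constructions and sign classes", {
  cond <- range_condition(1, 1, n_levels = 8)
  grid <- condition_grid_for_test()[seq(1, 256, by = 4), ]
  ev <- (grid$gain - grid$loss) / 2
  up <- 0.2 + 0.6 * (ev - min(ev)) / diff(range(ev))
  down <- 0.9 - 0.5 * (ev - min(ev)) / diff(range(ev))
  Z <- rbind(up, down)
  curves <- ev_binned_unit_curves(Z, dplyr::mutate(grid, ev = ev), n_bins = 6)
  plus <- dplyr::filter(curves, class == "+EV")
  minus <- dplyr::filter(curves, class == "-EV")
  fit <- lm(response ~ ev_mid, plus)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_equal(unname(coef(fit)[2]), 0.6 / diff(range(ev)), tolerance = 0.05)
  expect_true(all(diff(minus$response) < 0))
  # constant units are excluded; an all-constant matrix errors
  expect_error(ev_binned_unit_curves(matrix(0.5, 2, nrow(grid)), grid), "constant")
  expect_error(ev_binned_unit_curves(Z, grid, n_bins = 1), "2 EV bins")
})

test_that("behavioral sensitivities read off exact linear value landscapes", {
  grid <- tidyr::expand_grid(gain = seq(0, 1, length.out = 8),
                             loss = seq(0, 1, length.out = 8))
  ev_net <- dplyr::mutate(grid, value = (gain - loss) / 2)
  s <- behavioral_sensitivities(ev_net)
  expect_equal(s$sens_gain, 0.5)
  expect_equal(s$sens_loss, 0.5)
  expect_equal(s$loss_aversion_ratio, 1)

  s3 <- behavioral_sensitivities(dplyr::mutate(grid, value = 0.2 * gain - 0.6 * loss))
  expect_equal(s3$loss_aversion_ratio, 3)

  s_bad <- behavioral_sensitivities(dplyr::mutate(grid, value = -0.1 * gain - 0.2 * loss))
  expect_true(is.na(s_bad$loss_aversion_ratio))
  expect_false(s_bad$ratio_ok)
})

test_that("value-cell classification labels constructed units correctly", {
  withr::with_seed(21, {
    n_t <- 200
    gv <- rnorm(n_t)                     # gamble (offer) value
    choice <- rbinom(n_t, 1, plogis(2 * gv))
    chosen <- gv * choice
    offer_unit <- 0.5 + 0.2 * gv / max(abs(gv))
    choice_unit <- 0.3 + 0.4 * choice + rnorm(n_t, sd = 0.02)
    noise_unit <- runif(n_t)
    Z <- rbind(offer_unit, choice_unit, noise_unit)
    cl <- classify_value_cells(Z, choice, gv, chosen)
    expect_true(cl$units$offer_value_cell[1])
    expect_true(cl$units$choice_cell[2])
    # constant unit is unclassified
    cl2 <- classify_value_cells(rbind(rep(0.5, n_t), offer_unit), choice, gv, chosen)
    expect_true(cl2$units$unclassified[1])
  })
  expect_error(classify_value_cells(matrix(runif(10), 1), rep(0:1, 5),
                                    rnorm(10)), "20 trials")
})

test_that("pure-noise units are flagged at the nominal false-positive rate", {
  withr::with_seed(22, {
    n_u <- 4000; n_t <- 60
    gv <- rnorm(n_t)
    choice <- rbinom(n_t, 1, 0.5)
    Z <- matrix(runif(n_u * n_t), n_u, n_t)
    cl <- classify_value_cells(Z, choice, gv)
    expect_lt(abs(cl$proportions$offer_value_cell - 0.05), 0.015)
    expect_lt(abs(cl$proportions$choice_cell - 0.05), 0.015)
  })
})

test_that("noise robustness has its exact limits and a coin-flip asymptote", {
  net <- train_readout_to_ev(vs_network(seed = 3),
                             condition_grid_for_test())
  d <- make_factorial_design(range_condition(1, 1, n_levels = 4), seed = 2)
  curve <- noise_robustness_curve(list(net = net), d, sds = c(0, 1000),
                                  n_reps = 400, seed = 1)
  expect_equal(curve$consistency[curve$sd == 0], 1)
  expect_lt(abs(curve$consistency[curve$sd == 1000] - 0.5), 0.05)
  expect_error(noise_robustness_curve(list(net = net), d, sds = -1), "non-negative")
})

test_that("the range-grid sweep summarizes its per-cell metrics coherently", {
  sw <- range_grid_sweep(c(0.5, 1), 0.5, plasticity_params(), n_runs = 4,
                         seed = 2, n_levels = 8)
  expect_equal(nrow(sw), 2)
  expect_true(all(c("enc_gain", "enc_loss", "enc_ev", "sens_gain",
                    "sens_loss", "loss_aversion_ratio") %in% names(sw)))
  expect_equal(sw$loss_aversion_ratio, sw$sens_loss / sw$sens_gain)
})
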