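test_that("session projection zeroes within-session means and is idempotent", {
  withr::with_seed(1, {
    Y <- matrix(rnorm(6 * 20), 6, 20)
    sess <- rep(1:2, each = 10)
    offsets <- matrix(rnorm(6 * 2, sd = 3), 6, 2)
    Yo <- Y + offsets[, sess]
    Yc <- project_out_sessions(Yo, sess)
    for (s in 1:2) expect_lt(max(abs(rowMeans(Yc[, sess == s]))), 1e-12)
    expect_equal(project_out_sessions(Yc, sess), Yc)
    # known offsets exactly removed, within-session structure intact
    Y0 <- Y - cbind(rowMeans(Y[, sess == 1]), rowMeans(Y[, sess == 2]))[, sess]
    expect_equal(Yc, Y0)
  })
  expect_warning(project_out_sessions(matrix(1:4, 2), c(1, 1)), "one session")
})

test_that("RDMs have their exact correlation-distance identities", {
  withr::with_seed(2, {
    Y <- matrix(rnorm(5 * 4), 5, 4)
    Y[, 2] <- Y[, 1]           # duplicate pattern: dissimilarity 0
    Y[, 3] <- -2 * Y[, 1] + 1  # negated (anticorrelated) pattern: dissimilarity 2
  })
  D <- compute_rdm(Y)
  expect_s3_class(D, "vs_rdm")
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 2)
  expect_equal(diag(unclass(D)), rep(0, 4))
  expect_equal(unclass(D), t(unclass(D)))
  expect_true(all(unclass(D) >= 0 & unclass(D) <= 2))

  # 3-trial, 3-unit brute-force correlation oracle
  Y2 <- withr::with_seed(3, matrix(rnorm(9), 3, 3))
  D2 <- compute_rdm(Y2)
  for (a in 1:3) for (b in 1:3) {
    want <- if (a == b) 0 else 1 - cor(Y2[, a], Y2[, b])
    expect_equal(D2[a, b], want, tolerance = 1e-12, ignore_attr = TRUE)
  }

  # constant column flagged missing
  Y3 <- withr::with_seed(4, matrix(rnorm(12), 3, 4)); Y3[, 2] <- 1
  D3 <- compute_rdm(Y3)
  expect_true(all(is.na(D3[2, -2])))
  expect_equal(attr(D3, "flagged_constant"), 2L, ignore_attr = TRUE)
  expect_error(compute_rdm(matrix(1:4, 1)), "2 units")
})

test_that("RDMs are invariant to affine transforms of trial patterns", {
  withr::with_seed(5, {
    Y <- matrix(rnorm(8 * 10), 8, 10)
    a <- runif(10, 0.5, 3)       # per-trial positive scalings
    b <- rnorm(10)               # per-trial offsets
    Yt <- sweep(sweep(Y, 2, a, `*`), 2, b, `+`)
    expect_equal(unclass(compute_rdm(Yt)), unclass(compute_rdm(Y)),
                 tolerance = 1e-10)
  })
})

test_that("delay detrending removes exactly the per-delay means", {
  withr::with_seed(6, {
    Y <- matrix(rnorm(6 * 30), 6, 30)
    D <- compute_rdm(Y)
    Dc <- delay_detrend(D)
    delay <- abs(outer(1:30, 1:30, `-`))
    for (d in 1:29) expect_lt(abs(mean(unclass(Dc)[delay == d])), 1e-12)
    # an RDM that is a pure function of delay corrects to all zeros
    Dpure <- structure(0.01 * delay, class = c("vs_rdm", "matrix"))
    expect_lt(max(abs(unclass(delay_detrend(Dpure)))), 1e-12)
  })
})

test_that("delay detrending preserves randomized attribute structure", {
  withr::with_seed(7, {
    n_t <- 200
    gains <- sample(rep(seq(0.1, 1, length.out = 8), length.out = n_t))
    losses <- sample(rep(seq(0.1, 1, length.out = 8), length.out = n_t))
    delay <- abs(outer(1:n_t, 1:n_t, `-`))
    D <- 0.05 * abs(outer(gains, gains, `-`)) + 0.02 * abs(outer(losses, losses, `-`)) +
      0.003 * delay + 0.1
    diag(D) <- 0
    D <- structure(D, class = c("vs_rdm", "matrix"))
    cor_slope <- attribute_encoding_strength(delay_detrend(D), gains, losses)
    g1 <- cor_slope$estimate[cor_slope$term == "gain_distance"]
    l1 <- cor_slope$estimate[cor_slope$term == "loss_distance"]
    expect_lt(abs(g1 - 0.05) / 0.05, 0.05)
    expect_lt(abs(l1 - 0.02) / 0.02, 0.05)
  })
})

test_that("encoding strengths recover exact planted slopes and match brute force", {
  withr::with_seed(8, {
    n_t <- 12
    gains <- runif(n_t); losses <- runif(n_t)
    D <- 0.02 * abs(outer(gains, gains, `-`)) +
      0.005 * abs(outer(losses, losses, `-`)) + 0.1
    diag(D) <- 0
    D <- structure(D, class = c("vs_rdm", "matrix"))
    est <- suppressWarnings(attribute_encoding_strength(D, gains, losses))
    expect_equal(est$estimate[est$term == "gain_distance"], 0.02, tolerance = 1e-10)
    expect_equal(est$estimate[est$term == "loss_distance"], 0.005, tolerance = 1e-10)
    # brute-force per-pair oracle (diagonal intercept contaminates neither)
    brute <- brute_encoding_slopes(unclass(D), gains, losses)
    expect_equal(est$estimate[2:3], unname(brute), tolerance = 1e-10)
  })
  # shuffled RDM: slopes within 2 nominal s.e. of zero
  withr::with_seed(9, {
    n_t <- 40
    gains <- runif(n_t); losses <- runif(n_t)
    D <- matrix(0, n_t, n_t)
    D[lower.tri(D)] <- sample(runif(n_t * (n_t - 1) / 2))
    D <- D + t(D)
    D <- structure(D, class = c("vs_rdm", "matrix"))
    est <- attribute_encoding_strength(D, gains, losses)
    expect_true(all(abs(est$estimate[2:3]) <= 2 * est$std.error[2:3]))
  })
})

test_that("EV encoding strength is a separate single-regressor fit", {
  withr::with_seed(10, {
    n_t <- 15
    evs <- runif(n_t, -0.5, 0.5)
    D <- 0.03 * abs(outer(evs, evs, `-`)); diag(D) <- 0
    D <- structure(D, class = c("vs_rdm", "matrix"))
    est <- suppressWarnings(ev_encoding_strength(D, evs))
    expect_equal(est$estimate[est$term == "ev_distance"], 0.03, tolerance = 1e-10)
    # EV-unrelated dissimilarities give a near-zero slope
    D2 <- structure(matrix(0.5, n_t, n_t) - diag(0.5, n_t),
                    class = c("vs_rdm", "matrix"))
    est2 <- suppressWarnings(ev_encoding_strength(D2, evs))
    expect_equal(est2$estimate[2], 0, tolerance = 1e-10)
  })
})

test_that("binned RDMs aggregate trial pairs by level", {
  withr::with_seed(11, {
    levels <- seq(0.1, 1, length.out = 4)
    vals <- rep(levels, each = 3)
    n_t <- length(vals)
    Y <- matrix(rnorm(6 * n_t), 6, n_t)
    D <- compute_rdm(Y)
    B <- binned_rdm(D, vals)
    expect_equal(dim(unclass(B)), c(4L, 4L))
    # entry (1,2) is the mean over all 3x3 cross pairs
    expect_equal(B[1, 2], mean(unclass(D)[vals == levels[1], vals == levels[2]]))
    # diagonal uses within-level pairs
    blk <- unclass(D)[vals == levels[3], vals == levels[3]]
    expect_equal(B[3, 3], mean(blk[lower.tri(blk)]))
    # invariant to within-level reordering
    perm <- c(3, 1, 2, 4:n_t)
    B2 <- binned_rdm(structure(unclass(D)[perm, perm], class = class(D)), vals[perm])
    expect_equal(unclass(B2), unclass(B))
    # one trial per level: binned RDM is the relabeled trial RDM
    Y1 <- matrix(rnorm(6 * 4), 6, 4)
    D1 <- compute_rdm(Y1)
    B1 <- binned_rdm(D1, levels)
    expect_equal(unclass(B1)[lower.tri(B1)], unclass(D1)[lower.tri(D1)])
    expect_true(all(is.na(diag(unclass(B1)))))   # no within-level pairs
    expect_true(length(attr(B1, "empty_pairs")) == 4)
  })
})

test_that("sixteen gain levels produce a 16 x 16 gain-RDM", {
  d <- gen_group_design(group_design_spec("narrow"))
  net <- vs_network(seed = 2, money_unit = 40)
  Z <- ann_forward(net, d)$Z
  B <- binned_rdm(compute_rdm(Z), d$gain)
  expect_equal(dim(unclass(B)), c(16L, 16L))
})

test_that("RDM similarity and its group test behave at the null and identity", {
  withr::with_seed(12, {
    Y <- matrix(rnorm(8 * 12), 8, 12)
    D <- compute_rdm(Y)
    expect_equal(rdm_similarity(D, D)$r, 1)
    rs <- replicate(300, {
      A <- compute_rdm(matrix(rnorm(6 * 10), 6, 10))
      B <- compute_rdm(matrix(rnorm(6 * 10), 6, 10))
      rdm_similarity(A, B)$r
    })
    expect_lt(abs(mean(rs)), 0.03)
    gt <- rdm_group_test(atanh(rs))
    expect_gt(gt$p, 0.001)   # null correlations: no systematic group effect
  })
  expect_error(rdm_similarity(compute_rdm(matrix(rnorm(6), 2, 3)),
                              compute_rdm(matrix(rnorm(8), 2, 4))), "match")
})
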