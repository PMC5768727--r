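test_that("group model estimates time-point means and variances", {
  m <- fit_group_model(rbind(rep(0, 5), rep(2, 5)))
  expect_equal(m$mu, rep(1, 5))
  expect_equal(m$sigma2, rep(1, 5))          # population variance

  # identical members engage the variance floor
  md <- fit_group_model(rbind(rep(3, 4), rep(3, 4)))
  expect_equal(md$sigma2, rep(1e-8, 4))
  expect_equal(md$n_floored, 4L)

  # 17 random members against the direct column-wise oracle
  set.seed(20)
  Y <- matrix(rnorm(17 * 30), nrow = 17)
  mp <- fit_group_model(Y, var_type = "population")
  expect_equal(mp$mu, colMeans(Y), tolerance = 1e-12)
  expect_equal(mp$sigma2, apply(Y, 2, function(c) mean((c - mean(c))^2)),
               tolerance = 1e-12)
  ms <- fit_group_model(Y, var_type = "sample")
  expect_equal(ms$sigma2, apply(Y, 2, var), tolerance = 1e-12)

  expect_error(fit_group_model(matrix(1, 1, 5)), ">= 2 members")
})

test_that("log-likelihood matches closed forms and the univariate oracle", {
  m <- fit_group_model(rbind(c(-1, -1), c(1, 1)))   # mu = 0, sigma2 = 1
  expect_equal(log_likelihood(m, c(0, 0)), -log(2 * pi),
               tolerance = 1e-12)

  # sum of univariate normal log-densities (k = 3)
  set.seed(21)
  Y <- matrix(rnorm(12), nrow = 4)
  m3 <- fit_group_model(Y)
  y <- rnorm(3)
  oracle <- sum(dnorm(y, m3$mu, sqrt(m3$sigma2), log = TRUE))
  expect_equal(log_likelihood(m3, y), oracle, tolerance = 1e-10)

  # scaling all variances x4 at yhat = mu lowers the value by (k/2) ln 4
  m4 <- m3; m4$sigma2 <- m3$sigma2 * 4
  expect_equal(log_likelihood(m3, m3$mu) - log_likelihood(m4, m3$mu),
               (3 / 2) * log(4), tolerance = 1e-10)

  expect_error(log_likelihood(m3, rnorm(5)), "does not match")
})

test_that("streaming and matrix forms of the log-likelihood agree", {
  set.seed(22)
  for (i in 1:5) {
    k <- sample(5:50, 1)
    m <- fit_group_model(matrix(rnorm(6 * k), nrow = 6))
    y <- rnorm(k)
    # explicit multivariate form with the dense diagonal covariance
    S <- diag(m$sigma2)
    dense <- -0.5 * (determinant(S)$modulus +
                       drop(t(y - m$mu) %*% solve(S) %*% (y - m$mu)) +
                       k * log(2 * pi))
    expect_equal(log_likelihood(m, y), as.numeric(dense),
                 tolerance = 1e-9)
    # matrix (row-wise) input equals the scalar path
    Y2 <- rbind(y, rnorm(k))
    expect_equal(log_likelihood(m, Y2),
                 c(log_likelihood(m, Y2[1, ]), log_likelihood(m, Y2[2, ])),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("log-likelihood ratio is antisymmetric with unit-variance closed form", {
  set.seed(23)
  k <- 20
  mm <- fit_group_model(matrix(rnorm(5 * k, 1), nrow = 5))
  mn <- fit_group_model(matrix(rnorm(5 * k, -1), nrow = 5))
  y <- rnorm(k)
  expect_equal(llr(mm, mm, y), 0)
  expect_equal(llr(mm, mn, y), -llr(mn, mm, y), tolerance = 1e-12)

  # with unit variances Lambda reduces to half the squared-distance gap
  mu_m <- rnorm(k); mu_n <- rnorm(k)
  m1 <- mm; m1$mu <- mu_m; m1$sigma2 <- rep(1, k)
  m2 <- mn; m2$mu <- mu_n; m2$sigma2 <- rep(1, k)
  expect_equal(llr(m1, m2, y),
               0.5 * (sum((y - mu_n)^2) - sum((y - mu_m)^2)),
               tolerance = 1e-10)
  m2$sigma2 <- rep(1, k + 1); m2$mu <- rnorm(k + 1); m2$k <- k + 1
  expect_error(llr(m1, m2, y), "different lengths")
})

test_that("a series drawn from the first model has positive expected LLR", {
  set.seed(24)
  k <- 200
  mu_m <- rnorm(k); mu_n <- rnorm(k)
  m1 <- structure(list(group = "M", mu = mu_m, sigma2 = rep(1, k), k = k),
                  class = "gaussian_group_model")
  m2 <- structure(list(group = "N", mu = mu_n, sigma2 = rep(1, k), k = k),
                  class = "gaussian_group_model")
  draws <- matrix(rnorm(500 * k), nrow = 500) + rep(mu_m, each = 500)
  lam <- llr(m1, m2, draws)
  expect_gt(mean(lam), 0)
  # Monte Carlo mean close to the analytic value ||mu_m - mu_n||^2 / 2
  expect_equal(mean(lam), sum((mu_m - mu_n)^2) / 2,
               tolerance = 0.1 * sum((mu_m - mu_n)^2) / 2)
})

test_that("region ranking scores correct-group fit with deterministic ties", {
  co <- tiny_cohort(seed = 3, effect_size = 2, noise_sd = 1)
  enc <- encode_cohort(attr(co, "feature_matrix"), co)
  groups <- vapply(enc, function(e) e$group, character(1))
  nr <- nrow(enc[[1]]$yhat)
  models_m <- lapply(seq_len(nr), function(r) fit_group_model(
    t(vapply(enc[groups == "musician"], function(e) e$yhat[r, ],
             numeric(120))), "M"))
  models_n <- lapply(seq_len(nr), function(r) fit_group_model(
    t(vapply(enc[groups == "nonmusician"], function(e) e$yhat[r, ],
             numeric(120))), "N"))

  ranked <- rank_regions(models_m, models_n, enc)
  scores <- attr(ranked, "scores")
  # brute-force re-sort oracle
  unsorted <- scores[order(ranked)]
  expect_identical(ranked[order(ranked)], seq_len(nr))
  expect_identical(as.integer(ranked), order(-unsorted, seq_len(nr)))
  expect_true(all(diff(scores) <= 0))

  # matches the ranking computed inside the decoder on the same data
  dec <- train_decoder(enc, n_top_regions = 3)
  expect_identical(as.integer(ranked), dec$ranking)
  expect_equal(unsorted, dec$scores, tolerance = 1e-9)

  # single region -> trivially ranked first
  r1 <- rank_regions(models_m[1], models_n[1], enc)
  expect_identical(as.integer(r1), 1L)
  expect_error(rank_regions(models_m, models_n, list()), "empty")
})

test_that("planted regions occupy the top ranks at strong effect sizes", {
  hits <- vapply(1:8, function(s) {
    co <- tiny_cohort(seed = s, effect_size = 2, noise_sd = 1,
                      n_per_group = 8L)
    enc <- encode_cohort(attr(co, "feature_matrix"), co)
    dec <- train_decoder(enc, n_top_regions = 3)
    all(sort(dec$selected) == attr(co, "discriminative_regions"))
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
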