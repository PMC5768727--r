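test_that("performance metrics match their definitions and oracles", {
  lab <- c("musician", "musician", "nonmusician", "nonmusician")
  m <- metrics(lab, c(0.9, 0.8, 0.4, 0.1), lab)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$auc, 1)

  # mixed predictions
  pred <- c("musician", "nonmusician", "nonmusician", "musician")
  m2 <- metrics(pred, c(0.6, 0.4, 0.3, 0.7), lab)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$specificity, 0.5)

  # AUC against the brute-force pair-counting oracle
  set.seed(40)
  for (i in 1:5) {
    n <- 20
    lab_i <- sample(rep(c("musician", "nonmusician"), 10))
    p <- round(runif(n), 1)           # coarse grid forces ties
    pos <- which(lab_i == "musician"); neg <- which(lab_i == "nonmusician")
    wins <- 0
    for (a in pos) for (b in neg)
      wins <- wins + (p[a] > p[b]) + 0.5 * (p[a] == p[b])
    expect_equal(metrics(lab_i, p, lab_i)$auc, wins / 100)
  }
  expect_error(metrics(lab, 1:4, rep("musician", 4)), "both classes")
})

test_that("binomial significance uses the exact upper tail", {
  b <- binomial_significance(0.5, 36)
  # oracle: explicit summation of the binomial pmf
  oracle <- sum(choose(36, 18:36) * 0.5^36)
  expect_equal(b$median_p, oracle, tolerance = 1e-12)
  expect_equal(b$median_p, 0.5660303, tolerance = 1e-6)
  expect_equal(binomial_significance(1, 36)$median_p, 2^-36)
  expect_equal(binomial_significance(0, 36)$median_p, 1)
  # median across runs
  expect_equal(binomial_significance(c(0.5, 1, 0), 36)$median_p, oracle)
  expect_error(binomial_significance(0.5, 0), "positive")
  expect_error(binomial_significance(1.2, 36), "\\[0, 1\\]")
})

test_that("cross-validation covers each participant once per run", {
  co <- tiny_cohort(seed = 2)
  cv <- run_cv(co, n_top_regions = 3, n_runs = 2, seed = 9)
  expect_equal(nrow(cv$per_run), 2L)
  expect_equal(cv$n_folds, 6L)
  for (i in seq_along(cv$runs)) {
    run <- cv$runs[[i]]
    # every participant predicted exactly once, with finite outputs
    expect_true(all(run$pred %in% c("musician", "nonmusician")))
    expect_true(all(is.finite(run$prob)))
    expect_true(all(is.finite(run$llr)))
    # pairing is a bijection between the groups
    expect_setequal(run$pairing[, "musician"], which(cv$labels == "musician"))
    expect_setequal(run$pairing[, "nonmusician"],
                    which(cv$labels == "nonmusician"))
    # run accuracy equals the mean of per-fold correctness
    expect_equal(mean(run$pred == cv$labels), cv$per_run$accuracy[i])
  }
  # seeded determinism of the whole experiment
  cv2 <- run_cv(co, n_top_regions = 3, n_runs = 2, seed = 9)
  expect_equal(cv$per_run, cv2$per_run)
  expect_identical(cv$runs[[1]]$pred, cv2$runs[[1]]$pred)

  expect_error(run_cv(co[1:11], X = attr(co, "feature_matrix"),
                      n_top_regions = 3), "balanced")
  expect_error(run_cv(co, n_top_regions = 0), "n_top_regions")
  expect_error(run_cv(co, n_top_regions = 99), "n_top_regions")
})

test_that("strong planted effects are decoded near-perfectly", {
  accs <- vapply(1:3, function(s)
    cohort_cv_accuracy(tiny_spec(seed = s, effect_size = 2.5,
                                 noise_sd = 1)), numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("region selection frequencies count folds and favor planted regions", {
  co <- tiny_cohort(seed = 4, effect_size = 2, noise_sd = 1)
  cv <- run_cv(co, n_top_regions = 3, n_runs = 2, seed = 2)
  freq <- region_consistency(cv)
  expect_equal(sum(freq), 3)               # n_top per fold
  expect_true(all(freq >= 0 & freq <= 1))
  top3 <- names(freq)[1:3]
  expect_setequal(top3, paste0("R", attr(co, "discriminative_regions")))

  # selecting every region makes every frequency 1
  cv_all <- run_cv(co, n_top_regions = 12, n_runs = 1, seed = 2)
  expect_true(all(region_consistency(cv_all) == 1))
})

test_that("held-out LLR group test finds planted group differences", {
  co <- tiny_cohort(seed = 5, effect_size = 2, noise_sd = 1)
  cv <- run_cv(co, n_top_regions = 3, n_runs = 2, seed = 3)
  tab <- llr_group_test(cv)
  expect_equal(nrow(tab), 12L)
  disc <- paste0("R", attr(co, "discriminative_regions"))
  expect_true(all(tab$z[tab$region %in% disc] > 2))
  expect_true(all(tab$p[tab$region %in% disc] < 0.05))
  # p is the upper-tail normal probability of the averaged z
  expect_equal(tab$p, pnorm(tab$z, lower.tail = FALSE))
  # the t -> z mapping preserves order with the direct-t variant
  tab_t <- llr_group_test(cv, method = "direct_t")
  expect_equal(order(tab$z), order(tab_t$z))
})

test_that("LLR group test is calibrated under the null", {
  zs <- vapply(1:6, function(s) {
    co <- tiny_cohort(seed = 50 + s, effect_size = 0)
    cv <- run_cv(co, n_top_regions = 3, n_runs = 1, seed = s)
    mean(llr_group_test(cv)$z)
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.5)
})

test_that("familiarity partial correlation matches the residual oracle", {
  # 6-row hand instance, partial r computed by two-stage residual regression
  prob <- c(0.9, 0.7, 0.8, 0.3, 0.2, 0.4)
  y <- c(1, 1, 1, 0, 0, 0)
  fam <- c(4.1, 3.0, 3.5, 2.0, 2.5, 1.5)
  rx <- residuals(lm(prob ~ fam)); ry <- residuals(lm(y ~ fam))
  oracle <- cor(rx, ry)
  cv_stub <- structure(list(
    runs = list(list(prob = prob)),
    labels = c(rep("musician", 3), rep("nonmusician", 3)),
    familiarity = fam), class = "cv_result")
  expect_equal(familiarity_partial_correlation(cv_stub)$mean_r, oracle,
               tolerance = 1e-10)

  # probability driven by familiarity alone -> partial r ~ 0
  set.seed(41)
  n <- 400
  fam2 <- rnorm(n)
  prob2 <- plogis(2 * fam2)
  lab2 <- rep(c("musician", "nonmusician"), each = n / 2)
  cv_conf <- structure(list(runs = list(list(prob = prob2)), labels = lab2,
                            familiarity = fam2), class = "cv_result")
  expect_lt(abs(familiarity_partial_correlation(cv_conf)$mean_r), 0.05)

  # zero-variance familiarity falls back to the plain correlation
  cv_flat <- structure(list(runs = list(list(prob = prob)),
                            labels = cv_stub$labels,
                            familiarity = rep(3, 6)), class = "cv_result")
  expect_warning(r <- familiarity_partial_correlation(cv_flat)$mean_r,
                 "zero-variance")
  expect_equal(r, cor(prob, y), tolerance = 1e-12)
})

test_that("decoder probabilities carry class signal beyond familiarity", {
  co <- tiny_cohort(seed = 6, effect_size = 2, noise_sd = 2)
  cv <- run_cv(co, n_top_regions = 3, n_runs = 2, seed = 4)
  expect_gt(familiarity_partial_correlation(cv)$mean_r, 0.3)
})

test_that("coefficient group tests match the pooled-variance formula", {
  tbl <- data.frame(
    group = rep(c("musician", "nonmusician"), each = 4),
    region = "R1", feature = "F1",
    beta = c(2.1, 2.5, 1.9, 2.3, 1.2, 1.0, 1.5, 1.1))
  out <- beta_group_tests(tbl)
  bm <- tbl$beta[1:4]; bn <- tbl$beta[5:8]
  sp2 <- (3 * var(bm) + 3 * var(bn)) / 6
  t_oracle <- (mean(bm) - mean(bn)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(out$t, t_oracle, tolerance = 1e-10)
  expect_equal(out$p, 2 * pt(abs(t_oracle), 6, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(out$t_mus, mean(bm) / (sd(bm) / 2), tolerance = 1e-10)

  # equal group samples -> t = 0
  tbl0 <- tbl; tbl0$beta[5:8] <- tbl0$beta[1:4]
  expect_equal(beta_group_tests(tbl0)$t, 0)
  expect_error(beta_group_tests(tbl[c(1, 5:8), ]), ">= 2")
})

test_that("region sweep reports shrinking confidence bands", {
  co <- tiny_cohort(seed = 7, effect_size = 1.5, noise_sd = 2)
  sw2 <- sweep_regions(co, region_counts = c(1, 3, 12), n_runs = 2,
                       seed = 5)
  expect_equal(sw2$n_regions, c(1, 3, 12))
  expect_true(all(sw2$lo95 <= sw2$lo68 & sw2$hi68 <= sw2$hi95))
  sw6 <- sweep_regions(co, region_counts = 3, n_runs = 8, seed = 5)
  width2 <- sw2$hi95[2] - sw2$lo95[2]
  width6 <- sw6$hi95 - sw6$lo95
  expect_lt(width6, width2 + 1e-12)
  expect_error(sweep_regions(co, region_counts = 0, n_runs = 1), "1..")
})

test_that("fixed-region decoding separates lateralized signal", {
  # plant signal only in the 'right-hemisphere' half of the regions:
  # regions 1..3 discriminative, declared as RH; 7..9 as homologous LH
  co <- tiny_cohort(seed = 8, effect_size = 2, noise_sd = 1)
  out <- lateralization_compare(
    co, region_sets = list(LH = 7:9, RH = 1:3, both = c(1:3, 7:9)),
    n_runs = 2, seed = 6)
  expect_setequal(out$set, c("LH", "RH", "both"))
  acc <- setNames(out$mean_accuracy, out$set)
  expect_gt(acc[["RH"]], acc[["LH"]])
  expect_gt(acc[["RH"]], 0.8)
  expect_lt(abs(acc[["LH"]] - 0.5), 0.35)
  expect_error(
    lateralization_compare(co, region_sets = list(1:2), n_runs = 1),
    "named")
  expect_error(run_cv(co, regions = c("R1", "nope"), n_runs = 1),
               "unknown region")
})
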