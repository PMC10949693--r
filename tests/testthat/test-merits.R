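test_that("core statistics match the worked three-point example", {
  p <- paired_outcomes(c(10, 20, 30), c(11, 19, 31), "calibration")
  s <- core_stats(p)
  expect_equal(s$rss, 3)
  expect_equal(s$ssx, 200)
  expect_equal(s$r2, 0.985)
  expect_equal(s$rmse, 1.0)
  expect_equal(s$bias, -1 / 3)
  perfect <- core_stats(paired_outcomes(1:3, 1:3))
  expect_equal(perfect$rss, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$bias, 0)
  flat <- core_stats(paired_outcomes(c(5, 5, 5), c(4, 5, 6)))
  expect_true(is.na(flat$r2))
  expect_match(flat$flags, "constant")
})

test_that("Q2 follows the PRESS/SSX identity", {
  cal_ssx <- 200
  p <- paired_outcomes(c(10, 20, 30), c(12, 18, 32), "cross_validation")
  q <- q2_press(p, cal_ssx)
  expect_equal(q$press, 12)
  expect_equal(q$q2, 0.94)
  expect_equal(q2_press(paired_outcomes(1:5, 1:5, "cross_validation"), 10)$q2, 1)
  # PRESS equal to SSX means no better than the mean model
  pm <- paired_outcomes(c(0, 10), c(5, 5), "cross_validation")
  expect_equal(q2_press(pm, 50)$q2, 0)
})

test_that("precision statistics match the printed formulas", {
  p <- paired_outcomes(c(10, 20, 30), c(11, 19, 31), "prediction")
  s <- precision_stats(p)
  expect_equal(s$bias, -1 / 3)
  expect_equal(s$sec, sqrt(24 / 18))
  expect_equal(s$rrmsep_pct, (1 / 3) * sqrt(3) / 20 * 100)
  expect_equal(s$bcmsep, 1 - 1 / 9)
  # conventional relative error uses the 1/sqrt(n) prefactor instead
  expect_equal(precision_stats(p, conventional = TRUE)$rrmsep_pct,
               sqrt(3 / 3) / 20 * 100)
  perfect <- precision_stats(paired_outcomes(1:4, 1:4))
  expect_equal(perfect$sec, 0)
  expect_equal(perfect$rrmsep_pct, 0)
  expect_equal(perfect$bcmsep, 0)
  # a constant error is absorbed entirely by the bias
  ce <- precision_stats(paired_outcomes(c(10, 20, 30), c(10, 20, 30) + 2.5))
  expect_equal(ce$bcmsep, 0)
  expect_equal(ce$sec, 0)
})

test_that("every statistic matches brute-force arithmetic on random vectors", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    y <- runif(n, 5, 40)
    yh <- y + rnorm(n, sd = runif(1, 0.01, 2))
    o <- oracle_stats(y, yh)
    s <- core_stats(paired_outcomes(y, yh))
    pr <- precision_stats(paired_outcomes(y, yh))
    expect_equal(s$rss, o$rss, tolerance = 1e-10)
    expect_equal(s$ssx, o$ssx, tolerance = 1e-10)
    expect_equal(s$r2, o$r2, tolerance = 1e-10)
    expect_equal(s$rmse, o$rmse, tolerance = 1e-10)
    expect_equal(s$bias, o$bias, tolerance = 1e-10)
    expect_equal(pr$sec, o$sec, tolerance = 1e-10)
    expect_equal(pr$rrmsep_pct, o$rrmsep, tolerance = 1e-10)
    expect_equal(pr$bcmsep, o$bcmsep, tolerance = 1e-10)
    # algebraic identities: BCMSEP = RMSE^2 - bias^2 >= 0;
    # SEC^2 = n/(n-1) BCMSEP
    expect_gte(pr$bcmsep, -1e-12)
    expect_equal(pr$bcmsep, s$rmse^2 - s$bias^2, tolerance = 1e-12)
    expect_equal(pr$sec^2, n / (n - 1) * pr$bcmsep, tolerance = 1e-10)
  }
})

test_that("R2 is permutation invariant and RMSE scales linearly", {
  set.seed(5)
  y <- runif(10, 10, 30); yh <- y + rnorm(10, sd = 0.5)
  perm <- sample(10)
  expect_equal(core_stats(paired_outcomes(y, yh))$r2,
               core_stats(paired_outcomes(y[perm], yh[perm]))$r2)
  expect_equal(core_stats(paired_outcomes(3 * y, 3 * yh))$rmse,
               3 * core_stats(paired_outcomes(y, yh))$rmse)
})

test_that("LOD and LOQ follow 3.3 and 10 sigma over slope", {
  ll <- lod_loq(list(slope = 1, sigma = 0.1))
  expect_equal(ll$lod, 0.33)
  expect_equal(ll$loq, 1.0)
  expect_equal(ll$loq / ll$lod, 10 / 3.3)
  expect_equal(lod_loq(list(slope = 2, sigma = 0))$lod, 0)
  expect_error(lod_loq(list(slope = 0, sigma = 0.1)), "slope")
  # regression-line sigma equals the hand least-squares residual SE (n-2)
  set.seed(8)
  x <- runif(12, 10, 30)
  y <- 0.98 * x + 0.3 + rnorm(12, sd = 0.2)
  line <- regression_line(y, x)
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  expect_equal(line$intercept, beta[1], tolerance = 1e-10)
  expect_equal(line$slope, beta[2], tolerance = 1e-10)
  expect_equal(line$sigma, sqrt(sum(res^2) / 10), tolerance = 1e-10)
})

test_that("recovery and %RSD follow the reporting conventions", {
  expect_equal(recovery_rsd(19.8, 20)$overall$mean_recovery_pct, 99.0)
  expect_equal(recovery_rsd(c(10, 10, 10), 10)$per_level$rsd_pct, 0)
  r <- recovery_rsd(c(99, 100, 101), 100)
  expect_equal(r$overall$mean_recovery_pct, 100)
  expect_equal(r$per_level$rsd_pct, 1.0)
  expect_error(recovery_rsd(10, 0), "nominal")
  g <- recovery_rsd(c(15.1, 14.9, 20.2, 19.8), c(15, 15, 20, 20),
                    groups = c(15, 15, 20, 20))
  expect_equal(nrow(g$per_level), 2L)
})

test_that("one-way ANOVA matches the sum-of-squares oracle", {
  same <- anova_oneway(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4))
  res <- anova_oneway(g)
  o <- oracle_anova(g)
  expect_equal(res$f, o$f, tolerance = 1e-10)
  expect_equal(res$p, o$p, tolerance = 1e-10)
  expect_equal(res$f_critical, stats::qf(0.95, 1, 4))
  set.seed(31)
  g3 <- list(a = rnorm(5, 100), b = rnorm(7, 100), c = rnorm(6, 101))
  res3 <- anova_oneway(g3)
  o3 <- oracle_anova(g3)
  expect_equal(res3$f, o3$f, tolerance = 1e-10)
  expect_equal(res3$p, o3$p, tolerance = 1e-10)
  expect_error(anova_oneway(list(a = 1:3)), "2 groups")
})

test_that("merit reports compose the individual statistics", {
  y <- c(10, 20, 30, 15, 25); yh <- y + c(0.2, -0.1, 0.3, 0, -0.2)
  ycv <- y + c(0.4, -0.2, 0.5, 0.1, -0.3)
  rep <- merit_report(
    calibration = paired_outcomes(y, yh, "calibration"),
    cv = paired_outcomes(y, ycv, "cross_validation"),
    prediction = paired_outcomes(y, yh, "prediction"),
    recovery_found = yh, recovery_nominal = y)
  cs <- core_stats(paired_outcomes(y, yh))
  expect_equal(rep$rmsec, cs$rmse)
  expect_equal(rep$r2, cs$r2)
  expect_equal(rep$q2, q2_press(paired_outcomes(y, ycv, "cross_validation"),
                                cs$ssx)$q2)
  expect_equal(rep$rrmsep_pct,
               precision_stats(paired_outcomes(y, yh))$rrmsep_pct)
  expect_equal(rep$lod,
               lod_loq(regression_line(y, yh))$lod)
  # all-perfect inputs give zeros and ones
  perf <- merit_report(calibration = paired_outcomes(y, y, "calibration"),
                       cv = paired_outcomes(y, y, "cross_validation"))
  expect_equal(perf$r2, 1)
  expect_equal(perf$q2, 1)
  expect_equal(perf$rmsec, 0)
  expect_equal(perf$sec, 0)
})
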