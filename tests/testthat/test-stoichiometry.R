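# Orthogonal regression, DSC, line shifts, response vectors.

test_that("major-axis fit recovers collinear and symmetric configurations", {
  f1 <- fit_orthogonal(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  expect_equal(f1$intercept, 0, tolerance = 1e-12)

  # S_nn = S_cc = 5, S_nc = 4 -> slope exactly 1 through the centroid
  f2 <- fit_orthogonal(c(0, 1, 2, 3), c(0, 2, 1, 3))
  expect_equal(f2$slope, 1, tolerance = 1e-12)
  expect_equal(f2$intercept, 0, tolerance = 1e-12)

  f3 <- fit_orthogonal(c(0, 2, 4), c(1, 0, -1))
  expect_equal(f3$slope, -0.5, tolerance = 1e-12)
  expect_equal(f3$intercept, 1, tolerance = 1e-12)
})

test_that("fit passes through the centroid and matches the eigen route", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_tls_points(sample(4:30, 1))
    f <- fit_orthogonal(p$x, p$y)
    expect_equal(f$intercept, f$centroid[["c"]] - f$slope * f$centroid[["n"]],
                 tolerance = 1e-9)
    ev <- eigen(stats::cov(cbind(p$x, p$y)))$vectors[, 1]
    expect_equal(f$slope, ev[2] / ev[1], tolerance = 1e-8)
  }
})

test_that("degenerate and edge geometries are handled explicitly", {
  expect_error(fit_orthogonal(c(0, 1), c(0, 1)), "3 points")
  expect_error(fit_orthogonal(c(0, 0, 1, 1), c(0, 1, 0, 1)), "degenerate")
  expect_error(fit_orthogonal(c(1, 1, 1), c(1, 1, 1)), "degenerate")
  # horizontal and vertical major axes
  fh <- fit_orthogonal(c(-2, 0, 2, 0), c(0, 0.5, 0, -0.5))
  expect_equal(fh$slope, 0)
  fv <- fit_orthogonal(c(0, 0.5, 0, -0.5), c(-2, 0, 2, 0))
  expect_identical(fv$slope, Inf)
  expect_true(fv$vertical)
})

test_that("axis swap maps the fitted line onto its inverse-slope image", {
  set.seed(23)
  for (i in 1:10) {
    p <- random_tls_points(12)
    f <- fit_orthogonal(p$x, p$y)
    g <- fit_orthogonal(p$y, p$x)
    expect_equal(g$slope, 1 / f$slope, tolerance = 1e-8)
  }
})

test_that("reduced-major-axis variant uses the geometric-mean slope", {
  set.seed(31)
  p <- random_tls_points(20)
  f <- fit_orthogonal(p$x, p$y, method = "rma")
  dn <- p$x - mean(p$x); dc <- p$y - mean(p$y)
  expect_equal(f$slope, sign(sum(dn * dc)) * sqrt(sum(dc^2) / sum(dn^2)),
               tolerance = 1e-12)
})

test_that("DSC worked example on the control-average line", {
  line <- list(slope = -4.0, intercept = 70.7)
  up <- dsc(4.0, 56.0, line)
  expect_equal(up$diff_c, 1.3, tolerance = 1e-9)
  expect_equal(up$diff_n, 0.325, tolerance = 1e-9)
  expect_equal(up$dsc, 1.3 / sqrt(17), tolerance = 1e-9)
  expect_equal(up$dsc, 0.3153, tolerance = 1e-4)
  down <- dsc(4.0, 53.0, line)
  expect_equal(down$dsc, -1.7 / sqrt(17), tolerance = 1e-9)
  expect_equal(down$dsc, -0.4123, tolerance = 1e-4)
  on_line <- dsc(4.0, 70.7 - 16.0, line)
  expect_identical(on_line$dsc, 0)
})

test_that("altitude formula equals signed perpendicular projection", {
  set.seed(5)
  for (i in 1:50) {
    a <- stats::runif(1, -50, 120); b <- stats::runif(1, -8, 8)
    if (abs(b) < 1e-3) b <- b + 0.5
    x <- stats::runif(10, 0, 8); y <- stats::runif(10, 20, 80)
    v <- dsc(x, y, list(slope = b, intercept = a))
    expect_equal(v$dsc, projection_distance(x, y, a, b), tolerance = 1e-9)
    # sign agreement of the two gaps for negative slopes
    if (b < 0) expect_false(any(v$flagged))
  }
})

test_that("DSC is invariant under joint translation of points and line", {
  set.seed(9)
  x <- stats::runif(8, 2, 6); y <- stats::runif(8, 45, 65)
  f <- fit_orthogonal(x, y)
  v1 <- dsc(x, y, f)$dsc
  sh <- c(1.7, -3.1)
  f2 <- fit_orthogonal(x + sh[1], y + sh[2])
  v2 <- dsc(x + sh[1], y + sh[2], f2)$dsc
  expect_equal(v2, v1, tolerance = 1e-9)
})

test_that("mean signed DSC of the fitted points is zero", {
  set.seed(13)
  for (i in 1:10) {
    p <- random_tls_points(sample(5:40, 1))
    f <- fit_orthogonal(p$x, p$y)
    v <- dsc(p$x, p$y, f)$dsc
    expect_lt(abs(mean(v)), 1e-9 * max(1, max(abs(p$y))))
  }
})

test_that("per-cell fits attach DSC against each seed's own cell line", {
  sim <- simulate_dataset(synthetic_config(), seed = 4)
  st <- fit_seed_lines(sim$dataset)
  expect_identical(nrow(st$fits), 24L)    # 4 experiments x 6 conditions
  expect_identical(nrow(st$dsc), sum(sim$dataset$records$organ == "seeds"))
  # DSC of each cell's own points averages to zero
  agg <- stats::aggregate(dsc ~ experiment + condition, data = st$dsc, FUN = mean)
  expect_true(all(abs(agg$dsc) < 1e-9))
})

test_that("condition shifts difference each stress against its experiment control", {
  fits <- data.frame(
    experiment = c("1", "1", "2", "2", "3"),
    condition = c("control", "lowN", "control", "lowN", "lowN"),
    slope = c(-4.0, -4.6, -4.2, -4.4, -5.0),
    intercept = c(70, 72, 71, 75, 80))
  expect_warning(sh <- condition_shifts(fits), "lacks a control")
  expect_identical(nrow(sh$per_experiment), 2L)
  expect_equal(sh$per_experiment$d_slope, c(-0.6, -0.2))
  expect_equal(sh$per_experiment$d_intercept, c(2, 4))
  expect_equal(sh$summary$mean_d_intercept, 3)
  expect_equal(sh$summary$sd_d_intercept, sqrt(2))
  # identical fits give zero shifts
  same <- data.frame(experiment = "1", condition = c("control", "dark"),
                     slope = -4, intercept = 70)
  expect_equal(condition_shifts(same)$per_experiment$d_slope, 0)
})

test_that("response vectors measure displacement from the control baseline", {
  seeds <- rbind(
    data.frame(genotype = "g1", condition = "control", n_pct = 4.0, c_pct = 54.7),
    data.frame(genotype = "g1", condition = "drought", n_pct = 4.5, c_pct = 53.5))
  rv <- response_vectors(seeds)
  expect_equal(rv$vectors$d_n, 0.5)
  expect_equal(rv$vectors$d_c, -1.2)
  expect_equal(rv$vectors$length, 1.3)

  # zero displacement: zero vector, undefined angle
  seeds2 <- seeds; seeds2$n_pct[2] <- 4.0; seeds2$c_pct[2] <- 54.7
  rv2 <- response_vectors(seeds2)
  expect_identical(rv2$vectors$length, 0)
  expect_true(is.na(rv2$vectors$angle_deg))

  # two genotypes pulling in opposite N directions -> heterogeneous
  seeds3 <- rbind(
    data.frame(genotype = c("g1", "g2"), condition = "control",
               n_pct = c(4, 4), c_pct = c(55, 55)),
    data.frame(genotype = c("g1", "g2"), condition = "stress",
               n_pct = c(4.8, 3.2), c_pct = c(55.1, 54.9)))
  rv3 <- response_vectors(seeds3)
  expect_true(rv3$summary$heterogeneous)
  # and aligned vectors are homogeneous
  seeds4 <- seeds3
  seeds4$n_pct[3:4] <- c(4.8, 4.7); seeds4$c_pct[3:4] <- c(54.0, 54.1)
  expect_false(response_vectors(seeds4)$summary$heterogeneous)
})
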