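test_that("cumulative curve construction is exact on forced cases", {
  one <- build_cumulative_curve(c(sole = 35))
  expect_equal(one$points, data.frame(x = 100, y = 100))

  two <- build_cumulative_curve(c(a = 80, b = 20))
  expect_equal(two$points$x, c(50, 100))
  expect_equal(two$points$y, c(80, 100))
  expect_equal(two$species, c("a", "b"))

  # geometric coverages, ratio 0.8: cumulative y follows the closed form
  S <- 21
  geo <- stats::setNames(0.8^(0:(S - 1)), sprintf("g%02d", 1:S))
  cur <- build_cumulative_curve(geo)
  expect_equal(cur$points$y[5], 100 * (1 - 0.8^5) / (1 - 0.8^S),
               tolerance = 1e-9)
  expect_equal(cur$points$x[5], 100 * 5 / S)

  # invariants: x strictly increasing, y non-decreasing, ends at (100,100)
  expect_true(all(diff(cur$points$x) > 0))
  expect_true(all(diff(cur$points$y) >= 0))
  expect_equal(unlist(cur$points[S, ]), c(x = 100, y = 100),
               tolerance = 1e-9)
})

test_that("curve construction rejects degenerate input and breaks ties by name", {
  expect_error(build_cumulative_curve(numeric(0)), "no species")
  expect_error(build_cumulative_curve(c(a = 0, b = 0)), "zero")
  tied <- build_cumulative_curve(c(zeta = 10, alpha = 10, mid = 30))
  expect_equal(tied$species, c("mid", "alpha", "zeta"))
})

test_that("least-squares fit recovers known curves exactly", {
  x <- 100 * (1:6) / 6
  lin <- structure(list(points = data.frame(x = x, y = 0.833 * x + 16.66),
                        S = 6L, measure = "coverage"),
                   class = "godron_curve")
  f1 <- fit_smooth_curve(lin, degree = 1)
  expect_equal(f1$coefficients, c(16.66, 0.833, 0), tolerance = 1e-9)
  expect_equal(f1$r_squared, 1, tolerance = 1e-9)

  qy <- -0.010 * x^2 + 1.857 * x + 14.51
  quad <- structure(list(points = data.frame(x = x, y = qy), S = 6L,
                         measure = "coverage"), class = "godron_curve")
  f2 <- fit_smooth_curve(quad, degree = 2)
  expect_equal(f2$coefficients, c(14.51, 1.857, -0.010), tolerance = 1e-9)
  expect_equal(f2$r_squared, 1, tolerance = 1e-9)

  short <- build_cumulative_curve(c(a = 60, b = 40))
  expect_error(fit_smooth_curve(short, degree = 2), "at least 3 points")
})

test_that("fit agrees with an independent normal-equations solver", {
  set.seed(11)
  for (i in 1:200) {
    S <- sample(4:30, 1)
    shares <- sort(stats::runif(S, 0.1, 5), decreasing = TRUE)
    cur <- build_cumulative_curve(stats::setNames(shares,
                                                  sprintf("s%02d", 1:S)))
    f <- fit_smooth_curve(cur, degree = 2)
    oracle <- normal_equations_fit(cur$points$x, cur$points$y, 2)
    expect_equal(f$coefficients, oracle, tolerance = 1e-8)
  }
})

test_that("anti-diagonal intersection matches published stability points", {
  # printed quadratics recovered at 2 decimals
  expect_equal(round(intersect_with_antidiagonal(
    godron_fit(20.09, 1.82, -0.010))[["x_star"]], 2), 31.96)
  expect_equal(round(intersect_with_antidiagonal(
    godron_fit(20.27, 1.989, -0.012))[["x_star"]], 2), 30.38)
  expect_equal(round(intersect_with_antidiagonal(
    godron_fit(12.54, 2.287, -0.014))[["x_star"]], 2), 30.59)

  # constant curve already at the stability level
  p <- intersect_with_antidiagonal(godron_fit(80, 0))
  expect_equal(unname(p), c(20, 80))

  # bracketing-root oracle agreement
  p <- intersect_with_antidiagonal(godron_fit(20.09, 1.82, -0.010))
  expect_equal(p[["x_star"]], bisection_intersection(20.09, 1.82, -0.010),
               tolerance = 1e-6)
  expect_equal(p[["y_star"]], 100 - p[["x_star"]], tolerance = 1e-9)

  expect_error(intersect_with_antidiagonal(godron_fit(200, 2, 0.5)),
               "no.*intersection")
})

test_that("closed-form roots equal bisection on random in-range curves", {
  set.seed(5)
  n <- 0
  while (n < 300) {
    c2 <- stats::runif(1, -0.02, -0.001)
    c1 <- stats::runif(1, 0.5, 3)
    c0 <- stats::runif(1, 5, 40)
    root <- tryCatch(intersect_with_antidiagonal(godron_fit(c0, c1, c2)),
                     error = function(e) NULL)
    if (is.null(root)) next
    n <- n + 1
    expect_equal(root[["x_star"]], bisection_intersection(c0, c1, c2),
                 tolerance = 1e-6)
  }
})

test_that("distance to the stability point reproduces published values", {
  expect_equal(distance_to_stability_point(c(20, 80)), 0)
  expect_equal(round(distance_to_stability_point(c(29.88, 70.12)), 2), 13.97)
  expect_equal(round(distance_to_stability_point(c(30.38, 69.62)), 2), 14.68)
  expect_equal(round(distance_to_stability_point(c(33.95, 66.05)), 2), 19.73)
  expect_equal(round(distance_to_stability_point(c(45.48, 54.52)), 2), 36.03)
  # on the anti-diagonal the distance collapses to sqrt(2)|x - 20|
  expect_equal(distance_to_stability_point(c(33.95, 66.05)),
               sqrt(2) * 13.95, tolerance = 1e-9)
})

test_that("classification is inclusive at the sqrt(200) threshold", {
  expect_equal(round(godron_threshold(), 3), 14.142)
  expect_true(classify_stability(0))
  expect_true(classify_stability(godron_threshold()))
  expect_true(classify_stability(14.142))
  expect_false(classify_stability(14.143))
  expect_error(classify_stability(-1), ">= 0")
})

test_that("assess_stability composes the stages and honours paper_compat", {
  # a stratum calibrated to cross the anti-diagonal exactly at (20, 80)
  sh <- shares_for_stability_point(20, 12)
  a <- assess_stability(sh)
  expect_equal(a$distance, 0, tolerance = 1e-6)
  expect_true(a$stable)

  # stage-by-stage recomposition on a generated stratum
  d <- synth_dataset(synth_config(seed = 1))
  obs <- stratify(d, 25, "outside_crown")
  a <- assess_stability(obs)
  cov <- tapply(obs$coverage, obs$species, sum)
  cur <- build_cumulative_curve(cov)
  fit <- fit_smooth_curve(cur, 2)
  p <- intersect_with_antidiagonal(fit)
  expect_equal(a$fit$coefficients, fit$coefficients)
  expect_equal(a$intersection, p)
  expect_equal(a$distance, distance_to_stability_point(p), tolerance = 1e-12)
  expect_equal(a$stable, classify_stability(a$distance))

  # paper_compat rounds the intersection before the distance
  ap <- assess_stability(obs, paper_compat = TRUE)
  expect_equal(ap$intersection, round(p, 2))
  expect_equal(ap$distance,
               round(distance_to_stability_point(round(p, 2)), 2))

  # two species only: quadratic falls back to a line
  expect_message(a2 <- assess_stability(c(a = 70, b = 30)), "degree-1")
  expect_equal(a2$fit$degree, 1)
})

test_that("the intersection lies on the anti-diagonal and scaling is neutral", {
  set.seed(9)
  for (i in 1:40) {
    S <- sample(5:25, 1)
    shares <- sort(stats::runif(S, 0.2, 6), decreasing = TRUE)
    names(shares) <- sprintf("s%02d", 1:S)
    a <- assess_stability(shares)
    expect_equal(sum(a$intersection), 100, tolerance = 1e-9)
    expect_equal(a$distance, sqrt(2) * abs(a$intersection[["x_star"]] - 20),
                 tolerance = 1e-9)
    # positive rescaling of all coverages changes nothing
    b <- assess_stability(shares * stats::runif(1, 0.1, 8))
    expect_equal(b$distance, a$distance, tolerance = 1e-9)
  }
})

test_that("two-species dominance sweeps trace the V around the 20/80 point", {
  # closed form: for shares (p, 1-p) the fitted line meets the
  # anti-diagonal at x* = (200 - 200p)/(3 - 2p), which crosses 20 at
  # p = 0.875; the distance falls to 0 there and rises on either side
  ps <- seq(0.55, 0.99, by = 0.02)
  dist <- vapply(ps, function(p) {
    suppressMessages(assess_stability(c(dom = p, sub = 1 - p)))$distance
  }, 0)
  xstar <- (200 - 200 * ps) / (3 - 2 * ps)
  expect_equal(dist, sqrt(2) * abs(xstar - 20), tolerance = 1e-9)
  branch <- ps < 0.875
  expect_true(all(diff(dist[branch]) < 0))
  expect_true(all(diff(dist[!branch]) > 0))
  p0 <- suppressMessages(assess_stability(c(dom = 87.5, sub = 12.5)))
  expect_equal(p0$distance, 0, tolerance = 1e-9)
})
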