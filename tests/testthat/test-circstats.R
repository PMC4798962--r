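# Circular statistics: mean/CI, Rayleigh, Kuiper, binned anti-alignment,
# threshold shear, scalar-product regression.

test_that("circular mean and confidence arc behave on degenerate and clean data", {
  s <- circular_mean_ci(rep(180, 50))
  expect_equal(s$mean_angle_deg, 180)
  expect_equal(s$resultant_length, 1)
  expect_equal(s$ci95_halfwidth_deg, 0)
  expect_true(s$significantly_polarized)

  s2 <- circular_mean_ci(c(0, 180))
  expect_lt(s2$resultant_length, 1e-12)
  expect_false(s2$significantly_polarized)
  expect_true(is.na(s2$ci95_halfwidth_deg))

  expect_error(circular_mean_ci(90), "at least 2")
})

test_that("von Mises draws centre on the requested direction with a valid CI", {
  a <- with_seed_test(11, rvonmises(1000, 180, 2))
  s <- circular_mean_ci(a)
  expect_true(s$significantly_polarized)
  expect_lt(s$rayleigh_p, 1e-3)
  expect_lt(abs(ang_diff(s$mean_angle_deg, 180)), s$ci95_halfwidth_deg)
  # concentration 0 degenerates to the uniform distribution
  u <- with_seed_test(12, rvonmises(2000, 0, 0))
  expect_gt(rayleigh_test(u)$p_value, 0.05)
})

test_that("Kuiper statistic matches a brute-force ECDF oracle on tiny samples", {
  # oracle: evaluate both empirical CDFs on the pooled support directly
  kuiper_oracle <- function(a, b) {
    xs <- sort(unique(c(a, b) %% 360))
    d <- vapply(xs, function(x) mean(a %% 360 <= x) - mean(b %% 360 <= x),
                numeric(1))
    max(c(d, 0)) - min(c(d, 0))
  }
  set.seed(31)
  for (i in 1:20) {
    a <- runif(5, 0, 360); b <- runif(5, 0, 360)
    expect_equal(kuiper_two_sample(a, b, method = "asymptotic")$statistic,
                 kuiper_oracle(a, b), tolerance = 1e-12)
  }
  # permutation p matches full enumeration of label assignments (n small)
  a <- c(10, 100, 200, 250, 300); b <- c(40, 130, 170, 260, 340)
  v_obs <- kuiper_two_sample(a, b, method = "asymptotic")$statistic
  pool <- c(a, b)
  combs <- utils::combn(10, 5)
  v_all <- apply(combs, 2, function(ix) kuiper_oracle(pool[ix], pool[-ix]))
  # mid-p over the full enumeration (ties at half weight), matching the
  # package's permutation convention
  p_exact <- mean(v_all > v_obs + 1e-12) + 0.5 * mean(abs(v_all - v_obs) <= 1e-12)
  p_perm <- kuiper_two_sample(a, b, n_perm = 9999, seed = 5)$p_value
  expect_equal(p_perm, p_exact, tolerance = 0.02)
})

test_that("Kuiper test separates distributions and is rotation invariant", {
  # identical samples attain the minimal V and a p-value near 1
  s <- with_seed_test(17, runif(20, 0, 360))
  expect_warning(kt0 <- kuiper_two_sample(s, s, n_perm = 99), "n_perm")
  expect_equal(kt0$statistic, 0)
  expect_gt(kt0$p_value, 0.9)

  set.seed(7)
  a <- runif(500, 0, 360)
  b <- rvonmises(500, 90, 2)
  kt <- kuiper_two_sample(a, b, n_perm = 999, seed = 1)
  expect_lt(kt$p_value, 0.01)
  # common rotation leaves V unchanged
  v1 <- kuiper_two_sample(a, b, method = "asymptotic")$statistic
  v2 <- kuiper_two_sample(a + 123.4, b + 123.4, method = "asymptotic")$statistic
  expect_lt(abs(v1 - v2), 1e-12)
  expect_error(kuiper_two_sample(numeric(0), b), "nonempty")
})

test_that("anti-aligned fraction counts the 180 +/- window and matches the uniform null", {
  expect_equal(antialigned_fraction(rep(180, 10)), 1.0)
  expect_equal(antialigned_fraction(c(180, 170, 90, 0), 45), 0.5)
  u <- with_seed_test(21, runif(10000, 0, 360))
  se3 <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(antialigned_fraction(u) - 0.25), se3)
  expect_error(antialigned_fraction(1:10, 200), "window")
})

test_that("WSS binning reports per-bin fractions, Wilson CIs and exclusions", {
  rec <- data.frame(wss_pa = c(1, 2, 3, 4, NA), angle_deg = c(180, 0, 170, 90, 180))
  b1 <- bin_by_wss(rec, breaks = c(0, 10))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$n, 4L)
  expect_equal(b1$fraction_antialigned, 0.5)
  expect_equal(attr(b1, "n_excluded"), 1L)
  expect_true(b1$ci_lo < 0.5 && b1$ci_hi > 0.5)
  # empty bins report n = 0 and undefined fraction
  b2 <- bin_by_wss(rec, breaks = c(0, 5, 10, 20))
  expect_equal(b2$n, c(4L, 0L, 0L))
  expect_true(all(is.na(b2$fraction_antialigned[2:3])))
  expect_error(bin_by_wss(rec, breaks = c(3, 2, 1)), "strictly increasing")
})

test_that("threshold shear interpolates the binned curve and handles non-crossing", {
  bp <- data.frame(midpoint_pa = c(2, 6), n = c(50L, 50L),
                   fraction_antialigned = c(0.4, 0.8))
  expect_equal(polarization_threshold_shear(bp, 0.6), 4.0)
  bp_low <- data.frame(midpoint_pa = c(2, 6), n = c(50L, 50L),
                       fraction_antialigned = c(0.2, 0.3))
  expect_true(is.na(polarization_threshold_shear(bp_low, 0.6)))
  one <- data.frame(midpoint_pa = 2, n = 50L, fraction_antialigned = 0.9)
  expect_warning(res <- polarization_threshold_shear(one, 0.6), "nonempty")
  expect_true(is.na(res))
})

test_that("scalar-product regression recovers exact gradients by sign subset", {
  tau <- seq(0.5, 8, length.out = 40)
  # all cells polarized exactly against flow with |p| = 5: s = -5 tau
  rec_neg <- data.frame(scalar_product = -5 * tau, wss_pa = tau)
  fit <- scalar_product_regression(rec_neg)
  neg <- fit[fit$subset == "negative", ]
  expect_equal(neg$gradient, -5, tolerance = 1e-10)
  expect_equal(neg$r_value, -1, tolerance = 1e-10)
  expect_false(fit$available[fit$subset == "positive"])
  # all with flow: gradient +5
  fit2 <- scalar_product_regression(data.frame(scalar_product = 5 * tau,
                                               wss_pa = tau))
  expect_equal(fit2$gradient[fit2$subset == "positive"], 5, tolerance = 1e-10)
  # zero scalar products belong to neither subset
  fit3 <- scalar_product_regression(data.frame(scalar_product = c(0, 0, 0, -1, -2, -3),
                                               wss_pa = c(1, 2, 3, 1, 2, 3)))
  expect_equal(fit3$n[fit3$subset == "negative"], 3L)
  expect_equal(fit3$n[fit3$subset == "positive"], 0L)
})

test_that("angle histogram covers the circle in fixed bins", {
  h <- angle_histogram(c(0, 5, 15, 355), 10)
  expect_equal(nrow(h), 36)
  expect_equal(sum(h$count), 4L)
  expect_equal(h$count[1], 2L)   # 0 and 5
  expect_equal(h$count[36], 1L)  # 355
})
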