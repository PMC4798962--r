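# Circular statistics for endothelial polarity angles.
#
# Angles are in degrees on [0, 360), measured counter-clockwise from the local
# flow direction: 0 = polarized with flow, 180 = polarized against flow.

#' Draw from a von Mises distribution
#'
#' Samples circular data with mean direction `mu_deg` and concentration
#' `kappa` using the Best-Fisher rejection algorithm. `kappa = 0` gives the
#' uniform circular distribution.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction, degrees.
#' @param kappa Concentration parameter (>= 0); larger is tighter.
#' @return Numeric vector of angles in degrees on [0, 360).
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  stop_if_not(is_scalar_num(kappa) && kappa >= 0, "kappa must be >= 0")
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-9) return(fold_angle(stats::runif(n, 0, 360)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  fold_angle(mu_deg + rad2deg(out[seq_len(n)]))
}

#' Rayleigh test of circular uniformity
#'
#' @param angles_deg Angles in degrees.
#' @return List with `R_bar` (mean resultant length), `statistic`
#'   (Z = n * R_bar^2) and `p_value` (second-order approximation).
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  stop_if_not(n >= 2, "Rayleigh test needs n >= 2 angles")
  th <- deg2rad(angles_deg)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(R_bar = rbar, statistic = z, p_value = min(max(p, 0), 1))
}

#' Circular mean direction with confidence arc
#'
#' Computes the mean direction, mean resultant length and the standard
#' large-sample confidence arc for the mean (via the circular dispersion),
#' plus a Rayleigh test of uniformity. The confidence arc is reported only
#' when uniformity is rejected at `alpha`; otherwise the mean direction is
#' not meaningfully localized and `ci_halfwidth_deg` is `NA`.
#'
#' @param angles_deg Angles in degrees (n >= 2).
#' @param alpha Significance level for the uniformity test and 1-alpha arc.
#' @return Object of class `angular_summary`: list with `n`,
#'   `mean_angle_deg`, `resultant_length`, `ci95_halfwidth_deg`,
#'   `significantly_polarized`, `rayleigh_p`.
#' @export
circular_mean_ci <- function(angles_deg, alpha = 0.05) {
  n <- length(angles_deg)
  stop_if_not(n >= 2, "need at least 2 angles")
  th <- deg2rad(angles_deg)
  C <- mean(cos(th)); S <- mean(sin(th))
  rbar <- sqrt(C^2 + S^2)
  mu <- fold_angle(rad2deg(atan2(S, C)))
  rt <- rayleigh_test(angles_deg)
  signif <- rt$p_value < alpha
  hw <- NA_real_
  if (signif && rbar > 0) {
    m2 <- mean(cos(2 * (th - deg2rad(mu))))
    disp <- (1 - m2) / (2 * rbar^2)          # circular dispersion
    sarg <- stats::qnorm(1 - alpha / 2) * sqrt(disp / n)
    hw <- if (sarg <= 1) rad2deg(asin(sarg)) else NA_real_
  }
  structure(list(n = n, mean_angle_deg = mu, resultant_length = rbar,
                 ci95_halfwidth_deg = hw, significantly_polarized = signif,
                 rayleigh_p = rt$p_value),
            class = "angular_summary")
}

#' @export
print.angular_summary <- function(x, ...) {
  cat(sprintf("Angular summary (n = %d)\n", x$n))
  cat(sprintf("  mean direction: %.2f deg  (resultant length %.3f)\n",
              x$mean_angle_deg, x$resultant_length))
  if (!is.na(x$ci95_halfwidth_deg))
    cat(sprintf("  confidence arc: +/- %.2f deg\n", x$ci95_halfwidth_deg))
  cat(sprintf("  Rayleigh p = %.3g (%spolarized)\n", x$rayleigh_p,
              if (x$significantly_polarized) "" else "not "))
  invisible(x)
}

# Two-sample Kuiper statistic V = max(F1 - F2) + max(F2 - F1) over the pooled
# sample, with ties between samples aggregated so both ECDFs jump together.
# Rotation-invariant by construction (the difference path starts and ends at 0).
kuiper_statistic <- function(a_deg, b_deg) {
  a <- fold_angle(a_deg); b <- fold_angle(b_deg)
  n1 <- length(a); n2 <- length(b)
  x <- c(a, b)
  w <- c(rep(1 / n1, n1), rep(-1 / n2, n2))
  o <- order(x)
  xs <- x[o]
  d <- cumsum(w[o])
  # evaluate the ECDF difference only at the last index of each tied value
  last <- c(xs[-1] != xs[-length(xs)], TRUE)
  dv <- d[last]
  max(dv, 0) - min(dv, 0)
}

#' Two-sample Kuiper test for circular data
#'
#' The Kuiper test is the rotation-invariant circular analogue of the
#' two-sample Kolmogorov-Smirnov test, with statistic
#' V = max(D+) + max(D-) between the two empirical circular CDFs. The
#' p-value is obtained by permutation of pooled sample labels (default) or by
#' Stephens' asymptotic series.
#'
#' With equal sample sizes the statistic takes values on a coarse grid, so
#' ties between the observed and permuted statistics are common; the
#' permutation p-value therefore uses the mid-p convention (ties counted at
#' half weight), which keeps the empirical type-I error at its nominal level
#' where the plain counting rule would be conservative.
#'
#' @param a_deg,b_deg Angle samples in degrees (both nonempty).
#' @param n_perm Number of label permutations (permutation method).
#' @param seed Integer seed for the permutation draw (optional).
#' @param method `"permutation"` or `"asymptotic"`.
#' @return List with `statistic` (V), `p_value`, `method`, `n_a`, `n_b`.
#' @export
kuiper_two_sample <- function(a_deg, b_deg, n_perm = 9999, seed = NULL,
                              method = c("permutation", "asymptotic")) {
  method <- match.arg(method)
  stop_if_not(length(a_deg) > 0 && length(b_deg) > 0,
              "both samples must be nonempty")
  n1 <- length(a_deg); n2 <- length(b_deg)
  V <- kuiper_statistic(a_deg, b_deg)
  if (method == "asymptotic") {
    ne <- n1 * n2 / (n1 + n2)
    lam <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
    j <- 1:100
    p <- 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
    p <- min(max(p, 0), 1)
  } else {
    if (n_perm < 100)
      warning("n_perm < 100 gives a very coarse permutation p-value")
    x <- fold_angle(c(a_deg, b_deg))
    o <- order(x)
    xs <- x[o]
    last <- c(xs[-1] != xs[-length(xs)], TRUE)
    w0 <- c(rep(1 / n1, n1), rep(-1 / n2, n2))
    perm_v <- function() {
      vapply(seq_len(n_perm), function(i) {
        d <- cumsum(sample(w0))[last]
        max(d, 0) - min(d, 0)
      }, numeric(1))
    }
    vp <- if (is.null(seed)) perm_v() else with_seed(seed, perm_v())
    n_gt <- sum(vp > V + 1e-12)
    n_eq <- sum(abs(vp - V) <= 1e-12)
    p <- min(1, (0.5 + n_gt + 0.5 * n_eq) / (n_perm + 1))
  }
  list(statistic = V, p_value = p, method = method, n_a = n1, n_b = n2)
}

#' Fraction of cells polarized against the flow
#'
#' Fraction of angles within `window_deg` of anti-parallel, i.e. inside
#' [180 - window, 180 + window] degrees relative to flow.
#'
#' @param angles_deg Angles in degrees.
#' @param window_deg Half-window around 180 degrees; default 45.
#' @return Fraction in [0, 1].
#' @export
antialigned_fraction <- function(angles_deg, window_deg = 45) {
  stop_if_not(is_scalar_num(window_deg) && window_deg > 0 && window_deg < 180,
              "window_deg must lie in (0, 180)")
  a <- fold_angle(angles_deg)
  mean(a >= 180 - window_deg & a <= 180 + window_deg)
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Bin anti-alignment fraction by wall shear stress
#'
#' Bins cell records by WSS magnitude and reports, per bin, the number of
#' cells and the fraction polarized within `window_deg` of anti-parallel to
#' flow, with Wilson binomial confidence intervals. Bins are half-open
#' [lo, hi) with the last bin closed. Default bin edges are deciles of the
#' observed WSS distribution; pass `breaks` for fixed edges.
#'
#' @param records Data frame with columns `wss_pa` and `angle_deg`
#'   (rows with missing WSS are excluded and counted).
#' @param breaks Strictly increasing bin edges in Pa, or `NULL` for
#'   `n_bins` quantile bins.
#' @param n_bins Number of quantile bins when `breaks` is `NULL`.
#' @param window_deg Anti-alignment half-window, degrees.
#' @param conf_level Confidence level for the Wilson intervals.
#' @return Object of class `binned_polarization`: data frame with columns
#'   `bin_lo`, `bin_hi`, `midpoint_pa`, `n`, `fraction_antialigned`,
#'   `ci_lo`, `ci_hi`; attribute `n_excluded` counts records without WSS.
#' @export
bin_by_wss <- function(records, breaks = NULL, n_bins = 10, window_deg = 45,
                       conf_level = 0.95) {
  stop_if_not(all(c("wss_pa", "angle_deg") %in% names(records)),
              "records must have columns wss_pa and angle_deg")
  keep <- is.finite(records$wss_pa) & is.finite(records$angle_deg)
  n_excluded <- sum(!keep)
  wss <- records$wss_pa[keep]
  ang <- fold_angle(records$angle_deg[keep])
  if (is.null(breaks)) {
    breaks <- unique(stats::quantile(wss, probs = seq(0, 1, length.out = n_bins + 1),
                                     names = FALSE, type = 7))
    stop_if_not(length(breaks) >= 2, "WSS distribution is degenerate: cannot bin")
  }
  stop_if_not(all(diff(breaks) > 0), "bin edges must be strictly increasing")
  nb <- length(breaks) - 1L
  idx <- findInterval(wss, breaks, rightmost.closed = TRUE)
  in_range <- idx >= 1L & idx <= nb
  n_excluded <- n_excluded + sum(!in_range)
  idx <- idx[in_range]; ang <- ang[in_range]
  anti <- ang >= 180 - window_deg & ang <= 180 + window_deg
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  out$midpoint_pa <- (out$bin_lo + out$bin_hi) / 2
  out$n <- as.integer(tabulate(idx, nbins = nb))
  k <- vapply(seq_len(nb), function(b) sum(anti[idx == b]), numeric(1))
  out$fraction_antialigned <- ifelse(out$n > 0, k / out$n, NA_real_)
  ci <- t(vapply(seq_len(nb), function(b) wilson_ci(k[b], out$n[b], conf_level),
                 numeric(2)))
  out$ci_lo <- ci[, 1]; out$ci_hi <- ci[, 2]
  structure(out, n_excluded = n_excluded, window_deg = window_deg,
            class = c("binned_polarization", "data.frame"))
}

#' Shear at which the anti-aligned fraction first reaches a target
#'
#' Linearly interpolates the binned anti-aligned fraction against bin
#' midpoints and returns the smallest WSS at which the curve first reaches
#' `target_fraction`. This generalizes the threshold readout "shear needed
#' for X% of cells to polarize against flow".
#'
#' @param binned A `binned_polarization` object (or data frame with
#'   `midpoint_pa`, `n`, `fraction_antialigned`).
#' @param target_fraction Target fraction in (0, 1); default 0.6.
#' @return Crossing shear in Pa, or `NA` if the target is never reached
#'   (or fewer than 2 nonempty bins, with a warning).
#' @export
polarization_threshold_shear <- function(binned, target_fraction = 0.6) {
  stop_if_not(is_scalar_num(target_fraction) &&
                target_fraction > 0 && target_fraction < 1,
              "target_fraction must lie in (0, 1)")
  ok <- binned$n > 0 & is.finite(binned$fraction_antialigned)
  x <- binned$midpoint_pa[ok]
  y <- binned$fraction_antialigned[ok]
  if (length(x) < 2) {
    warning("fewer than 2 nonempty bins; threshold shear undefined")
    return(NA_real_)
  }
  if (y[1] >= target_fraction) return(x[1])
  for (i in seq_len(length(x) - 1)) {
    if (y[i] < target_fraction && y[i + 1] >= target_fraction) {
      return(x[i] + (target_fraction - y[i]) / (y[i + 1] - y[i]) *
               (x[i + 1] - x[i]))
    }
  }
  NA_real_
}

#' Monotone trend test for binned anti-alignment
#'
#' One-sided Kendall rank correlation of the per-bin anti-aligned fraction
#' against the bin midpoint, testing for an increasing trend of polarization
#' with WSS (the expected signature of a shear-threshold response).
#'
#' @param binned A `binned_polarization` object.
#' @return List with `tau` and `p_value` (alternative: increasing).
#' @export
antialignment_trend_test <- function(binned) {
  ok <- binned$n > 0 & is.finite(binned$fraction_antialigned)
  stop_if_not(sum(ok) >= 3, "need at least 3 nonempty bins for a trend test")
  ct <- suppressWarnings(
    stats::cor.test(binned$midpoint_pa[ok], binned$fraction_antialigned[ok],
                    method = "kendall", alternative = "greater"))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}

#' Scalar-product regression against WSS
#'
#' Splits cells by the sign of the scalar product s = |p| * tau * cos(theta)
#' and fits ordinary least squares of s against WSS separately for the
#' positive (with-flow) and negative (against-flow) subsets. The fitted
#' gradient estimates |p| * cos(theta), the projection of the polarity vector
#' onto the flow axis; a more negative gradient in the negative subset means
#' stronger polarization against flow for a given WSS.
#'
#' @param records Data frame with columns `scalar_product` and `wss_pa`.
#' @return Data frame of class `scalar_regression` with one row per subset
#'   (`positive`, `negative`): `gradient` (um), `intercept` (um Pa),
#'   `r_value`, `n`, `available`.
#' @export
scalar_product_regression <- function(records) {
  stop_if_not(all(c("scalar_product", "wss_pa") %in% names(records)),
              "records must have columns scalar_product and wss_pa")
  ok <- is.finite(records$scalar_product) & is.finite(records$wss_pa)
  s <- records$scalar_product[ok]
  tau <- records$wss_pa[ok]
  fit_one <- function(subset) {
    sel <- if (subset == "positive") s > 0 else s < 0
    n <- sum(sel)
    if (n < 3) {
      return(data.frame(subset = subset, gradient = NA_real_,
                        intercept = NA_real_, r_value = NA_real_,
                        n = n, available = FALSE))
    }
    fit <- stats::lm.fit(cbind(1, tau[sel]), s[sel])
    r <- if (stats::sd(tau[sel]) > 0 && stats::sd(s[sel]) > 0)
      stats::cor(tau[sel], s[sel]) else NA_real_
    data.frame(subset = subset, gradient = unname(fit$coefficients[2]),
               intercept = unname(fit$coefficients[1]), r_value = r,
               n = n, available = TRUE)
  }
  out <- rbind(fit_one("positive"), fit_one("negative"))
  class(out) <- c("scalar_regression", "data.frame")
  out
}

#' Angle histogram for rose plots
#'
#' Counts angles in fixed-width bins (default 10 degrees), ready for
#' external rose-plot rendering.
#'
#' @param angles_deg Angles in degrees.
#' @param bin_width_deg Bin width; must divide 360.
#' @return Data frame with `bin_lo_deg`, `bin_hi_deg`, `count`.
#' @export
angle_histogram <- function(angles_deg, bin_width_deg = 10) {
  stop_if_not(360 %% bin_width_deg == 0, "bin width must divide 360")
  a <- fold_angle(angles_deg)
  nb <- 360 / bin_width_deg
  idx <- pmin(floor(a / bin_width_deg) + 1, nb)
  data.frame(bin_lo_deg = (seq_len(nb) - 1) * bin_width_deg,
             bin_hi_deg = seq_len(nb) * bin_width_deg,
             count = as.integer(tabulate(idx, nbins = nb)))
}
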