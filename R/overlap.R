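#' Overlapping coefficient of two normal densities
#'
#' Computes the overlapping coefficient (OVL) of two univariate normal
#' distributions: the area under the pointwise minimum of the two densities,
#' \eqn{\int \min(f_1, f_2)\,dx}. The OVL is bounded in \[0, 1\] and equals 1
#' exactly when the two distributions coincide. In test-retest analysis it is
#' read as the probability that two measures are "the same".
#'
#' The computation is analytic. When the two standard deviations are equal
#' (within relative tolerance 1e-12), the closed form
#' \eqn{2\Phi(-|\mu_1-\mu_2|/(2\sigma))} is used. Otherwise the two points
#' where the densities cross are obtained by equating log-densities (a
#' quadratic in x), and the OVL is the sum of normal CDF masses of the
#' pointwise-smaller density over the three segments the crossings delimit;
#' which density is smaller on a segment is decided by evaluating both at an
#' interior point.
#'
#' @param mu1,mu2 Means of the two distributions.
#' @param sigma1,sigma2 Standard deviations; must be positive.
#' @return The overlapping coefficient, a single number in \[0, 1\].
#' @seealso [ovl_numeric()] for the grid-integration cross-check,
#'   [vo2_compare()] for the device-aware front end.
#' @examples
#' ovl_normal(0, 1, 2, 1)      # equal variances: 2 * pnorm(-1)
#' ovl_normal(1.5, 0.06, 1.5, 0.06)  # identical: 1
#' @export
ovl_normal <- function(mu1, sigma1, mu2, sigma2) {
  check_scalar_number(mu1, "mu1")
  check_scalar_number(mu2, "mu2")
  check_scalar_number(sigma1, "sigma1", positive = TRUE)
  check_scalar_number(sigma2, "sigma2", positive = TRUE)

  if (abs(sigma1 - sigma2) <= 1e-12 * max(sigma1, sigma2)) {
    return(2 * stats::pnorm(-abs(mu1 - mu2) / (2 * sigma1)))
  }

  # Canonical argument order makes the result bitwise-symmetric under swap.
  if (sigma2 < sigma1 || (sigma2 == sigma1 && mu2 < mu1)) {
    tmp <- mu1; mu1 <- mu2; mu2 <- tmp
    tmp <- sigma1; sigma1 <- sigma2; sigma2 <- tmp
  }

  # log f1(x) = log f2(x)  <=>  A x^2 + B x + C = 0
  a <- 1 / sigma2^2 - 1 / sigma1^2
  b <- -2 * (mu2 / sigma2^2 - mu1 / sigma1^2)
  cc <- mu2^2 / sigma2^2 - mu1^2 / sigma1^2 - 2 * log(sigma1 / sigma2)
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) {
    # Unequal sigmas always cross twice in exact arithmetic; a non-positive
    # discriminant only arises from rounding when sigmas are nearly equal.
    return(2 * stats::pnorm(-abs(mu1 - mu2) / (sigma1 + sigma2)))
  }
  roots <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))

  lower <- c(-Inf, roots[1], roots[2])
  upper <- c(roots[1], roots[2], Inf)
  total <- 0
  for (i in 1:3) {
    mid <- if (is.infinite(lower[i])) {
      upper[i] - 1
    } else if (is.infinite(upper[i])) {
      lower[i] + 1
    } else {
      (lower[i] + upper[i]) / 2
    }
    # compare on the log scale: far from both means the densities underflow
    # to 0 and would tie, misassigning the segment
    if (stats::dnorm(mid, mu1, sigma1, log = TRUE) <=
        stats::dnorm(mid, mu2, sigma2, log = TRUE)) {
      total <- total + stats::pnorm(upper[i], mu1, sigma1) - stats::pnorm(lower[i], mu1, sigma1)
    } else {
      total <- total + stats::pnorm(upper[i], mu2, sigma2) - stats::pnorm(lower[i], mu2, sigma2)
    }
  }
  min(max(total, 0), 1)
}

#' Overlapping coefficient by brute-force grid integration
#'
#' Trapezoidal integration of the pointwise minimum of the two normal
#' densities over \eqn{[\min(\mu) - 8\max(\sigma),\ \max(\mu) + 8\max(\sigma)]}.
#' Exists as an independent numerical oracle for [ovl_normal()]; use the
#' analytic function for real work.
#'
#' @inheritParams ovl_normal
#' @param grid_step Integration step; must be positive.
#' @return Approximate overlapping coefficient.
#' @export
ovl_numeric <- function(mu1, sigma1, mu2, sigma2, grid_step = 1e-4) {
  check_scalar_number(mu1, "mu1")
  check_scalar_number(mu2, "mu2")
  check_scalar_number(sigma1, "sigma1", positive = TRUE)
  check_scalar_number(sigma2, "sigma2", positive = TRUE)
  check_scalar_number(grid_step, "grid_step", positive = TRUE)

  lo <- min(mu1, mu2) - 8 * max(sigma1, sigma2)
  hi <- max(mu1, mu2) + 8 * max(sigma1, sigma2)
  x <- seq(lo, hi, by = grid_step)
  f <- pmin(stats::dnorm(x, mu1, sigma1), stats::dnorm(x, mu2, sigma2))
  n <- length(f)
  sum((f[-1] + f[-n]) / 2) * grid_step
}

#' Solve for the common sigma giving a target overlap
#'
#' Inverts the equal-variance closed form: finds the unique \eqn{\sigma} with
#' \eqn{2\Phi(-\delta/(2\sigma)) =} `target_ovl` by bracketing root-find.
#' Used to initialize calibration recovery (one equal-variance sigma per
#' printed worked example).
#'
#' @param delta Absolute difference between the two means (L/min); > 0.
#' @param target_ovl Target overlapping coefficient, strictly in (0, 1).
#' @return The solving sigma (L/min).
#' @export
solve_sigma_equal <- function(delta, target_ovl) {
  check_scalar_number(delta, "delta", positive = TRUE)
  check_scalar_number(target_ovl, "target_ovl")
  if (target_ovl <= 0 || target_ovl >= 1) {
    abort_invalid_input(sprintf(
      "`target_ovl` must lie strictly in (0, 1); got %g", target_ovl
    ))
  }
  # 2*pnorm(-delta/(2*sigma)) is increasing in sigma: invert directly, then
  # polish with uniroot for a forward-check-tight answer.
  sigma0 <- -delta / (2 * stats::qnorm(target_ovl / 2))
  f <- function(s) 2 * stats::pnorm(-delta / (2 * s)) - target_ovl
  stats::uniroot(f, lower = sigma0 / 2, upper = sigma0 * 2, tol = 1e-14)$root
}
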