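# Composite-null machinery: the node-level max-p statistic is referred to a
# three-component mixture
#   Pr(Pmax <= p) = pi00 p^2 + pi10 p Pr(Pa <= p | a != 0)
#                             + pi01 p Pr(Pb <= p | b != 0)
# whose weights are estimated across all nodes and whose alternative power
# functions are estimated nonparametrically.

#' Estimate the proportion of null hypotheses from p-values
#'
#' Empirical characteristic function estimator of the proportion of true
#' nulls among a set of test p-values. P-values are converted to z-scores
#' (`sign * qnorm(1 - p/2)` when coefficient signs are supplied, one-sided
#' `qnorm(1 - p)` otherwise) and the estimator is the infimum over
#' `t in [0, sqrt(log J)]` of
#' `int_{-1}^{1} (1 - |xi|) Re(phi_J(t xi)) exp(t^2 xi^2 / 2) dxi`,
#' where `phi_J` is the empirical characteristic function of the z-scores.
#' The integral is evaluated by the trapezoid rule on a 201-point grid in
#' `xi` and the infimum over a 101-point grid in `t`; the result is clamped
#' to `[1/J, 1]`.
#'
#' @param p_values vector of p-values (at least 20).
#' @param signs optional vector of coefficient signs (+1/-1) for the signed
#'   z-conversion.
#' @param xi_points,t_points quadrature grid sizes.
#' @return estimated null proportion in `[1/J, 1]`.
#' @export
estimate_pi0 <- function(p_values, signs = NULL,
                         xi_points = 201L, t_points = 101L) {
  p <- .clamp_p(p_values)
  J <- length(p)
  if (J < 20L) {
    warning("fewer than 20 p-values; returning pi0 = 1", call. = FALSE)
    return(1)
  }
  if (is.null(signs)) {
    z <- qnorm(1 - p)
  } else {
    stopifnot(length(signs) == J)
    s <- ifelse(signs >= 0, 1, -1)
    z <- s * qnorm(1 - p / 2)
  }

  t_max <- sqrt(log(J))
  t_grid <- seq(0, t_max, length.out = t_points)
  # the integrand is even in xi, so integrate on [0, 1] and double; the
  # half-grid trapezoid doubled is identical to the full 2*m - 1 point rule
  m <- (xi_points + 1L) %/% 2L
  xi <- seq(0, 1, length.out = m)
  w_xi <- rep(1 / (m - 1), m); w_xi[c(1L, m)] <- 0.5 / (m - 1)  # trapezoid
  S <- outer(t_grid, xi)                       # t_points x m matrix of t*xi
  phi_re <- matrix(rowMeans(cos(outer(as.vector(S), z))),
                   nrow = t_points)
  integrand <- (matrix(1 - xi, t_points, m, byrow = TRUE)) *
    phi_re * exp(S^2 / 2)
  vals <- 2 * drop(integrand %*% w_xi)          # symmetry: double [0, 1]
  est <- min(vals)
  min(max(est, 1 / J), 1)
}

#' Combine marginal null proportions into the three-part null mixture
#'
#' Given the estimated proportions of nodes null for the treatment-mediator
#' association (`pi0_alpha`) and for the mediator-outcome association
#' (`pi0_beta`), forms the mixture weights `(pi00, pi10, pi01)` of the
#' composite no-mediation null. Two estimators of the overall null
#' proportion `pi0` are supported: `"product"` uses
#' `pi0 = pi0_alpha + pi0_beta - pi0_alpha * pi0_beta`; `"maxp"` plugs in a
#' direct estimate obtained from the max-p statistics (argument `pi0_max`).
#' Negative components (possible in finite samples under `"maxp"`) are
#' clamped to zero and the triple renormalised to sum to one.
#'
#' @param pi0_alpha,pi0_beta marginal null-proportion estimates in `[0, 1]`.
#' @param pi0_max direct estimate of the overall null proportion (required
#'   for `approach = "maxp"`).
#' @param approach `"product"` or `"maxp"`.
#' @return list of class `null_mix` with components `pi00`, `pi10`, `pi01`,
#'   `pi0_alpha`, `pi0_beta`, `pi0`, `approach`.
#' @examples
#' combine_null_proportions(0.8, 0.9)  # pi0 = 0.98, pi00 = 0.72/0.98, ...
#' @export
combine_null_proportions <- function(pi0_alpha, pi0_beta, pi0_max = NULL,
                                     approach = c("product", "maxp")) {
  approach <- match.arg(approach)
  stopifnot(pi0_alpha >= 0, pi0_alpha <= 1, pi0_beta >= 0, pi0_beta <= 1)
  if (approach == "product") {
    pi0 <- pi0_alpha + pi0_beta - pi0_alpha * pi0_beta
    comp <- c(pi00 = pi0_alpha * pi0_beta,
              pi10 = (1 - pi0_alpha) * pi0_beta,
              pi01 = pi0_alpha * (1 - pi0_beta)) / pi0
  } else {
    if (is.null(pi0_max)) {
      stop("'pi0_max' is required for the maxp approach", call. = FALSE)
    }
    pi0 <- pi0_max
    if (pi0 <= 0) stop("pi0 must be positive", call. = FALSE)
    comp <- c(pi00 = (pi0_alpha + pi0_beta - pi0) / pi0,
              pi10 = (pi0 - pi0_alpha) / pi0,
              pi01 = (pi0 - pi0_beta) / pi0)
  }
  comp <- pmax(comp, 0)
  comp <- comp / sum(comp)
  structure(list(pi00 = unname(comp[1L]), pi10 = unname(comp[2L]),
                 pi01 = unname(comp[3L]),
                 pi0_alpha = pi0_alpha, pi0_beta = pi0_beta, pi0 = pi0,
                 approach = approach),
            class = "null_mix")
}

#' @export
print.null_mix <- function(x, ...) {
  cat(sprintf("Null mixture (%s): pi00 = %.3f, pi10 = %.3f, pi01 = %.3f\n",
              x$approach, x$pi00, x$pi10, x$pi01))
  invisible(x)
}

#' Grenander estimate of a decreasing p-value density
#'
#' Computes the nonparametric maximum likelihood estimate of a decreasing
#' density on `[0, 1]`: the left derivative of the least concave majorant
#' (LCM) of the empirical CDF of the p-values. Returned as the LCM knots and
#' the constant density value on each inter-knot interval.
#'
#' @param p_values p-values in `(0, 1]`.
#' @return list with `knots` (increasing, starting at 0 and ending at 1),
#'   `ecdf_knots` (LCM heights at the knots), and `slopes` (density on each
#'   of the `length(knots) - 1` intervals, non-increasing).
#' @export
grenander_density <- function(p_values) {
  p <- sort(p_values)
  if (any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  n <- length(p)
  ux <- unique(p)
  uy <- cumsum(tabulate(match(p, ux))) / n
  x <- c(0, ux)
  y <- c(0, uy)
  if (x[length(x)] < 1) {
    x <- c(x, 1)
    y <- c(y, 1)
  }
  # least concave majorant: upper hull by a monotone stack over the sorted
  # points; slopes along the hull are strictly decreasing
  keep <- c(1L, 2L)
  for (i in seq(3L, length(x))) {
    while (length(keep) >= 2L) {
      a <- keep[length(keep) - 1L]
      b <- keep[length(keep)]
      s1 <- (y[b] - y[a]) / (x[b] - x[a])
      s2 <- (y[i] - y[b]) / (x[i] - x[b])
      if (s2 >= s1 - 1e-12) keep <- keep[-length(keep)] else break
    }
    keep <- c(keep, i)
  }
  kx <- x[keep]
  ky <- y[keep]
  list(knots = kx, ecdf_knots = ky, slopes = diff(ky) / diff(kx))
}

#' Estimated CDF of p-values under the alternative
#'
#' Estimates the power function `Pr(P <= p | alternative)` for one of the
#' two association tests. The marginal p-value density is estimated by the
#' Grenander estimator; under the composite null this density is the mixture
#' `f(p) = pi_alt f(p | alt) + pi_null`, where `pi_null` is the total weight
#' of the components under which the p-value is uniform (`pi00 + pi01` for
#' the treatment association, `pi00 + pi10` for the outcome association).
#' The conditional density is recovered as
#' `max((f(p) - pi_null) / pi_alt, 0)`, integrated to a CDF, and
#' renormalised to reach 1 at `p = 1`. Evaluation at arbitrary points is by
#' linear interpolation of the integrated piecewise-constant density.
#'
#' @param p_values the observed p-values of the relevant association test at
#'   all (non-degenerate) nodes.
#' @param null_mix a [combine_null_proportions()] result.
#' @param which `"alpha"` (treatment-mediator) or `"beta"`
#'   (mediator-outcome).
#' @return a function mapping p-values to estimated alternative CDF values;
#'   the constant-1 function when the alternative mass is zero.
#' @export
grenander_alt_cdf <- function(p_values, null_mix,
                              which = c("alpha", "beta")) {
  which <- match.arg(which)
  pi_null <- if (which == "alpha") {
    null_mix$pi00 + null_mix$pi01
  } else {
    null_mix$pi00 + null_mix$pi10
  }
  pi_alt <- 1 - pi_null
  if (pi_alt <= 0) {
    return(function(q) rep(1, length(q)))
  }
  if (length(unique(p_values)) == 1L) {
    warning("all p-values identical; degenerate step CDF", call. = FALSE)
    p0 <- p_values[1L]
    return(function(q) as.numeric(q >= p0))
  }
  gren <- grenander_density(p_values)
  f_alt <- pmax((gren$slopes - pi_null) / pi_alt, 0)
  cdf <- c(0, cumsum(f_alt * diff(gren$knots)))
  total <- cdf[length(cdf)]
  if (total <= 0) {
    return(function(q) rep(1, length(q)))
  }
  cdf <- cdf / total
  approxfun(gren$knots, cdf, method = "linear", yleft = 0, yright = 1,
            rule = 2)
}

#' Mixture p-value for the composite no-mediation null
#'
#' Converts a node's max-p statistic into its mediation test p-value under
#' the estimated three-component null mixture:
#' `p = pi00 pmax^2 + pi10 pmax F_alpha(pmax) + pi01 pmax F_beta(pmax)`,
#' where `F_alpha`, `F_beta` are the estimated alternative CDFs of the two
#' association p-values evaluated at `pmax`.
#'
#' @param p_max max-p statistic(s) in `[0, 1]`.
#' @param null_mix a [combine_null_proportions()] result.
#' @param power_alpha,power_beta alternative CDF values at `p_max`, in
#'   `[0, 1]` (vectors recycled against `p_max`).
#' @return mediation p-value(s) in `(0, 1]`.
#' @examples
#' nm <- combine_null_proportions(0.8, 0.9)
#' mixture_pvalue(0.1, nm, 1, 1)
#' @export
mixture_pvalue <- function(p_max, null_mix, power_alpha, power_beta) {
  stopifnot(all(p_max >= 0 & p_max <= 1),
            all(power_alpha >= 0 & power_alpha <= 1),
            all(power_beta >= 0 & power_beta <= 1))
  p <- null_mix$pi00 * p_max^2 +
    null_mix$pi10 * p_max * power_alpha +
    null_mix$pi01 * p_max * power_beta
  pmin(pmax(p, 1e-300), 1)
}

# Full composite-null stage: from node-level association p-values (and
# signs) to per-node mediation p-values. Returns the null_mix and p_j's.
.composite_stage <- function(p_alpha, p_beta, sign_alpha, sign_beta,
                             approach = c("product", "maxp")) {
  approach <- match.arg(approach)
  p_alpha <- .clamp_p(p_alpha)
  p_beta <- .clamp_p(p_beta)
  pi0_a <- estimate_pi0(p_alpha, signs = sign_alpha)
  pi0_b <- estimate_pi0(p_beta, signs = sign_beta)
  p_max <- pmax(p_alpha, p_beta)
  pi0_max <- if (approach == "maxp") estimate_pi0(p_max) else NULL
  nm <- combine_null_proportions(pi0_a, pi0_b, pi0_max, approach)
  f_a <- grenander_alt_cdf(p_alpha, nm, "alpha")
  f_b <- grenander_alt_cdf(p_beta, nm, "beta")
  p_med <- mixture_pvalue(p_max, nm, f_a(p_max), f_b(p_max))
  list(null_mix = nm, p_max = p_max, p_mediation = p_med)
}
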