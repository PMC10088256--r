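# Community-level inference: harmonic-mean combination of the node-level
# mediation p-values (heavy-tailed Landau null) and Benjamini-Hochberg
# selection of mediating nodes.

# Upper tail P(X > lam) of the standard Landau distribution
# (stable law with index 1 and maximal skewness, scale pi/2, in the
# convention with characteristic function exp(-(pi/2)|t| - i t log|t|)).
# Three regimes:
#   lam > 300   : asymptotic series 1/lam + (log(lam) + gamma - 1)/lam^2
#   1 <= lam <= 300 : direct tail integral
#                 (1/pi) Int_0^inf exp(-t log t - lam t) sin(pi t)/t dt
#   lam < 1     : Gil-Pelaez inversion of the characteristic function
# All quadrature is piecewise on short intervals, so the oscillating factors
# are resolved.
.plandau_upper <- function(lam) {
  vapply(lam, function(l) {
    if (!is.finite(l)) return(if (l > 0) 0 else 1)
    if (l > 300) {
      # expansion of the tail integral in powers of 1/l (log-weighted)
      g <- .EULER_GAMMA
      ll <- log(l)
      t3 <- (2 * ll^2 - 2 * (3 - 2 * g) * ll +
               2 * ((1.5 - g)^2 + pi^2 / 6 - 1.25)) / (2 * l^3) -
        pi^2 / (3 * l^3)
      return(1 / l + (ll + g - 1) / l^2 + t3)
    }
    if (l >= 1) {
      g <- function(t) ifelse(t <= 0, pi,
                              exp(-t * log(t) - l * t) * sin(pi * t) / t)
      up <- max(5, 80 / l)
      tot <- .piecewise_integral(g, 0, up, step = 0.5)
      tot <- tot + integrate(g, up, Inf, rel.tol = 1e-10,
                             subdivisions = 200L)$value
      return(min(max(tot / pi, 0), 1))
    }
    if (l < -60) return(1)
    # CDF via Gil-Pelaez; SF = 1 - CDF
    g <- function(t) ifelse(t <= 0, l,
                            exp(-pi * t / 2) * sin(t * l + t * log(t)) / t)
    per <- 2 * pi / max(abs(l) + 3, 4)   # resolve the oscillation
    cdf <- 0.5 + .piecewise_integral(g, 0, 60, step = min(0.5, per / 4)) / pi
    min(max(1 - cdf, 0), 1)
  }, numeric(1))
}

.piecewise_integral <- function(g, lo, hi, step) {
  brk <- seq(lo, hi, by = step)
  if (brk[length(brk)] < hi) brk <- c(brk, hi)
  tot <- 0
  for (k in seq_len(length(brk) - 1L)) {
    tot <- tot + integrate(g, brk[k], brk[k + 1L], rel.tol = 1e-10,
                           abs.tol = 1e-13, subdivisions = 50L)$value
  }
  tot
}

#' Harmonic mean p-value combination
#'
#' Combines p-values with the weighted harmonic mean
#' `p_ring = sum(w) / sum(w / p)` and computes the community-level p-value
#' as the tail probability of the harmonic mean's asymptotic null
#' distribution: for `J` tests with weights summing to one,
#' `1 / p_ring` minus `log(J) + 1 - gamma` follows a standard Landau law
#' (the maximally skewed stable law of index 1). The heavy tail makes the
#' combination robust to dependence among the p-values. With a single
#' p-value the combination is exact and returns it unchanged.
#'
#' @param p_values p-values in `(0, 1]`; zeros are clamped to `1e-15` with a
#'   warning.
#' @param weights optional non-negative weights (default equal); normalised
#'   to sum to one.
#' @return list with `p_ring` (the weighted harmonic mean), `global_p`, the
#'   `weights` used, and `J`.
#' @examples
#' hmp_combine(c(0.01, 1))$p_ring  # 1 / 50.5
#' @export
hmp_combine <- function(p_values, weights = NULL) {
  J <- length(p_values)
  if (J == 0L) stop("no p-values supplied", call. = FALSE)
  if (any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(p_values == 0)) {
    warning("zero p-values clamped to 1e-15", call. = FALSE)
    p_values <- pmax(p_values, 1e-15)
  }
  if (is.null(weights)) {
    weights <- rep(1 / J, J)
  } else {
    stopifnot(length(weights) == J, all(weights >= 0), sum(weights) > 0)
    weights <- weights / sum(weights)
  }
  x <- sum(weights / p_values)
  p_ring <- 1 / x
  global_p <- if (J == 1L) {
    p_ring
  } else {
    .plandau_upper(x - log(J) - (1 - .EULER_GAMMA))
  }
  list(p_ring = p_ring, global_p = min(max(global_p, 0), 1),
       weights = weights, J = J)
}

#' Fisher combination of independent p-values
#'
#' `-2 sum(log p)` referred to chi-square with `2J` degrees of freedom.
#' Suitable when the node-level p-values are (asymptotically) independent
#' and the signal is dense; provided as an alternative to [hmp_combine()].
#'
#' @inheritParams hmp_combine
#' @return list with `stat` and `global_p`.
#' @export
fisher_combine <- function(p_values) {
  J <- length(p_values)
  if (J == 0L) stop("no p-values supplied", call. = FALSE)
  p <- pmax(p_values, 1e-300)
  stat <- -2 * sum(log(p))
  list(stat = stat,
       global_p = pchisq(stat, df = 2 * J, lower.tail = FALSE))
}

#' Benjamini-Hochberg selection of significant nodes
#'
#' Standard step-up BH procedure at target FDR `q`.
#'
#' @param p_values p-values.
#' @param q target false discovery rate in `(0, 1)`.
#' @return list with `selected` (indices), `q_bh` (BH-adjusted values).
#' @examples
#' bh_select(c(0.01, 0.02, 0.04, 0.5), q = 0.1)$selected
#' @export
bh_select <- function(p_values, q = 0.05) {
  stopifnot(q > 0, q < 1)
  q_bh <- p.adjust(p_values, method = "BH")
  list(selected = which(q_bh <= q), q_bh = q_bh)
}
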