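# Local association tests for the two regressions of each node-level
# mediation model:
#   (1) E{ logit(M_j) } = alpha_jX' X + alpha_j T        (distribution-free)
#   (2) g{ E(Y) }       = beta_jX' X + beta_jT T + beta_j logit(M_j)
# with g identity (continuous Y) or logit (binary Y). Both null hypotheses
# (alpha_j = 0, beta_j = 0) are tested with classical Rao score statistics
# from the null-restricted fits, referred to chi-square(1), or with
# Freedman-Lane permutation of null-model residuals.

# QR helper: returns Q with orthonormal columns spanning the column space.
.qr_q <- function(X) {
  qr.Q(qr(X))
}

# Score test of the coefficient of `v` added to the linear model y ~ Z
# (Z includes the intercept). Uses the ML dispersion RSS0/n of the null fit.
# Returns the score statistic, its sign, and the chi-square(1) p-value.
.score_linear <- function(y, Z, v) {
  n <- length(y)
  Qz <- .qr_q(Z)
  ry <- y - Qz %*% crossprod(Qz, y)
  rv <- v - Qz %*% crossprod(Qz, v)
  rss0 <- sum(ry^2)
  den <- (rss0 / n) * sum(rv^2)
  if (den <= 0) {
    return(list(stat = NA_real_, sign = 0, p = NA_real_))
  }
  u <- sum(ry * rv)
  stat <- u^2 / den
  list(stat = stat, sign = sign(u),
       p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Efficient score test of the coefficient of `v` added to a logistic model
# y ~ Z, computed from the null-restricted ML fit.
.score_logistic <- function(y, Z, v) {
  fit <- suppressWarnings(glm.fit(Z, y, family = binomial()))
  if (!fit$converged) {
    return(NULL)
  }
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  sw <- sqrt(w)
  Qzw <- .qr_q(Z * sw)
  vw <- v * sw
  den <- sum(vw^2) - sum(crossprod(Qzw, vw)^2)
  if (den <= 0) {
    return(list(stat = NA_real_, sign = 0, p = NA_real_))
  }
  u <- sum((y - mu) * v)
  stat <- u^2 / den
  list(stat = stat, sign = sign(u),
       p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Adaptive Freedman-Lane permutation p-value. `stat_fun(Vres)` maps a matrix
# of permuted, Z-residualised replacement columns to a vector of score
# statistics; `resid0` are the null-model residuals of the permuted variable.
# Permutation stops early once `min_exceed` statistics at least as large as
# the observed one have been seen; p = (b + 1) / (B + 1).
.adaptive_perm <- function(stat_obs, resid0, fitted0, stat_fun,
                           B_max = 10000L, min_exceed = 100L,
                           batch = 500L, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  n <- length(resid0)
  b <- 0L
  B <- 0L
  while (B < B_max && b < min_exceed) {
    nb <- min(batch, B_max - B)
    P <- vapply(seq_len(nb), function(i) resid0[sample.int(n)],
                numeric(n))
    stats <- stat_fun(fitted0 + P)
    b <- b + sum(stats >= stat_obs - 1e-12, na.rm = TRUE)
    B <- B + nb
  }
  list(p = (b + 1) / (B + 1), b = b, B = B)
}

#' Score test of the treatment-mediator association at one node
#'
#' Rao score test of `alpha = 0` in the linear model of the log-ratio
#' mediator on confounders and treatment. The asymptotic reference is
#' chi-square(1); the permutation method permutes the residuals of the
#' treatment regressed on the confounders (Freedman-Lane) and recomputes the
#' score statistic, with adaptive early stopping.
#'
#' @param mediator numeric vector (log-ratio values) for the included
#'   subjects.
#' @param treatment binary 0/1 vector, same length.
#' @param covariates optional numeric matrix of confounders (no intercept
#'   column; one is added internally).
#' @param method `"asymptotic"` or `"permutation"`.
#' @param seed RNG seed for the permutation method.
#' @param B_max,min_exceed adaptive permutation controls: permutation stops
#'   at `B_max` draws or once `min_exceed` exceedances are observed.
#' @return list with `p`, `sign`, `stat`, `method`, and for permutation the
#'   counts `b` and `B`.
#' @export
test_alpha <- function(mediator, treatment, covariates = NULL,
                       method = c("asymptotic", "permutation"),
                       seed = NULL, B_max = 10000L, min_exceed = 100L) {
  method <- match.arg(method)
  keep <- !is.na(mediator)
  m <- mediator[keep]
  tr <- treatment[keep]
  n <- length(m)
  X <- cbind(rep(1, n), if (!is.null(covariates)) {
    as.matrix(covariates)[keep, , drop = FALSE]
  })
  if (length(unique(tr)) < 2L || var(m) == 0) {
    stop("degenerate design: constant treatment or mediator among included subjects",
         call. = FALSE)
  }
  obs <- .score_linear(m, X, tr)
  if (method == "asymptotic") {
    return(list(p = obs$p, sign = obs$sign, stat = obs$stat,
                method = "asymptotic"))
  }
  # Freedman-Lane: permute residuals of T ~ X, re-residualise, recompute.
  Qx <- .qr_q(X)
  t_fit <- drop(Qx %*% crossprod(Qx, tr))
  t_res <- tr - t_fit
  rm <- m - Qx %*% crossprod(Qx, m)
  sig2 <- sum(rm^2) / n
  stat_fun <- function(Tstar) {
    Tres <- Tstar - Qx %*% crossprod(Qx, Tstar)
    u <- drop(crossprod(Tres, rm))
    den <- sig2 * colSums(Tres^2)
    u^2 / den
  }
  pm <- .adaptive_perm(obs$stat, t_res, t_fit, stat_fun,
                       B_max = B_max, min_exceed = min_exceed, seed = seed)
  list(p = pm$p, sign = obs$sign, stat = obs$stat, method = "permutation",
       b = pm$b, B = pm$B)
}

#' Score test of the mediator-outcome association at one node
#'
#' Rao score test of `beta = 0` in the generalized linear model of the
#' outcome on confounders, treatment, and the log-ratio mediator (identity
#' link for continuous outcomes, logit link for binary ones). The
#' permutation method permutes the residuals of the mediator regressed on
#' confounders and treatment (Freedman-Lane). If the null logistic fit fails
#' to converge, the permutation path is used with a warning.
#'
#' @inheritParams test_alpha
#' @param outcome numeric (continuous) or 0/1 (binary) outcome vector.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return list as in [test_alpha()].
#' @export
test_beta <- function(mediator, treatment, outcome, covariates = NULL,
                      outcome_type = c("continuous", "binary"),
                      method = c("asymptotic", "permutation"),
                      seed = NULL, B_max = 10000L, min_exceed = 100L) {
  outcome_type <- match.arg(outcome_type)
  method <- match.arg(method)
  keep <- !is.na(mediator)
  m <- mediator[keep]
  tr <- treatment[keep]
  y <- outcome[keep]
  n <- length(m)
  Z <- cbind(rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE],
             tr)
  if (var(m) == 0) {
    stop("degenerate design: constant mediator among included subjects",
         call. = FALSE)
  }
  if (outcome_type == "continuous") {
    obs <- .score_linear(y, Z, m)
  } else {
    obs <- .score_logistic(y, Z, m)
    if (is.null(obs)) {
      if (method == "asymptotic") {
        warning("null logistic fit did not converge; ",
                "falling back to the permutation p-value", call. = FALSE)
        method <- "permutation"
      }
      # score statistic from the last (unconverged) iterate, used only for
      # ranking within the permutation scheme
      fit <- suppressWarnings(glm.fit(Z, y, family = binomial()))
      mu <- pmin(pmax(fit$fitted.values, 1e-10), 1 - 1e-10)
      w <- mu * (1 - mu)
      Qzw <- .qr_q(Z * sqrt(w))
      vw <- m * sqrt(w)
      den <- sum(vw^2) - sum(crossprod(Qzw, vw)^2)
      u <- sum((y - mu) * m)
      obs <- list(stat = u^2 / max(den, 1e-12), sign = sign(u), p = NA_real_)
    }
  }
  if (method == "asymptotic") {
    return(list(p = obs$p, sign = obs$sign, stat = obs$stat,
                method = "asymptotic"))
  }
  # Freedman-Lane: permute residuals of M ~ (X, T).
  Qz <- .qr_q(Z)
  m_fit <- drop(Qz %*% crossprod(Qz, m))
  m_res <- m - m_fit
  if (outcome_type == "continuous") {
    ry <- y - Qz %*% crossprod(Qz, y)
    sig2 <- sum(ry^2) / n
    stat_fun <- function(Mstar) {
      Mres <- Mstar - Qz %*% crossprod(Qz, Mstar)
      u <- drop(crossprod(Mres, ry))
      u^2 / (sig2 * colSums(Mres^2))
    }
  } else {
    fit <- suppressWarnings(glm.fit(Z, y, family = binomial()))
    mu <- pmin(pmax(fit$fitted.values, 1e-10), 1 - 1e-10)
    w <- mu * (1 - mu)
    sw <- sqrt(w)
    Qzw <- .qr_q(Z * sw)
    res_y <- y - mu
    stat_fun <- function(Mstar) {
      u <- drop(crossprod(Mstar, res_y))
      Mw <- Mstar * sw
      den <- colSums(Mw^2) - colSums(crossprod(Qzw, Mw)^2)
      u^2 / pmax(den, 1e-12)
    }
  }
  pm <- .adaptive_perm(obs$stat, m_res, m_fit, stat_fun,
                       B_max = B_max, min_exceed = min_exceed, seed = seed)
  list(p = pm$p, sign = obs$sign, stat = obs$stat, method = "permutation",
       b = pm$b, B = pm$B)
}

#' Sobel test of the mediation product
#'
#' Classical normal-theory test of `alpha * beta = 0` based on the delta
#' method: `z = ab / sqrt(a^2 se_b^2 + b^2 se_a^2)`, two-sided normal
#' reference. Provided as a comparator; it is well known to be conservative
#' under the composite null.
#'
#' @param alpha_hat,se_alpha estimate and standard error of the
#'   treatment-mediator coefficient.
#' @param beta_hat,se_beta estimate and standard error of the
#'   mediator-outcome coefficient.
#' @return two-sided p-value.
#' @export
sobel_test <- function(alpha_hat, se_alpha, beta_hat, se_beta) {
  if (any(se_alpha <= 0) || any(se_beta <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  den <- sqrt(alpha_hat^2 * se_beta^2 + beta_hat^2 * se_alpha^2)
  z <- ifelse(den == 0, 0, alpha_hat * beta_hat / den)
  2 * pnorm(abs(z), lower.tail = FALSE)
}

#' Joint significance (max-p) test
#'
#' Takes the larger of the two association p-values and refers it to the
#' Uniform(0,1) distribution, i.e. the joint significance test. Provided as
#' a comparator; it is conservative under the composite null.
#'
#' @param p_alpha,p_beta association p-values.
#' @return `pmax(p_alpha, p_beta)`.
#' @export
joint_significance_test <- function(p_alpha, p_beta) {
  pmax(p_alpha, p_beta)
}

# Vectorised association tests for all non-degenerate nodes. Nodes sharing
# an inclusion mask are processed as a block with plain matrix algebra;
# permutation requests drop to the per-node functions. Returns a data frame
# with one row per node (p_alpha, p_beta, signs, n_included, degeneracy and,
# for continuous outcomes, Wald estimates for the Sobel comparator).
.node_tests <- function(subc, treatment, outcome, covariates = NULL,
                        outcome_type = c("continuous", "binary"),
                        method = c("asymptotic", "permutation"),
                        seed = NULL, B_max = 10000L, min_exceed = 100L,
                        comparators = FALSE) {
  outcome_type <- match.arg(outcome_type)
  method <- match.arg(method)
  M <- subc$mediator
  inc <- subc$include
  n <- nrow(M)
  J <- ncol(M)
  q <- 1L + if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  min_n <- max(10L, q + 3L)

  out <- data.frame(node = seq_len(J),
                    label = subc$structure$node_label,
                    n_included = colSums(inc),
                    p_alpha = NA_real_, p_beta = NA_real_,
                    sign_alpha = NA_real_, sign_beta = NA_real_,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  if (comparators) {
    out$alpha_hat <- out$se_alpha <- out$beta_hat <- out$se_beta <- NA_real_
  }

  med_var <- apply(M, 2, function(x) var(x[!is.na(x)]))
  tr_var <- vapply(seq_len(J), function(j) {
    length(unique(treatment[inc[, j]])) > 1L
  }, logical(1))
  out$degenerate <- out$n_included < min_n | is.na(med_var) |
    med_var <= 0 | !tr_var
  active <- which(!out$degenerate)
  if (length(active) == 0L) {
    return(out)
  }

  if (method == "permutation") {
    for (j in active) {
      keep <- inc[, j]
      sj <- if (is.null(seed)) NULL else .derive_seed(seed, j)
      a <- test_alpha(M[, j], treatment, covariates, method = "permutation",
                      seed = sj, B_max = B_max, min_exceed = min_exceed)
      b <- test_beta(M[, j], treatment, outcome, covariates,
                     outcome_type = outcome_type, method = "permutation",
                     seed = if (is.null(sj)) NULL else sj + 1,
                     B_max = B_max, min_exceed = min_exceed)
      out$p_alpha[j] <- a$p; out$sign_alpha[j] <- a$sign
      out$p_beta[j] <- b$p; out$sign_beta[j] <- b$sign
    }
    if (comparators) {
      out <- .add_wald_estimates(out, subc, treatment, outcome, covariates,
                                 outcome_type, active)
    }
    return(out)
  }

  # asymptotic path: block by identical inclusion masks
  mask_key <- apply(inc[, active, drop = FALSE], 2, paste, collapse = "")
  for (key in unique(mask_key)) {
    jj <- active[mask_key == key]
    keep <- inc[, jj[1L]]
    ns <- sum(keep)
    Mb <- M[keep, jj, drop = FALSE]
    tr <- treatment[keep]
    y <- outcome[keep]
    X <- cbind(rep(1, ns), if (!is.null(covariates)) {
      as.matrix(covariates)[keep, , drop = FALSE]
    })
    Z <- cbind(X, tr)

    # alpha: score of T added to M ~ X, per node
    Qx <- .qr_q(X)
    t_res <- tr - Qx %*% crossprod(Qx, tr)
    Mres_x <- Mb - Qx %*% crossprod(Qx, Mb)
    rss_m <- colSums(Mres_x^2)
    u_a <- drop(crossprod(t_res, Mb))
    v_a <- (rss_m / ns) * sum(t_res^2)
    stat_a <- u_a^2 / v_a
    out$p_alpha[jj] <- pchisq(stat_a, 1, lower.tail = FALSE)
    out$sign_alpha[jj] <- sign(u_a)

    # beta: score of M added to Y ~ (X, T), shared null fit per block
    Qz <- .qr_q(Z)
    Mres_z <- Mb - Qz %*% crossprod(Qz, Mb)
    if (outcome_type == "continuous") {
      ry <- y - Qz %*% crossprod(Qz, y)
      sig2 <- sum(ry^2) / ns
      u_b <- drop(crossprod(ry, Mb))
      v_b <- sig2 * colSums(Mres_z^2)
    } else {
      fit <- suppressWarnings(glm.fit(Z, y, family = binomial()))
      mu <- pmin(pmax(fit$fitted.values, 1e-10), 1 - 1e-10)
      w <- mu * (1 - mu)
      sw <- sqrt(w)
      Qzw <- .qr_q(Z * sw)
      Mw <- Mb * sw
      u_b <- drop(crossprod(y - mu, Mb))
      v_b <- colSums(Mw^2) - colSums(crossprod(Qzw, Mw)^2)
    }
    bad <- v_b <= 0
    stat_b <- ifelse(bad, NA_real_, u_b^2 / v_b)
    out$p_beta[jj] <- pchisq(stat_b, 1, lower.tail = FALSE)
    out$sign_beta[jj] <- sign(u_b)
    out$degenerate[jj[bad & !is.na(bad)]] <- TRUE

    if (comparators && outcome_type == "continuous") {
      # Wald estimates for Sobel, from the full fits (shared algebra)
      sst <- sum(t_res^2)
      a_hat <- u_a / sst
      rss_full_a <- rss_m - u_a^2 / sst
      out$alpha_hat[jj] <- a_hat
      out$se_alpha[jj] <- sqrt(pmax(rss_full_a, 0) /
                                 (ns - ncol(X) - 1) / sst)
      ssm <- colSums(Mres_z^2)
      ryy <- y - Qz %*% crossprod(Qz, y)
      ub2 <- drop(crossprod(ryy, Mb))
      b_hat <- ub2 / ssm
      rss_full_b <- sum(ryy^2) - ub2^2 / ssm
      out$beta_hat[jj] <- b_hat
      out$se_beta[jj] <- sqrt(pmax(rss_full_b, 0) /
                                (ns - ncol(Z) - 1) / ssm)
    }
  }
  if (comparators && outcome_type == "binary") {
    out <- .add_wald_estimates(out, subc, treatment, outcome, covariates,
                               outcome_type, active)
  }
  out$degenerate <- out$degenerate | is.na(out$p_alpha) | is.na(out$p_beta)
  out
}

# Per-node Wald estimates (alpha_hat, beta_hat and their SEs) via full-model
# fits; used for the Sobel comparator when the fast block path does not
# produce them (binary outcome, permutation method).
.add_wald_estimates <- function(out, subc, treatment, outcome, covariates,
                                outcome_type, active) {
  M <- subc$mediator
  for (j in active) {
    keep <- !is.na(M[, j])
    m <- M[keep, j]
    tr <- treatment[keep]
    y <- outcome[keep]
    X <- cbind(rep(1, sum(keep)), if (!is.null(covariates)) {
      as.matrix(covariates)[keep, , drop = FALSE]
    })
    fa <- stats::lm.fit(cbind(X, tr), m)
    rdf <- length(m) - ncol(X) - 1L
    s2 <- sum(fa$residuals^2) / rdf
    R <- chol2inv(fa$qr$qr[seq_len(ncol(X) + 1L), , drop = FALSE])
    out$alpha_hat[j] <- fa$coefficients[ncol(X) + 1L]
    out$se_alpha[j] <- sqrt(s2 * R[ncol(X) + 1L, ncol(X) + 1L])
    Zf <- cbind(X, tr, m)
    if (outcome_type == "continuous") {
      fb <- stats::lm.fit(Zf, y)
      rdf <- length(y) - ncol(Zf)
      s2 <- sum(fb$residuals^2) / rdf
      R <- chol2inv(fb$qr$qr[seq_len(ncol(Zf)), , drop = FALSE])
      out$beta_hat[j] <- fb$coefficients[ncol(Zf)]
      out$se_beta[j] <- sqrt(s2 * R[ncol(Zf), ncol(Zf)])
    } else {
      fb <- suppressWarnings(glm.fit(Zf, y, family = binomial()))
      cf <- fb$coefficients[ncol(Zf)]
      mu <- fb$fitted.values
      w <- mu * (1 - mu)
      XtWX <- crossprod(Zf * sqrt(w))
      cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
      if (!is.null(cov) && fb$converged) {
        out$beta_hat[j] <- cf
        out$se_beta[j] <- sqrt(cov[ncol(Zf), ncol(Zf)])
      }
    }
  }
  out
}
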