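# Shared fixture builders. All data are generated in code at test time.

# A small fixed community for structural tests: 4 taxa, hand-checkable.
tiny_tree <- function() read_tree_binary("((t5,(t6,t7)),t8);")

tiny_counts <- function() {
  matrix(c(5, 6, 7, 2,
           0, 0, 3, 1,
           0, 10, 0, 4),
         nrow = 3, byrow = TRUE,
         dimnames = list(paste0("s", 1:3), c("t5", "t6", "t7", "t8")))
}

# A quick synthetic dataset for end-to-end tests.
quick_dataset <- function(L = 20, n = 60, scenario = "null",
                          outcome_type = "continuous", seed = 7, ...) {
  bl <- simulate_baseline(L = L, n = 2, seed = seed)
  simulate_mediation_data(bl, n = n, scenario = scenario,
                          outcome_type = outcome_type, seed = seed + 1, ...)
}

# Independent least-concave-majorant oracle built on grDevices::chull:
# returns the slopes of the upper hull of the ECDF point set.
lcm_oracle <- function(p) {
  p <- sort(p)
  ux <- unique(p)
  uy <- cumsum(tabulate(match(p, ux))) / length(p)
  x <- c(0, ux); y <- c(0, uy)
  if (max(x) < 1) { x <- c(x, 1); y <- c(y, 1) }
  h <- grDevices::chull(x, y)          # counter-clockwise hull indices
  h <- sort(h[x[h] %in% x])            # all hull points, by x
  # keep only upper-hull points: those on or above every chord
  pts <- data.frame(x = x[h], y = y[h])
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    xi <- pts$x[i]; yi <- pts$y[i]
    for (a in seq_len(nrow(pts))) for (b in seq_len(nrow(pts))) {
      if (pts$x[a] < xi && pts$x[b] > xi) {
        yc <- pts$y[a] + (pts$y[b] - pts$y[a]) * (xi - pts$x[a]) /
          (pts$x[b] - pts$x[a])
        if (yi < yc - 1e-12) keep[i] <- FALSE
      }
    }
  }
  pts <- pts[keep, ]
  list(knots = pts$x, slopes = diff(pts$y) / diff(pts$x))
}

# Naive reimplementation of the empirical-characteristic-function null
# proportion estimator (same grids, scalar loops) used as a quadrature
# oracle.
pi0_oracle <- function(z, xi_points = 201, t_points = 101) {
  J <- length(z)
  tg <- seq(0, sqrt(log(J)), length.out = t_points)
  xg <- seq(-1, 1, length.out = xi_points)
  h <- xg[2] - xg[1]
  vals <- sapply(tg, function(t) {
    f <- sapply(xg, function(xi) {
      (1 - abs(xi)) * mean(cos(t * xi * z)) * exp(t^2 * xi^2 / 2)
    })
    sum((f[-1] + f[-length(f)]) / 2 * h)
  })
  min(max(min(vals), 1 / J), 1)
}
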