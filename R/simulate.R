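# Synthetic-data generator mirroring the structure of the simulation study:
# a fixed random binary tree and baseline abundance profile stand in for the
# real cohort the study resampled; counts are Dirichlet-multinomial,
# treatment effects are binomial count spikes on selected taxa, and outcomes
# follow zero-sum log-contrast models.

#' Generate a synthetic baseline community
#'
#' Creates a random rooted binary tree over `L` taxa and a subjects x taxa
#' count matrix. Baseline relative abundances follow a log-normal profile
#' sorted in decreasing order (a few dominant taxa and a long tail of rare
#' ones); per-subject compositions are Dirichlet perturbations of that
#' profile and counts are multinomial draws at a sequencing depth uniform on
#' `depth_range`.
#'
#' @param L number of leaf taxa (>= 4).
#' @param n number of subjects.
#' @param depth_range length-2 integer range of sequencing depths.
#' @param concentration Dirichlet concentration: larger values give subjects
#'   closer to the common profile (default 50, a realistic between-subject
#'   overdispersion for gut communities).
#' @param sdlog log-normal spread of the baseline profile (default 2).
#' @param seed optional RNG seed.
#' @return list with `tree` (`phylo`), `counts` (`n x L`, taxa named
#'   `OTU1..OTUL` in decreasing baseline abundance), and `base_props`.
#' @export
simulate_baseline <- function(L = 100L, n = 200L,
                              depth_range = c(10000L, 50000L),
                              concentration = 50, sdlog = 2, seed = NULL) {
  stopifnot(L >= 4L, n >= 2L, length(depth_range) == 2L,
            depth_range[1L] <= depth_range[2L], depth_range[1L] >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  base <- sort(exp(rnorm(L, 0, sdlog)), decreasing = TRUE)
  base <- base / sum(base)
  labels <- paste0("OTU", seq_len(L))
  tree <- ape::rtree(L, tip.label = sample(labels))
  depths <- if (depth_range[1L] == depth_range[2L]) {
    rep(depth_range[1L], n)
  } else {
    sample(seq(depth_range[1L], depth_range[2L]), n, replace = TRUE)
  }
  counts <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(L, shape = concentration * base)
    g[g <= 0] <- 1e-12
    drop(rmultinom(1, depths[i], g / sum(g)))
  }, numeric(L)))
  dimnames(counts) <- list(paste0("S", seq_len(n)), labels)
  list(tree = tree, counts = counts,
       base_props = stats::setNames(base, labels),
       depth_range = depth_range, concentration = concentration)
}

#' Spike treatment-associated taxa
#'
#' For each taxon in `s_alpha`, one of the two treatment arms is chosen with
#' probability 1/2 and every subject in that arm receives an added count
#' drawn from `Binomial(N_i, A * f_k)`, where `N_i` is the subject's
#' sequencing depth and `f_k` the taxon's average observed proportion across
#' all samples. `A` controls the strength of the treatment-mediator
#' association.
#'
#' @param counts subjects x taxa count matrix.
#' @param treatment 0/1 vector.
#' @param s_alpha taxa to perturb (names or column indices).
#' @param A association strength (default 0.5); `A * f_k > 1` is clamped to
#'   1 with a warning.
#' @param seed optional RNG seed.
#' @return the perturbed count matrix.
#' @export
perturb_treatment_taxa <- function(counts, treatment, s_alpha, A = 0.5,
                                   seed = NULL) {
  stopifnot(A >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  if (length(s_alpha) == 0L || A == 0) {
    return(counts)
  }
  depths <- rowSums(counts)
  props <- counts / depths
  for (k in s_alpha) {
    f_k <- mean(props[, k])
    prob <- A * f_k
    if (prob > 1) {
      warning("A * f_k > 1 for taxon ", k, "; clamped to 1", call. = FALSE)
      prob <- 1
    }
    arm <- sample(c(0, 1), 1L)
    idx <- which(treatment == arm)
    counts[idx, k] <- counts[idx, k] + rbinom(length(idx), depths[idx], prob)
  }
  counts
}

#' Simulate an outcome from a zero-sum log-contrast model
#'
#' Continuous outcomes follow
#' `Y = beta_T T + sum_k beta_k log(f_ik) + e`, binary outcomes the logistic
#' analogue, where `f_ik` is the observed proportion of taxon `k` in subject
#' `i` (computed after adding the pseudocount, so the logs are finite), the
#' `beta_k` are drawn Uniform(0, B) and centred to satisfy the zero-sum
#' constraint, and `beta_T` is drawn Uniform(0, 1) unless supplied.
#'
#' @param counts subjects x taxa count matrix (post perturbation).
#' @param treatment 0/1 vector.
#' @param s_beta outcome-associated taxa (names or indices); empty means the
#'   outcome depends on the treatment only.
#' @param B mediator-outcome association strength (default 0.5).
#' @param beta_T treatment coefficient; `NULL` draws Uniform(0, 1).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param sigma residual standard deviation of the continuous outcome
#'   (default 1).
#' @param pseudocount added before proportions so `log(f_ik)` is finite.
#' @param seed optional RNG seed.
#' @return list with `Y`, `beta_T`, `beta_k`.
#' @export
simulate_outcome <- function(counts, treatment, s_beta, B = 0.5,
                             beta_T = NULL,
                             outcome_type = c("continuous", "binary"),
                             sigma = 1, pseudocount = 0.5, seed = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  n <- nrow(counts)
  if (is.null(beta_T)) beta_T <- runif(1)
  lin <- beta_T * treatment
  beta_k <- numeric(0)
  if (length(s_beta) > 0L) {
    shifted <- counts + pseudocount
    props <- shifted / rowSums(shifted)
    beta_k <- runif(length(s_beta), 0, B)
    beta_k <- beta_k - mean(beta_k)          # zero-sum constraint
    lin <- lin + drop(log(props[, s_beta, drop = FALSE]) %*% beta_k)
  }
  Y <- if (outcome_type == "continuous") {
    lin + rnorm(n, 0, sigma)
  } else {
    rbinom(n, 1, 1 / (1 + exp(-lin)))
  }
  list(Y = Y, beta_T = beta_T,
       beta_k = if (length(s_beta)) stats::setNames(beta_k, s_beta) else beta_k)
}

# Pick `n_clades` disjoint clades with exactly `clade_size` descendant
# leaves; returns list of leaf-label vectors and the clade node indices.
.pick_clades <- function(struct, n_clades, clade_size = 3L) {
  sizes <- colSums(struct$left_mat + struct$right_mat)
  cand <- which(sizes == clade_size)
  if (length(cand) < n_clades) {
    stop("tree has too few clades with ", clade_size, " leaves", call. = FALSE)
  }
  picked <- integer(0)
  used <- character(0)
  for (c_idx in sample(cand)) {
    leaves <- struct$leaves[
      which(struct$left_mat[, c_idx] + struct$right_mat[, c_idx] > 0)]
    if (!any(leaves %in% used)) {
      picked <- c(picked, c_idx)
      used <- c(used, leaves)
      if (length(picked) == n_clades) break
    }
  }
  if (length(picked) < n_clades) {
    stop("could not find ", n_clades, " disjoint clades", call. = FALSE)
  }
  list(nodes = picked,
       leaves = lapply(picked, function(c_idx) {
         struct$leaves[
           which(struct$left_mat[, c_idx] + struct$right_mat[, c_idx] > 0)]
       }))
}

#' Simulate one complete mediation dataset
#'
#' Draws counts from a baseline community, splits subjects into equal-sized
#' treatment and control arms, plants treatment- and outcome-associated taxa
#' according to the scenario, and generates the outcome. Under null
#' scenarios the two taxon sets are disjoint (so no taxon mediates); under
#' the alternative they coincide and are either clustered (random clades of
#' three leaves) or scattered.
#'
#' @param baseline a [simulate_baseline()] result (its tree is reused across
#'   replicates; counts are redrawn unless `redraw_counts = FALSE`).
#' @param n subjects (even).
#' @param s_alpha_size,s_beta_size numbers of treatment-/outcome-associated
#'   taxa for null scenarios (ignored under the alternative).
#' @param n_mediators number of mediating taxa under the alternative (3 or 6
#'   clustered; any number scattered).
#' @param scenario `"null"` or `"alternative"`.
#' @param clustered cluster mediating taxa on the tree (default `TRUE`).
#' @param A,B association strengths (defaults 0.5).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param sigma residual SD of the continuous outcome.
#' @param pseudocount used for the outcome model's log proportions.
#' @param seed optional RNG seed.
#' @return list with `counts`, `tree`, `structure`, `treatment`, `outcome`,
#'   and `truth` (mediating taxa, mediating nodes = their ancestors, and the
#'   most recent common ancestor node(s) of each planted clade).
#' @export
simulate_mediation_data <- function(baseline, n = 200L,
                                    s_alpha_size = 0L, s_beta_size = 0L,
                                    n_mediators = 3L,
                                    scenario = c("null", "alternative"),
                                    clustered = TRUE, A = 0.5, B = 0.5,
                                    outcome_type = c("continuous", "binary"),
                                    sigma = 1, pseudocount = 0.5,
                                    seed = NULL) {
  scenario <- match.arg(scenario)
  outcome_type <- match.arg(outcome_type)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  stopifnot(n %% 2L == 0L)
  struct <- if (!is.null(baseline$structure)) baseline$structure else phylo_structure(baseline$tree)
  L <- length(struct$leaves)

  # fresh multinomial draws from the fixed baseline profile
  base <- baseline$base_props[struct$leaves]
  dr <- if (!is.null(baseline$depth_range)) baseline$depth_range else c(10000L, 50000L)
  conc <- if (!is.null(baseline$concentration)) baseline$concentration else 50
  depths <- if (dr[1L] == dr[2L]) rep(dr[1L], n) else sample(seq(dr[1L], dr[2L]), n, replace = TRUE)
  counts <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(L, shape = conc * base)
    g[g <= 0] <- 1e-12
    drop(rmultinom(1, depths[i], g / sum(g)))
  }, numeric(L)))
  dimnames(counts) <- list(paste0("S", seq_len(n)), struct$leaves)

  treatment <- sample(rep(c(0, 1), each = n / 2L))

  if (scenario == "null") {
    pool <- sample(struct$leaves)
    s_alpha <- head(pool, s_alpha_size)
    s_beta <- head(setdiff(pool, s_alpha), s_beta_size)
    truth <- list(mediating_taxa = character(0),
                  mediating_nodes = integer(0), mrca_nodes = integer(0),
                  s_alpha = s_alpha, s_beta = s_beta)
  } else {
    if (clustered) {
      stopifnot(n_mediators %% 3L == 0L)
      cl <- .pick_clades(struct, n_mediators %/% 3L, 3L)
      med <- unlist(cl$leaves)
      mrca <- cl$nodes
    } else {
      med <- sample(struct$leaves, n_mediators)
      mrca <- .mrca_node(struct, med)
    }
    s_alpha <- s_beta <- med
    truth <- list(mediating_taxa = med,
                  mediating_nodes = .ancestor_nodes(struct, med),
                  mrca_nodes = mrca,
                  s_alpha = s_alpha, s_beta = s_beta)
  }

  counts <- perturb_treatment_taxa(counts, treatment, s_alpha, A = A)
  out <- simulate_outcome(counts, treatment, s_beta, B = B,
                          outcome_type = outcome_type, sigma = sigma,
                          pseudocount = pseudocount)
  list(counts = counts, tree = struct$tree, structure = struct,
       treatment = treatment, outcome = out$Y, truth = truth,
       beta_T = out$beta_T, beta_k = out$beta_k)
}

#' Replicate simulation study
#'
#' Repeats [simulate_mediation_data()] + the full analysis pipeline and
#' tabulates operating characteristics: the empirical type I error (or
#' power) of the global test at `alpha_level`, the empirical FDR of the BH
#' node selection at `fdr_q`, and (under the alternative) the discovery rate
#' of the most recent common ancestor of the planted mediating taxa. When
#' `comparators = TRUE`, the joint significance and Sobel tests are run on
#' the identical node-level fits and summarised alongside.
#'
#' @inheritParams simulate_mediation_data
#' @param n_rep number of replicates.
#' @param L leaf taxa in the synthetic baseline.
#' @param method,pi_approach,combiner analysis settings (see [treemed()]).
#' @param alpha_level global-test significance threshold (default 0.05).
#' @param fdr_q node-selection target FDR (default 0.05).
#' @param comparators also run joint-significance and Sobel node tests.
#' @param seed master seed; replicate `r` uses a stream derived from
#'   `(seed, r)`, so results are independent of scheduling order.
#' @return list with `per_rep` (one row per replicate) and `summary`
#'   (rates with Monte-Carlo standard errors).
#' @export
run_replicates <- function(n_rep, n = 200L, L = 100L,
                           scenario = c("null", "alternative"),
                           s_alpha_size = 0L, s_beta_size = 0L,
                           n_mediators = 3L, clustered = TRUE,
                           A = 0.5, B = 0.5,
                           outcome_type = c("continuous", "binary"),
                           method = c("asymptotic", "permutation"),
                           pi_approach = c("product", "maxp"),
                           combiner = c("hmp", "fisher"),
                           alpha_level = 0.05, fdr_q = 0.05,
                           comparators = FALSE, sigma = 1,
                           pseudocount = 0.5, seed = 1L) {
  scenario <- match.arg(scenario)
  outcome_type <- match.arg(outcome_type)
  method <- match.arg(method)
  pi_approach <- match.arg(pi_approach)
  combiner <- match.arg(combiner)

  base_seed <- .derive_seed(seed, 0)
  baseline <- simulate_baseline(L = L, n = 2L, seed = base_seed)
  struct <- phylo_structure(baseline$tree)
  baseline$structure <- struct

  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    dat <- simulate_mediation_data(
      baseline, n = n, s_alpha_size = s_alpha_size,
      s_beta_size = s_beta_size, n_mediators = n_mediators,
      scenario = scenario, clustered = clustered, A = A, B = B,
      outcome_type = outcome_type, sigma = sigma,
      pseudocount = pseudocount, seed = .derive_seed(seed, r))
    subc <- build_subcompositions(struct, dat$counts, pseudocount)
    fit <- .analyze(subc, dat$treatment, dat$outcome, NULL, outcome_type,
                    method, pi_approach, combiner, fdr_q,
                    seed = .derive_seed(seed, r) + 1, B_max = 10000L,
                    comparators = comparators)
    nt <- fit$node_table
    ok <- !nt$degenerate
    is_med <- nt$node %in% dat$truth$mediating_nodes
    sel <- nt$selected
    fdp <- if (any(sel)) sum(sel & !is_med) / sum(sel) else 0
    row <- data.frame(
      rep = r, global_p = fit$global_p,
      pi00 = fit$null_mix$pi00, pi10 = fit$null_mix$pi10,
      pi01 = fit$null_mix$pi01,
      n_selected = sum(sel), fdp = fdp,
      mrca_found = if (length(dat$truth$mrca_nodes)) {
        mean(dat$truth$mrca_nodes %in% nt$node[sel])
      } else {
        NA_real_
      })
    if (comparators) {
      p_js <- nt$p_js[ok]
      row$global_p_js <- hmp_combine(p_js)$global_p
      sel_js <- bh_select(p_js, fdr_q)$selected
      sel_js <- nt$node[ok][sel_js]
      row$fdp_js <- if (length(sel_js)) {
        sum(!(sel_js %in% dat$truth$mediating_nodes)) / length(sel_js)
      } else 0
      has_sob <- ok & !is.na(nt$p_sobel)
      p_sob <- nt$p_sobel[has_sob]
      sel_sob <- nt$node[has_sob][bh_select(.clamp_p(p_sob), fdr_q)$selected]
      row$fdp_sobel <- if (length(sel_sob)) {
        sum(!(sel_sob %in% dat$truth$mediating_nodes)) / length(sel_sob)
      } else 0
      if (length(dat$truth$mrca_nodes)) {
        row$mrca_found_js <- mean(dat$truth$mrca_nodes %in% sel_js)
        row$mrca_found_sobel <- mean(dat$truth$mrca_nodes %in% sel_sob)
      } else {
        row$mrca_found_js <- row$mrca_found_sobel <- NA_real_
      }
    }
    rows[[r]] <- row
  }
  per_rep <- do.call(rbind, rows)

  rate <- function(x) {
    m <- mean(x, na.rm = TRUE)
    c(estimate = m, se = sqrt(m * (1 - m) / sum(!is.na(x))))
  }
  summary <- list(
    reject_global = rate(per_rep$global_p <= alpha_level),
    fdr = c(estimate = mean(per_rep$fdp), se = sd(per_rep$fdp) / sqrt(n_rep)),
    mrca_rate = if (scenario == "alternative") rate(per_rep$mrca_found) else NULL)
  if (comparators) {
    summary$reject_global_js <- rate(per_rep$global_p_js <= alpha_level)
    summary$fdr_js <- c(estimate = mean(per_rep$fdp_js),
                        se = sd(per_rep$fdp_js) / sqrt(n_rep))
    summary$fdr_sobel <- c(estimate = mean(per_rep$fdp_sobel),
                           se = sd(per_rep$fdp_sobel) / sqrt(n_rep))
    if (scenario == "alternative") {
      summary$mrca_rate_js <- rate(per_rep$mrca_found_js)
      summary$mrca_rate_sobel <- rate(per_rep$mrca_found_sobel)
    }
  }
  list(per_rep = per_rep, summary = summary,
       settings = list(n_rep = n_rep, n = n, L = L, scenario = scenario,
                       s_alpha_size = s_alpha_size, s_beta_size = s_beta_size,
                       n_mediators = n_mediators, clustered = clustered,
                       A = A, B = B, outcome_type = outcome_type,
                       method = method, pi_approach = pi_approach,
                       combiner = combiner, alpha_level = alpha_level,
                       fdr_q = fdr_q, seed = seed))
}
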