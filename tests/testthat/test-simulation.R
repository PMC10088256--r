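# The synthetic-data generator: structural contracts and the perturbation /
# outcome models.

test_that("baseline communities have the documented shape", {
  bl <- simulate_baseline(L = 100, n = 30, seed = 1)
  expect_equal(ape::Ntip(bl$tree), 100)
  expect_equal(bl$tree$Nnode, 99)
  expect_equal(dim(bl$counts), c(30, 100))
  expect_true(all(bl$counts >= 0))
  expect_equal(unname(bl$base_props), sort(bl$base_props, decreasing = TRUE),
               ignore_attr = TRUE)
  expect_equal(sum(bl$base_props), 1)
  depths <- rowSums(bl$counts)
  expect_true(all(depths >= 10000 & depths <= 50000))
  # degenerate depth range pins every subject's depth
  bl2 <- simulate_baseline(L = 10, n = 5, depth_range = c(3000, 3000), seed = 2)
  expect_true(all(rowSums(bl2$counts) == 3000))
})

test_that("treatment perturbation is a no-op when switched off", {
  bl <- simulate_baseline(L = 20, n = 20, seed = 3)
  tr <- rep(0:1, each = 10)
  expect_identical(perturb_treatment_taxa(bl$counts, tr, character(0)),
                   bl$counts)
  expect_identical(perturb_treatment_taxa(bl$counts, tr, "OTU1", A = 0),
                   bl$counts)
})

test_that("treatment perturbation spikes one arm with the right magnitude", {
  bl <- simulate_baseline(L = 20, n = 400, depth_range = c(10000, 10000),
                          seed = 4)
  tr <- rep(0:1, each = 200)
  f_k <- mean(bl$counts[, "OTU1"] / rowSums(bl$counts))
  pert <- perturb_treatment_taxa(bl$counts, tr, "OTU1", A = 0.5, seed = 5)
  delta <- pert[, "OTU1"] - bl$counts[, "OTU1"]
  # only one arm is touched, and other taxa are untouched
  touched <- tapply(delta, tr, function(x) any(x > 0))
  expect_equal(sum(touched), 1L)
  expect_identical(pert[, -1], bl$counts[, -1])
  # mean added count ~= N * A * f_k within 5 binomial SEs
  mu <- 10000 * 0.5 * f_k
  se <- sqrt(10000 * 0.5 * f_k / 200)
  expect_lt(abs(mean(delta[tr == (which(touched) - 1)]) - mu), 5 * se)
})

test_that("outcome model satisfies the zero-sum constraint", {
  bl <- simulate_baseline(L = 20, n = 50, seed = 6)
  tr <- rep(0:1, each = 25)
  out <- simulate_outcome(bl$counts, tr, paste0("OTU", 1:5), B = 0.5,
                          seed = 7)
  expect_equal(sum(out$beta_k), 0, tolerance = 1e-12)
  expect_true(all(abs(out$beta_k) <= 0.5))
  # empty outcome-taxon set: outcome depends on treatment only
  out0 <- simulate_outcome(bl$counts, tr, character(0), beta_T = 2,
                           sigma = 1e-6, seed = 8)
  expect_equal(unique(round(out0$Y[tr == 1] - out0$Y[tr == 0], 3)), 2)
  # binary outcomes are 0/1
  outb <- simulate_outcome(bl$counts, tr, paste0("OTU", 1:3),
                           outcome_type = "binary", seed = 9)
  expect_true(all(outb$Y %in% c(0, 1)))
})

test_that("truth bookkeeping marks ancestors of the planted mediators", {
  bl <- simulate_baseline(L = 50, n = 2, seed = 10)
  dat <- simulate_mediation_data(bl, n = 40, scenario = "alternative",
                                 n_mediators = 3, clustered = TRUE,
                                 seed = 11)
  expect_length(dat$truth$mediating_taxa, 3)
  st <- dat$structure
  mrca <- dat$truth$mrca_nodes
  expect_length(mrca, 1)
  clade_leaves <- c(st$left_leaves[[mrca]], st$right_leaves[[mrca]])
  expect_setequal(clade_leaves, dat$truth$mediating_taxa)
  # every mediating node subtends at least one mediating leaf, and the
  # ancestors of the mediating leaves are all flagged
  expect_setequal(dat$truth$mediating_nodes,
                  treemed:::.ancestor_nodes(st, dat$truth$mediating_taxa))
  expect_true(mrca %in% dat$truth$mediating_nodes)
  # two disjoint clades for six mediators
  dat6 <- simulate_mediation_data(bl, n = 40, scenario = "alternative",
                                  n_mediators = 6, clustered = TRUE,
                                  seed = 12)
  expect_length(dat6$truth$mrca_nodes, 2)
  expect_length(unique(dat6$truth$mediating_taxa), 6)
})

test_that("null scenarios keep the two taxon sets disjoint", {
  bl <- simulate_baseline(L = 30, n = 2, seed = 13)
  dat <- simulate_mediation_data(bl, n = 40, scenario = "null",
                                 s_alpha_size = 3, s_beta_size = 6,
                                 seed = 14)
  expect_length(intersect(dat$truth$s_alpha, dat$truth$s_beta), 0)
  expect_length(dat$truth$mediating_nodes, 0)
  expect_equal(sum(dat$treatment), 20)      # equal arms
})

test_that("replicate studies are reproducible from the master seed", {
  r1 <- run_replicates(n_rep = 3, n = 40, L = 25, scenario = "null",
                       seed = 15)
  r2 <- run_replicates(n_rep = 3, n = 40, L = 25, scenario = "null",
                       seed = 15)
  expect_identical(r1$per_rep, r2$per_rep)
  r3 <- run_replicates(n_rep = 3, n = 40, L = 25, scenario = "null",
                       seed = 16)
  expect_false(identical(r1$per_rep$global_p, r3$per_rep$global_p))
})

test_that("power increases with the association strengths", {
  pow <- function(A, B, seed) {
    res <- run_replicates(n_rep = 40, n = 100, L = 30,
                          scenario = "alternative", n_mediators = 3,
                          A = A, B = B, seed = seed)
    res$summary$reject_global[["estimate"]]
  }
  weak <- pow(0.05, 0.05, 17)
  strong <- pow(1, 1, 17)
  expect_gt(strong, weak)
})
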