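#' Phylogeny-guided mediation analysis of a microbial community
#'
#' Runs the full pipeline: builds the log-ratio subcomposition mediator at
#' every internal node of the tree, score-tests the treatment-mediator and
#' mediator-outcome associations in each local model, converts each node's
#' max-p statistic into a composite-null mixture p-value (with mixture
#' weights estimated across nodes and alternative power functions estimated
#' by the Grenander estimator), selects mediating nodes by
#' Benjamini-Hochberg, and combines the node p-values into a community-level
#' mediation test by the harmonic mean p-value.
#'
#' Nodes at which the local regression is unidentifiable are flagged
#' degenerate and excluded from the null-proportion estimation, the
#' selection, and the global combination (whose equal weights are
#' renormalised over the remaining nodes). A node is degenerate when fewer
#' than `max(10, ncol(X) + 3)` subjects have information on its
#' subcomposition (`X` including the intercept), when its mediator or the
#' treatment is constant among those subjects, or when a score-test variance
#' is not positive.
#'
#' @param counts subjects x taxa count matrix (or data frame); column names
#'   must match the tree's leaf labels.
#' @param tree rooted tree: a `phylo` object, Newick string/file, or a
#'   [phylo_structure()].
#' @param treatment binary 0/1 vector, one value per count-table row.
#' @param outcome outcome vector (numeric, or 0/1 for binary).
#' @param covariates optional numeric matrix/data frame of confounders.
#' @param outcome_type `"continuous"` or `"binary"`; never guessed from the
#'   data, since 0/1-coded continuous scores would be silently
#'   misclassified.
#' @param method `"asymptotic"` score tests or `"permutation"`
#'   (Freedman-Lane with adaptive early stopping).
#' @param pseudocount pseudocount for the log-ratio (default 0.5).
#' @param pi_approach `"product"` or `"maxp"` estimator of the null mixture
#'   (see [combine_null_proportions()]).
#' @param combiner `"hmp"` (default) or `"fisher"` global combination.
#' @param fdr target FDR for node selection (default 0.1).
#' @param seed master seed for the permutation method; per-node streams are
#'   derived from it deterministically.
#' @param prune passed to [build_subcompositions()]: allow intersecting
#'   mismatched leaf/count sets instead of erroring.
#' @param B_max maximum permutations per test.
#' @return An object of class `treemed`: a list with `node_table` (one row
#'   per internal node), `global_p`, `p_ring`, `null_mix`, `n_degenerate`,
#'   and `settings`.
#' @seealso [simulate_mediation_data()] to generate synthetic inputs,
#'   [pair_screen()] for the post-hoc leaf-pair heuristic.
#' @export
treemed <- function(counts, tree, treatment, outcome, covariates = NULL,
                    outcome_type = c("continuous", "binary"),
                    method = c("asymptotic", "permutation"),
                    pseudocount = 0.5,
                    pi_approach = c("product", "maxp"),
                    combiner = c("hmp", "fisher"),
                    fdr = 0.1, seed = NULL, prune = FALSE,
                    B_max = 10000L) {
  outcome_type <- match.arg(outcome_type)
  method <- match.arg(method)
  pi_approach <- match.arg(pi_approach)
  combiner <- match.arg(combiner)

  counts <- as.matrix(counts)
  n <- nrow(counts)
  stopifnot(length(treatment) == n, length(outcome) == n)
  if (!all(treatment %in% c(0, 1))) {
    stop("'treatment' must be coded 0/1", call. = FALSE)
  }
  if (outcome_type == "binary" && !all(outcome %in% c(0, 1, NA))) {
    stop("binary outcome must be coded 0/1", call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
  }
  # subjects with missing treatment/outcome/covariates are dropped globally,
  # so every local model sees the same cohort
  complete <- !is.na(treatment) & !is.na(outcome)
  if (!is.null(covariates)) complete <- complete & !apply(is.na(covariates), 1, any)
  if (any(!complete)) {
    message("dropping ", sum(!complete),
            " subject(s) with missing treatment/outcome/covariate values")
    counts <- counts[complete, , drop = FALSE]
    treatment <- treatment[complete]
    outcome <- outcome[complete]
    if (!is.null(covariates)) covariates <- covariates[complete, , drop = FALSE]
  }

  subc <- build_subcompositions(tree, counts, pseudocount, prune = prune)
  fit <- .analyze(subc, treatment, outcome, covariates, outcome_type,
                  method, pi_approach, combiner, fdr, seed, B_max)
  fit$settings <- list(outcome_type = outcome_type, method = method,
                       pseudocount = pseudocount, pi_approach = pi_approach,
                       combiner = combiner, fdr = fdr, seed = seed,
                       n_subjects = nrow(counts),
                       n_covariates = if (is.null(covariates)) 0L else ncol(covariates),
                       B_max = B_max)
  fit
}

# Core analysis shared by treemed() and the simulation driver: association
# tests -> composite-null stage -> BH selection + global combination.
.analyze <- function(subc, treatment, outcome, covariates, outcome_type,
                     method, pi_approach, combiner, fdr, seed, B_max,
                     comparators = FALSE) {
  tests <- .node_tests(subc, treatment, outcome, covariates, outcome_type,
                       method, seed, B_max, comparators = comparators)
  ok <- !tests$degenerate
  if (sum(ok) < 2L) {
    stop("fewer than 2 non-degenerate internal nodes; nothing to test",
         call. = FALSE)
  }
  cs <- .composite_stage(tests$p_alpha[ok], tests$p_beta[ok],
                         tests$sign_alpha[ok], tests$sign_beta[ok],
                         approach = pi_approach)
  nt <- tests
  nt$p_max <- NA_real_
  nt$p_mediation <- NA_real_
  nt$p_max[ok] <- cs$p_max
  nt$p_mediation[ok] <- cs$p_mediation
  sel <- bh_select(cs$p_mediation, q = fdr)
  nt$q_bh <- NA_real_
  nt$q_bh[ok] <- sel$q_bh
  nt$selected <- FALSE
  nt$selected[which(ok)[sel$selected]] <- TRUE
  if (comparators) {
    nt$p_js <- NA_real_
    nt$p_js[ok] <- joint_significance_test(.clamp_p(tests$p_alpha[ok]),
                                           .clamp_p(tests$p_beta[ok]))
    nt$p_sobel <- NA_real_
    has_se <- ok & !is.na(tests$se_alpha) & !is.na(tests$se_beta) &
      tests$se_alpha > 0 & tests$se_beta > 0
    nt$p_sobel[has_se] <- sobel_test(tests$alpha_hat[has_se],
                                     tests$se_alpha[has_se],
                                     tests$beta_hat[has_se],
                                     tests$se_beta[has_se])
  }
  comb <- if (combiner == "hmp") {
    hmp_combine(cs$p_mediation)
  } else {
    fisher_combine(cs$p_mediation)
  }
  structure(list(node_table = nt,
                 global_p = comb$global_p,
                 p_ring = if (combiner == "hmp") comb$p_ring else NA_real_,
                 combiner = combiner,
                 null_mix = cs$null_mix,
                 n_degenerate = sum(!ok),
                 J = nrow(tests)),
            class = "treemed")
}

#' @export
print.treemed <- function(x, ...) {
  cat("Phylogeny-guided mediation analysis\n")
  cat(sprintf("  %d internal nodes (%d degenerate, excluded)\n",
              x$J, x$n_degenerate))
  print(x$null_mix)
  cat(sprintf("  global mediation p-value (%s): %.4g\n",
              x$combiner, x$global_p))
  nsel <- sum(x$node_table$selected, na.rm = TRUE)
  if (nsel > 0) {
    cat("  selected nodes:\n")
    sel <- x$node_table[x$node_table$selected %in% TRUE, ]
    for (i in seq_len(nrow(sel))) {
      cat(sprintf("    node %d [%s]: p = %.3g, q = %.3g\n",
                  sel$node[i], sel$label[i], sel$p_mediation[i],
                  sel$q_bh[i]))
    }
  } else {
    cat("  no node selected at the target FDR\n")
  }
  invisible(x)
}

#' Leaf-pair screen under an internal node
#'
#' Post-hoc heuristic for interpreting a significant internal node whose one
#' child is a single leaf: the leaf is paired with each leaf descending from
#' the other child, the two-taxon subcomposition of each pair is formed, and
#' the treatment-subcomposition and subcomposition-outcome associations are
#' tested. The reported statistic per pair is the maximum of the two
#' p-values.
#'
#' @inheritParams treemed
#' @param node internal node index (postorder, as in the `node_table`).
#' @return data frame with one row per pair: the two taxa, `n_included`,
#'   `p_alpha`, `p_beta`, and `p_max`.
#' @export
pair_screen <- function(counts, tree, node, treatment, outcome,
                        covariates = NULL,
                        outcome_type = c("continuous", "binary"),
                        pseudocount = 0.5, prune = FALSE) {
  outcome_type <- match.arg(outcome_type)
  struct <- if (inherits(tree, "phylo_structure")) tree else phylo_structure(tree)
  stopifnot(node >= 1, node <= struct$J)
  left <- struct$left_leaves[[node]]
  right <- struct$right_leaves[[node]]
  if (length(left) == 1L) {
    anchor <- left; others <- right
  } else if (length(right) == 1L) {
    anchor <- right; others <- left
  } else {
    stop("node ", node, " has no leaf child; supply a node that pairs a ",
         "single taxon against a clade", call. = FALSE)
  }
  counts <- as.matrix(counts)
  rows <- lapply(others, function(ot) {
    a <- counts[, anchor]
    b <- counts[, ot]
    keep <- !(a == 0 & b == 0)
    if (sum(keep) < 10L) {
      warning("pair ", anchor, " / ", ot,
              " has fewer than 10 informative subjects; skipped",
              call. = FALSE)
      return(NULL)
    }
    m <- log((a[keep] + pseudocount) / (b[keep] + pseudocount))
    if (var(m) == 0 || length(unique(treatment[keep])) < 2L) {
      warning("pair ", anchor, " / ", ot, " is degenerate; skipped",
              call. = FALSE)
      return(NULL)
    }
    med <- rep(NA_real_, length(a)); med[keep] <- m
    pa <- test_alpha(med, treatment, covariates)$p
    pb <- test_beta(med, treatment, outcome, covariates,
                    outcome_type = outcome_type)$p
    data.frame(taxon_left = anchor, taxon_right = ot,
               n_included = sum(keep), p_alpha = pa, p_beta = pb,
               p_max = max(pa, pb), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no testable pair under node ", node, call. = FALSE)
  }
  do.call(rbind, rows)
}
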