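#' Build per-node subcompositions and log-ratio mediators
#'
#' For every internal node of the tree, aggregates the counts over the leaf
#' taxa subtended by its left and right child, and forms the log-ratio
#' mediator `log((left + c) / (right + c))` with pseudocount `c`. Subjects
#' whose left and right aggregated counts are both zero carry no information
#' on that subcomposition and are masked out of the node's local model.
#'
#' @param tree a rooted tree (any input accepted by [read_tree_binary()]) or
#'   a `phylo_structure`.
#' @param counts subjects x taxa matrix (or data frame) of non-negative
#'   integer counts; column names must cover the tree's leaf labels.
#' @param pseudocount positive constant added to the two aggregated counts
#'   before the log ratio (default 0.5).
#' @param prune if `TRUE`, leaves missing from the count table (and count
#'   columns missing from the tree) are dropped with a message; by default a
#'   mismatch is an error, so data problems are not hidden.
#' @return A list of class `node_subcompositions` with `n x J` matrices
#'   `left`, `right`, `include` (logical mask), `mediator` (`NA` where
#'   excluded), the `structure`, and the `pseudocount`.
#' @examples
#' tr <- read_tree_binary("((t5,(t6,t7)),t8);")
#' cnt <- matrix(c(5, 6, 7, 2), 1, dimnames = list("s1", c("t5","t6","t7","t8")))
#' sub <- build_subcompositions(tr, cnt)
#' # node pairing t5 against (t6,t7): log((5+0.5)/(13+0.5))
#' sub$mediator[1, sub$structure$node_label == "t5|t6+1more"]
#' @export
build_subcompositions <- function(tree, counts, pseudocount = 0.5,
                                  prune = FALSE) {
  struct <- if (inherits(tree, "phylo_structure")) tree else phylo_structure(tree)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    stop("'pseudocount' must be a single positive number", call. = FALSE)
  }
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    stop("count matrix must have taxon column names", call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }

  missing_in_counts <- setdiff(struct$leaves, colnames(counts))
  extra_in_counts <- setdiff(colnames(counts), struct$leaves)
  if (length(missing_in_counts) > 0 || length(extra_in_counts) > 0) {
    if (!prune) {
      stop("tree leaves and count columns do not match (",
           length(missing_in_counts), " leaves missing from counts, ",
           length(extra_in_counts), " count columns not in tree); ",
           "use prune = TRUE to intersect them explicitly", call. = FALSE)
    }
    if (length(missing_in_counts) > 0) {
      keep <- setdiff(struct$leaves, missing_in_counts)
      if (length(keep) < 2L) {
        stop("fewer than 2 leaves remain after pruning", call. = FALSE)
      }
      message("pruning ", length(missing_in_counts),
              " tree leaf/leaves absent from the count table")
      struct <- phylo_structure(
        ape::drop.tip(struct$tree, missing_in_counts))
    }
    if (length(extra_in_counts) > 0) {
      message("ignoring ", length(extra_in_counts),
              " count column(s) absent from the tree")
    }
  }

  m <- counts[, struct$leaves, drop = FALSE]
  left <- m %*% struct$left_mat
  right <- m %*% struct$right_mat
  include <- !(left == 0 & right == 0)
  mediator <- log((left + pseudocount) / (right + pseudocount))
  mediator[!include] <- NA_real_
  colnames(left) <- colnames(right) <- colnames(include) <-
    colnames(mediator) <- struct$node_label

  structure(list(left = left, right = right, include = include,
                 mediator = mediator, structure = struct,
                 pseudocount = pseudocount),
            class = "node_subcompositions")
}

#' @export
print.node_subcompositions <- function(x, ...) {
  cat("Subcompositions at", x$structure$J, "internal nodes,",
      nrow(x$mediator), "subjects (pseudocount", x$pseudocount, ")\n")
  frac <- mean(x$include)
  cat(sprintf("Included subject-node pairs: %.1f%%\n", 100 * frac))
  invisible(x)
}
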