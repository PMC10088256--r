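#' Read a rooted tree and resolve it to binary form
#'
#' Parses a Newick tree (from a file, a literal Newick string, or an existing
#' [ape::phylo] object), validates it, and resolves any multifurcation into a
#' left-leaning binary cascade so that every internal node has exactly two
#' children. The subcomposition mediation model is defined only on rooted
#' binary trees, so this normalisation is applied up front. Branch lengths
#' play no role in the method and are discarded.
#'
#' Multifurcations are resolved deterministically: a node with children
#' `c1, c2, ..., ck` (in input order) becomes `(((c1,c2),c3),...,ck)`. An
#' unrooted tree presented with a trifurcating root is resolved the same way,
#' with a warning, which implicitly roots it on the last child.
#'
#' @param tree a file path, a Newick string (must contain a semicolon), or a
#'   `phylo` object.
#' @return An object of class `phylo`, rooted and fully binary.
#' @examples
#' tr <- read_tree_binary("((A,B),C);")
#' tr$Nnode  # 2 internal nodes for 3 leaves
#' @export
read_tree_binary <- function(tree) {
  if (inherits(tree, "phylo")) {
    phy <- tree
  } else if (is.character(tree) && length(tree) == 1L) {
    if (grepl(";", tree, fixed = TRUE)) {
      phy <- tryCatch(ape::read.tree(text = tree),
                      error = function(e) NULL)
    } else {
      if (!file.exists(tree)) {
        stop("tree file not found: ", tree, call. = FALSE)
      }
      phy <- tryCatch(ape::read.tree(tree), error = function(e) NULL)
    }
    if (is.null(phy)) {
      stop("failed to parse Newick tree input", call. = FALSE)
    }
  } else {
    stop("'tree' must be a phylo object, a Newick string, or a file path",
         call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels in tree: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "),
         call. = FALSE)
  }
  if (ape::Ntip(phy) < 2L) {
    stop("tree must have at least 2 leaves", call. = FALSE)
  }
  phy <- ape::collapse.singles(phy)
  # a rooted strictly binary tree with L leaves has exactly L - 1 internal
  # nodes (ape::is.binary would accept a trifurcating "unrooted" root)
  if (phy$Nnode != ape::Ntip(phy) - 1L) {
    nroot_children <- sum(phy$edge[, 1] == ape::Ntip(phy) + 1L)
    if (nroot_children > 2L) {
      warning("tree root is not bifurcating; resolving to a rooted binary ",
              "tree by a left-leaning cascade of the input child order",
              call. = FALSE)
    }
    phy <- .binarize_left(phy)
  }
  phy
}

# Resolve every multifurcation into a left-leaning binary cascade that
# follows the input child order. Implemented by rebuilding the Newick
# string recursively (topology only) and re-parsing, which keeps the ape
# numbering conventions intact.
.binarize_left <- function(phy) {
  L <- ape::Ntip(phy)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  quote_lab <- function(x) {
    ifelse(grepl("[ ,():;'\\[\\]]", x), paste0("'", gsub("'", "''", x), "'"), x)
  }
  rec <- function(node) {
    if (node <= L) {
      return(quote_lab(phy$tip.label[node]))
    }
    parts <- vapply(kids[[as.character(node)]], rec, character(1))
    while (length(parts) > 1L) {
      parts <- c(sprintf("(%s,%s)", parts[1L], parts[2L]), parts[-(1:2)])
    }
    parts
  }
  ape::read.tree(text = paste0(rec(L + 1L), ";"))
}

#' Index the internal nodes of a binary tree
#'
#' Builds the bookkeeping used throughout the pipeline: internal nodes are
#' indexed 1..J in post-order (stable across runs), and for each internal
#' node the sets of leaf taxa subtended by its left and right child are
#' recorded, together with 0/1 leaf-membership matrices used to aggregate
#' counts.
#'
#' @param tree a rooted binary tree (`phylo`), e.g. from [read_tree_binary()].
#' @return A list of class `phylo_structure` with elements:
#'   \describe{
#'     \item{tree}{the `phylo` object}
#'     \item{J}{number of internal nodes (`= L - 1` for `L` leaves)}
#'     \item{leaves}{leaf labels, in `tip.label` order}
#'     \item{left_leaves, right_leaves}{lists of leaf-label vectors per node}
#'     \item{left_mat, right_mat}{`L x J` membership matrices}
#'     \item{node_label}{human-readable label per node, built from the leaf
#'       sets of its two children}
#'     \item{parent}{for each internal node, the index of its parent internal
#'       node (`NA` for the root)}
#'   }
#' @export
phylo_structure <- function(tree) {
  phy <- read_tree_binary(tree)
  L <- ape::Ntip(phy)
  J <- phy$Nnode
  stopifnot(J == L - 1L)
  kids <- split(phy$edge[, 2], phy$edge[, 1])

  index <- integer(L + J)    # ape node id -> postorder index (internal only)
  left_set <- vector("list", J)
  right_set <- vector("list", J)
  left_child <- integer(J)
  right_child <- integer(J)
  counter <- 0L
  rec <- function(node) {
    if (node <= L) {
      return(node)    # leaf: return own leaf set implicitly via id
    }
    ch <- kids[[as.character(node)]]
    lset <- rec(ch[1L])
    rset <- rec(ch[2L])
    counter <<- counter + 1L
    j <- counter
    index[node] <<- j
    left_set[[j]] <<- lset
    right_set[[j]] <<- rset
    left_child[j] <<- ch[1L]
    right_child[j] <<- ch[2L]
    c(lset, rset)
  }
  rec(L + 1L)

  left_mat <- matrix(0, L, J)
  right_mat <- matrix(0, L, J)
  for (j in seq_len(J)) {
    left_mat[left_set[[j]], j] <- 1
    right_mat[right_set[[j]], j] <- 1
  }
  rownames(left_mat) <- rownames(right_mat) <- phy$tip.label

  describe <- function(ids) {
    labs <- phy$tip.label[ids]
    if (length(labs) > 2L) {
      paste0(labs[1L], "+", length(labs) - 1L, "more")
    } else {
      paste(labs, collapse = "+")
    }
  }
  node_label <- vapply(seq_len(J), function(j) {
    paste0(describe(left_set[[j]]), "|", describe(right_set[[j]]))
  }, character(1))

  parent <- rep(NA_integer_, J)
  for (j in seq_len(J)) {
    for (ch in c(left_child[j], right_child[j])) {
      if (ch > L) parent[index[ch]] <- j
    }
  }

  structure(list(tree = phy, J = J, leaves = phy$tip.label,
                 left_leaves = lapply(left_set, function(i) phy$tip.label[i]),
                 right_leaves = lapply(right_set, function(i) phy$tip.label[i]),
                 left_mat = left_mat, right_mat = right_mat,
                 node_label = node_label, parent = parent),
            class = "phylo_structure")
}

# Internal-node indices of all ancestors (inclusive path to root) of a set
# of leaf labels: a node is an ancestor of a leaf iff the leaf belongs to
# its subtended set.
.ancestor_nodes <- function(struct, leaves) {
  idx <- match(leaves, struct$leaves)
  if (anyNA(idx)) stop("unknown leaf label(s)")
  below <- struct$left_mat[idx, , drop = FALSE] +
    struct$right_mat[idx, , drop = FALSE]
  which(colSums(below > 0) > 0)
}

# Most recent common ancestor (as internal-node index) of a set of leaves:
# the ancestor with the smallest subtree.
.mrca_node <- function(struct, leaves) {
  anc <- .ancestor_nodes(struct, leaves)
  sizes <- colSums(struct$left_mat + struct$right_mat)[anc]
  anc[which.min(sizes)]
}
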