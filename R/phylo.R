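# Tree handling: parsing, deterministic branch identity, root-to-tip paths,
# and the Brownian-motion covariance with Pagel's lambda transform.
#
# The canonical container is ape's "phylo" object. On top of it this module
# enforces a branch-identity convention: every branch is named after its
# child node, and internal nodes that arrive unlabeled receive deterministic
# labels "N1", "N2", ... in postorder, so per-branch rate tables and trees
# can be joined reproducibly across runs and tools.

#' Parse a Newick string into a validated phylogeny
#'
#' Reads a Newick tree, validates it (branch lengths present, positive and
#' finite on every non-root edge; tip labels unique and non-empty) and
#' assigns deterministic postorder labels `"N<k>"` to unlabeled internal
#' nodes so that branches can be identified by their child-node label.
#'
#' Ultrametricity is checked (all root-to-tip path lengths equal within a
#' relative tolerance of 1e-6) but violations only raise a warning: real
#' time-calibrated trees exported from dating services routinely carry
#' rounding error, and the downstream regression remains defined.
#'
#' @param text Newick string (used when `file` is `NULL`).
#' @param file Optional path to a Newick file; overrides `text`.
#' @param ultrametric_tol Relative tolerance for the ultrametricity check.
#' @return An object of class `phylo` with complete, unique `node.label`s.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$node.label  # "N2" (root) and "N1" (A-B ancestor)
#' @export
parse_newick <- function(text = NULL, file = NULL, ultrametric_tol = 1e-6) {
  if (!is.null(file)) {
    if (!file.exists(file)) abort_data(sprintf("tree file not found: %s", file))
    tree <- tryCatch(suppressWarnings(ape::read.tree(file)),
                     error = function(e) NULL)
  } else {
    if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
      abort_data("Newick input must be a single non-empty string")
    }
    tree <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                     error = function(e) NULL)
  }
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort_data("malformed Newick string: could not be parsed")
  }
  validate_phylo(tree, ultrametric_tol = ultrametric_tol)
}

#' @keywords internal
validate_phylo <- function(tree, ultrametric_tol = 1e-6) {
  tips <- tree$tip.label
  if (any(!nzchar(tips))) abort_data("empty tip label in tree")
  dup <- tips[duplicated(tips)]
  if (length(dup)) {
    abort_data(sprintf("duplicate tip label(s): %s", paste(unique(dup), collapse = ", ")))
  }
  el <- tree$edge.length
  if (is.null(el) || length(el) != nrow(tree$edge)) {
    abort_data("tree is missing branch lengths on one or more edges")
  }
  bad <- which(!is.finite(el) | el <= 0)
  if (length(bad)) {
    child <- tree$edge[bad[1L], 2L]
    tok <- if (child <= length(tips)) tips[child] else sprintf("internal node #%d", child)
    abort_data(sprintf(
      "branch leading to '%s' has missing, zero or non-finite length", tok))
  }
  tree <- label_internal_nodes(tree)
  d <- root_to_tip_depths(tree)
  h <- max(d)
  if (h > 0 && (max(d) - min(d)) / h > ultrametric_tol) {
    warning(sprintf(
      "tree is not ultrametric: root-to-tip depths range %.6g to %.6g",
      min(d), max(d)), call. = FALSE)
  }
  tree
}

# Deterministic internal-node labels: walk edges in ape postorder, collect
# internal nodes in order of first appearance as a child, append the root,
# and fill any missing/empty label with "N<k>" by that index. Existing
# labels are kept; the result must be unique.
#' @keywords internal
label_internal_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  root <- n_tip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  children <- po$edge[, 2L]
  internal_seq <- unique(children[children > n_tip])
  internal_seq <- c(internal_seq, root[!(root %in% internal_seq)])
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_node)
  lab[is.na(lab)] <- ""
  for (k in seq_along(internal_seq)) {
    idx <- internal_seq[k] - n_tip
    if (!nzchar(lab[idx])) lab[idx] <- sprintf("N%d", k)
  }
  all_lab <- c(tree$tip.label, lab)
  if (anyDuplicated(all_lab)) {
    abort_data(sprintf("duplicate node label(s) after assignment: %s",
                       paste(unique(all_lab[duplicated(all_lab)]), collapse = ", ")))
  }
  tree$node.label <- lab
  tree
}

#' @keywords internal
node_labels <- function(tree) {
  c(tree$tip.label, tree$node.label)
}

#' Branch identifiers of a tree
#'
#' Every branch is named after its child node; internal nodes must already
#' carry labels (see [parse_newick()]).
#' @param tree A labeled `phylo` object.
#' @return Character vector of branch ids, one per edge, in edge-matrix order.
#' @export
branch_ids <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) tree <- label_internal_nodes(tree)
  node_labels(tree)[tree$edge[, 2L]]
}

#' @keywords internal
root_to_tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  stats::setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Root-to-tip branch path for one species
#'
#' Lists the branches on the path from the root down to `tip`, each branch
#' identified by its child-node label, ordered root first.
#'
#' @param tree A labeled `phylo` object.
#' @param tip A tip label.
#' @return Character vector of branch ids, root to tip.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' root_to_tip_path(tr, "A")  # "N1" "A"
#' @export
root_to_tip_path <- function(tree, tip) {
  if (is.null(tree$node.label)) tree <- label_internal_nodes(tree)
  i <- match(tip, tree$tip.label)
  if (is.na(i)) abort_data(sprintf("tip '%s' not found in tree", tip))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  path <- integer(0)
  node <- i
  while (node != root) {
    path <- c(node, path)
    node <- parent[node]
    if (node == 0L) abort_data("disconnected node encountered while tracing path")
  }
  node_labels(tree)[path]
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' `C[i, j]` is the shared path length from the root to the most recent
#' common ancestor of species i and j; the diagonal holds root-to-tip
#' distances. For an ultrametric tree the diagonal is constant and equals
#' the tree height. Computed via [ape::vcv.phylo()] and restricted to the
#' requested species in the requested order.
#'
#' @param tree A `phylo` object.
#' @param species Tip labels to include (default: all tips, tree order).
#' @return An object of class `phylo_vcv`: a list with `species`, the
#'   matrix `C`, and `height` (max diagonal entry).
#' @export
vcv_matrix <- function(tree, species = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(species, tree$tip.label)
  if (length(missing)) {
    abort_data(sprintf("species not in tree: %s", paste(missing, collapse = ", ")))
  }
  if (length(species) < 2L) abort_config("need at least 2 species for a covariance matrix")
  C <- ape::vcv.phylo(tree)[species, species, drop = FALSE]
  structure(list(species = species, C = C, height = max(diag(C))),
            class = "phylo_vcv")
}

#' @export
print.phylo_vcv <- function(x, ...) {
  cat(sprintf("Phylogenetic covariance: %d species, tree height %.6g\n",
              length(x$species), x$height))
  invisible(x)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies all off-diagonal entries by `lambda` while leaving the
#' diagonal untouched. `lambda = 1` returns the Brownian covariance
#' unchanged; `lambda = 0` removes all phylogenetic correlation.
#'
#' @param C A `phylo_vcv` object or a plain covariance matrix.
#' @param lambda Scalar in `[0, 1]`.
#' @return A plain numeric matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (inherits(C, "phylo_vcv")) C <- C$C
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    abort_config("lambda must be a single value in [0, 1]")
  }
  d <- diag(C)
  M <- C * lambda
  diag(M) <- d
  M
}

#' Is a tree ultrametric within tolerance?
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on root-to-tip depth spread.
#' @return Logical.
#' @export
is_ultrametric_tol <- function(tree, tol = 1e-6) {
  d <- root_to_tip_depths(tree)
  h <- max(d)
  h == 0 || (max(d) - min(d)) / h <= tol
}
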