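#' Phylogenetic gene-order alignment by steinerization
#'
#' Assigns a gene order to every internal node of a rooted binary species
#' tree so that the summed event cost over all branches is (locally)
#' minimal.  Initialization proceeds bottom-up, inferring each parent from
#' the sibling alignment of its two children; the iterative phase sweeps
#' the internal nodes and re-solves, for each node M with parent A and
#' children X, Y, the 3-star `A|XY`, adopting the new center only when the
#' sum of the three incident branch costs strictly decreases.  The root,
#' which has no ancestor, is re-estimated from the sibling alignment of
#' its two children.  The total tree cost is therefore non-increasing
#' across rounds and the loop stops at the first round with no
#' improvement.
#'
#' @param phy rooted binary tree of class `phylo` (ape).
#' @param genomes named list of gene orders; names must biject with the
#'   tip labels.
#' @param costs a [cost_scheme].
#' @param signed signed-genome semantics.
#' @return `initialize_assignments()`: an object of class
#'   `"assigned_tree"` — list with `phy`, `assignments` (one gene order
#'   per node, indexed like ape's node numbering), `costs`, `signed`.
#' @name tree_steinerization
NULL

node_children <- function(phy, node)
  phy$edge[phy$edge[, 1L] == node, 2L]

node_parent <- function(phy, node) {
  p <- phy$edge[phy$edge[, 2L] == node, 1L]
  if (length(p)) p else NA_integer_
}

check_tree <- function(phy, genomes) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo tree")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy))
    stop("non-binary tree: multifurcations are not supported")
  if (!setequal(phy$tip.label, names(genomes)) ||
      anyDuplicated(names(genomes)))
    stop("tip labels and genome ids must match one-to-one")
  invisible(TRUE)
}

node_labels <- function(phy) {
  ntip <- length(phy$tip.label)
  nl <- phy$node.label
  if (is.null(nl) || any(!nzchar(nl)))
    nl <- paste0("node", ntip + seq_len(phy$Nnode))
  c(phy$tip.label, nl)
}

#' @rdname tree_steinerization
#' @export
initialize_assignments <- function(phy, genomes, costs = unit_costs(),
                                   signed = TRUE) {
  check_tree(phy, genomes)
  ntip <- length(phy$tip.label)
  asg <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) {
    g <- as_genes(genomes[[phy$tip.label[i]]])
    if (is.null(genomes[[phy$tip.label[i]]]))
      stop("unassigned leaf: ", phy$tip.label[i])
    asg[[i]] <- g
  }
  po <- reorder_postorder(phy)
  for (p in po) {
    kids <- node_children(phy, p)
    asg[[p]] <- as_genes(infer_parent(
      align_siblings(asg[[kids[1L]]], asg[[kids[2L]]], costs, signed)))
  }
  structure(list(phy = phy, assignments = asg, costs = costs,
                 signed = signed),
            class = "assigned_tree")
}

# parents in a child-first order
reorder_postorder <- function(phy) {
  e <- reorder(phy, "postorder")$edge
  unique(e[, 1L])
}

branch_cost_ad <- function(tree, parent_g, child_g) {
  out <- tryCatch(
    align_directed(parent_g, child_g, tree$costs, tree$signed,
                   allow_gain = TRUE)$cost,
    error = function(e) Inf)
  out
}

#' @rdname tree_steinerization
#' @param tree an `assigned_tree`.
#' @return `tree_cost()`: the sum over all edges of the directed
#'   (ancestor to descendant) alignment cost.
#' @export
tree_cost <- function(tree) {
  stopifnot(inherits(tree, "assigned_tree"))
  asg <- tree$assignments
  if (any(vapply(seq_along(asg), function(i) is.null(asg[[i]]), TRUE)))
    stop("unassigned node")
  e <- tree$phy$edge
  sum(vapply(seq_len(nrow(e)), function(r)
    branch_cost_ad(tree, asg[[e[r, 1L]]], asg[[e[r, 2L]]]), numeric(1)))
}

#' @rdname tree_steinerization
#' @return `reoptimize_round()`: list with the updated tree, `improved`
#'   (logical) and `n_improved`.
#' @export
reoptimize_round <- function(tree, costs = tree$costs) {
  stopifnot(inherits(tree, "assigned_tree"))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  asg <- tree$assignments
  n_improved <- 0L
  for (v in reorder_postorder(phy)) {
    kids <- node_children(phy, v)
    X <- asg[[kids[1L]]]; Y <- asg[[kids[2L]]]
    if (v == root) {
      cand <- tryCatch(as_genes(infer_parent(
        align_siblings(X, Y, costs, tree$signed))), error = function(e) NULL)
      if (is.null(cand)) next
      cur <- branch_cost_ad(tree, asg[[v]], X) +
             branch_cost_ad(tree, asg[[v]], Y)
      new <- branch_cost_ad(tree, cand, X) + branch_cost_ad(tree, cand, Y)
    } else {
      A <- asg[[node_parent(phy, v)]]
      sol <- tryCatch(
        solve_star(star_instance(A, X, Y, costs, tree$signed)),
        error = function(e) NULL)
      if (is.null(sol)) next
      cand <- as_genes(sol$center)
      cur <- branch_cost_ad(tree, A, asg[[v]]) +
             branch_cost_ad(tree, asg[[v]], X) +
             branch_cost_ad(tree, asg[[v]], Y)
      new <- branch_cost_ad(tree, A, cand) +
             branch_cost_ad(tree, cand, X) + branch_cost_ad(tree, cand, Y)
    }
    if (is.finite(new) && new < cur - 1e-9) {
      asg[[v]] <- cand
      n_improved <- n_improved + 1L
    }
  }
  tree$assignments <- asg
  list(tree = tree, improved = n_improved > 0L, n_improved = n_improved)
}

#' Run the full steinerization loop
#'
#' @inheritParams tree_steinerization
#' @param max_rounds upper bound on reoptimization rounds (observed
#'   instances converge within a handful).
#' @return an `assigned_tree` with a `$rounds` data frame (round, cost,
#'   n_improved); round 0 is the initialization.
#' @export
run_steinerization <- function(phy, genomes, costs = unit_costs(),
                               max_rounds = 20L, signed = TRUE) {
  tree <- initialize_assignments(phy, genomes, costs, signed)
  log <- data.frame(round = 0L, cost = tree_cost(tree), n_improved = NA_integer_)
  for (r in seq_len(max_rounds)) {
    step <- reoptimize_round(tree)
    tree <- step$tree
    log <- rbind(log, data.frame(round = r, cost = tree_cost(tree),
                                 n_improved = step$n_improved))
    if (!step$improved) break
  }
  tree$rounds <- log
  tree
}

#' @export
print.assigned_tree <- function(x, ...) {
  ntip <- length(x$phy$tip.label)
  cat("assigned tree:", ntip, "leaves,", x$phy$Nnode, "internal nodes\n")
  if (!is.null(x$rounds)) {
    cat(" cost by round:",
        paste(x$rounds$cost, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Gap-consistent multiple alignment of all node genomes
#'
#' Merges the directed parent-child alignments bottom-up into one multiple
#' alignment containing a row for every node of the tree (leaves and
#' assigned ancestors).
#'
#' @param tree a fully assigned `assigned_tree`.
#' @return character matrix with one row per node and `"-"` for gaps; no
#'   column is all-gap.
#' @export
build_multiple_alignment <- function(tree) {
  stopifnot(inherits(tree, "assigned_tree"))
  phy <- tree$phy
  asg <- tree$assignments
  labels <- node_labels(phy)
  ntip <- length(phy$tip.label)
  block <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip))
    block[[i]] <- matrix(asg[[i]], nrow = 1L,
                         dimnames = list(labels[i], NULL))
  for (p in reorder_postorder(phy)) {
    pb <- matrix(asg[[p]], nrow = 1L, dimnames = list(labels[p], NULL))
    for (kid in node_children(phy, p)) {
      pw <- align_directed(asg[[p]], asg[[kid]], tree$costs, tree$signed,
                           allow_gain = TRUE)$alignment
      pb <- merge_blocks(pb, labels[p], block[[kid]], labels[kid],
                         pw$rows[1L, ], pw$rows[2L, ])
    }
    block[[p]] <- pb
  }
  block[[ntip + 1L]]
}

# merge two alignment blocks through a pairwise alignment of their
# reference rows (anc = parent reference, desc = child reference)
merge_blocks <- function(pb, pref, cb, cref, anc, desc) {
  pv <- pb[pref, ]; cv <- cb[cref, ]
  stopifnot(sum(pv != "-") == sum(anc != "-"),
            sum(cv != "-") == sum(desc != "-"))
  pi <- 1L; ci <- 1L
  np <- length(pv); nc <- length(cv)
  out_p <- integer(); out_c <- integer() # 0 = filler gap column
  for (t in seq_along(anc)) {
    if (anc[t] != "-")
      while (pi <= np && pv[pi] == "-") {
        out_p <- c(out_p, pi); out_c <- c(out_c, 0L); pi <- pi + 1L
      }
    if (desc[t] != "-")
      while (ci <= nc && cv[ci] == "-") {
        out_p <- c(out_p, 0L); out_c <- c(out_c, ci); ci <- ci + 1L
      }
    if (anc[t] != "-" && desc[t] != "-") {
      out_p <- c(out_p, pi); out_c <- c(out_c, ci)
      pi <- pi + 1L; ci <- ci + 1L
    } else if (anc[t] != "-") {
      out_p <- c(out_p, pi); out_c <- c(out_c, 0L); pi <- pi + 1L
    } else if (desc[t] != "-") {
      out_p <- c(out_p, 0L); out_c <- c(out_c, ci); ci <- ci + 1L
    }
  }
  while (pi <= np) { out_p <- c(out_p, pi); out_c <- c(out_c, 0L); pi <- pi + 1L }
  while (ci <= nc) { out_p <- c(out_p, 0L); out_c <- c(out_c, ci); ci <- ci + 1L }
  lambda <- length(out_p)
  res <- matrix("-", nrow(pb) + nrow(cb), lambda,
                dimnames = list(c(rownames(pb), rownames(cb)), NULL))
  pk <- which(out_p > 0L)
  if (length(pk)) res[seq_len(nrow(pb)), pk] <- pb[, out_p[pk], drop = FALSE]
  ck <- which(out_c > 0L)
  if (length(ck))
    res[nrow(pb) + seq_len(nrow(cb)), ck] <- cb[, out_c[ck], drop = FALSE]
  res
}
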