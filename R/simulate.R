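#' Simulate gene-order evolution with ground truth
#'
#' Instances are generated by the protocol used throughout the package's
#' experiments: the genome at the top of the tree is a uniform random
#' sequence of `n` genes over `sigma` families to which `l` moves are
#' applied; every other genome is obtained by applying `l` moves to its
#' direct ancestor.  Under the `"dup_singleloss"` model a move is, with
#' equal probability, a duplication (length drawn from a geometric
#' distribution with parameter `dup_length_p`, support starting at 1,
#' source start and insertion point uniform with the copy placed outside
#' its source) or the loss of one uniformly chosen gene.  The
#' `"dup_loss_reversal"` model draws duplications, single-gene losses and
#' reversals (geometric length, uniform position) with equal probability.
#' A loss that would empty the genome is resampled.
#'
#' The event mixture and position distributions beyond those stated above
#' are the package's own defaults and are recorded in the instance.
#'
#' @param n root genome length (genes).
#' @param sigma alphabet size (number of gene families).
#' @param l moves per branch.
#' @param model `"dup_singleloss"` (default) or `"dup_loss_reversal"`.
#' @param dup_length_p geometric parameter for duplication (and reversal)
#'   lengths; mean length `1/p`.
#' @return `sim_params()`: a parameter object of class `"sim_params"`.
#' @name evolution_simulator
NULL

#' @rdname evolution_simulator
#' @export
sim_params <- function(n = 100L, sigma = 50L, l = 5L,
                       model = c("dup_singleloss", "dup_loss_reversal"),
                       dup_length_p = 0.5) {
  model <- match.arg(model)
  stopifnot(n >= 0L, sigma >= 0L, l >= 0L,
            dup_length_p > 0, dup_length_p <= 1)
  structure(list(n = as.integer(n), sigma = as.integer(sigma),
                 l = as.integer(l), model = model,
                 dup_length_p = dup_length_p),
            class = "sim_params")
}

#' @rdname evolution_simulator
#' @param id genome identifier.
#' @return `random_genome()`: a [gene_order] of `n` uniform draws over
#'   `sigma` families, all on the forward strand.
#' @export
random_genome <- function(n, sigma, id = NULL) {
  if (n > 0L && sigma < 1L) stop("sigma must be >= 1 when n >= 1")
  if (n == 0L) return(gene_order(character(), id = id))
  gene_order(paste0("g", sample.int(sigma, n, replace = TRUE)), id = id)
}

geom_len <- function(p, cap) {
  k <- stats::rgeom(1L, p) + 1L
  min(k, cap)
}

#' @rdname evolution_simulator
#' @param genome starting gene order.
#' @param params a `sim_params`.
#' @return `apply_moves()`: list with the derived `genome` and the true
#'   `history` (replayable [evo_op] list).
#' @export
apply_moves <- function(genome, l, params = sim_params()) {
  g <- as_genes(genome)
  if (!length(g) && l > 0L) stop("cannot apply moves to an empty genome")
  kinds <- switch(params$model,
    dup_singleloss = c("duplication", "loss"),
    dup_loss_reversal = c("duplication", "loss", "reversal"))
  hist <- list()
  for (t in seq_len(l)) {
    repeat {
      kind <- sample(kinds, 1L)
      n0 <- length(g)
      if (kind == "loss" && n0 <= 1L) next # would empty the genome
      op <- switch(kind,
        duplication = {
          k <- geom_len(params$dup_length_p, n0)
          i <- sample.int(n0 - k + 1L, 1L)
          bad <- if (k > 1L) i:(i + k - 2L) else integer()
          slots <- setdiff(0:n0, bad)
          j <- slots[sample.int(length(slots), 1L)]
          op_duplication(k, tgt_pos = j + 1L, src_start = i)
        },
        loss = op_loss(sample.int(n0, 1L), 1L),
        reversal = {
          k <- geom_len(params$dup_length_p, n0)
          op_reversal(sample.int(n0 - k + 1L, 1L), k)
        })
      break
    }
    g <- as_genes(replay_history(g, list(op)))
    hist[[length(hist) + 1L]] <- op
  }
  list(genome = gene_order(g, id = genome_id(genome)),
       history = structure(hist, class = "evo_history"))
}

#' @rdname evolution_simulator
#' @param topology a rooted binary `phylo` tree, or an integer leaf count
#'   (a random topology is then generated).
#' @return `simulate_tree()`: object of class `"simulated_instance"` with
#'   the tree, the leaf `genomes`, the `truth` (every node's genome), the
#'   per-edge true `histories` and the parameters.  Every branch carries
#'   exactly `l` true events.
#' @export
simulate_tree <- function(topology, params = sim_params()) {
  phy <- if (inherits(topology, "phylo")) topology
         else ape::rtree(as.integer(topology), rooted = TRUE, br = NULL)
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("topology must be a rooted binary tree")
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  asg <- vector("list", ntip + phy$Nnode)
  asg[[root]] <- as_genes(apply_moves(
    random_genome(params$n, params$sigma), params$l, params)$genome)
  e <- reorder(phy, "postorder")$edge
  histories <- vector("list", nrow(phy$edge))
  for (r in rev(seq_len(nrow(e)))) { # preorder over the postorder edges
    parent <- e[r, 1L]; child <- e[r, 2L]
    mv <- apply_moves(asg[[parent]], params$l, params)
    asg[[child]] <- as_genes(mv$genome)
    row <- which(phy$edge[, 1L] == parent & phy$edge[, 2L] == child)
    histories[[row]] <- mv$history
  }
  genomes <- stats::setNames(lapply(seq_len(ntip), function(i) {
    gene_order(asg[[i]], id = phy$tip.label[i])
  }), phy$tip.label)
  structure(list(phy = phy, genomes = genomes, truth = asg,
                 histories = histories, params = params,
                 true_total = params$l * nrow(phy$edge)),
            class = "simulated_instance")
}

#' @rdname evolution_simulator
#' @details `simulate_star()` generates one 3-star instance: the ancestor
#'   A by the root procedure, the true center by `l` moves from A, and
#'   the two siblings by `l` moves each from the center.
#' @return `simulate_star()`: list with `A`, `X`, `Y`, `M_true`, the three
#'   true branch histories and the parameters.
#' @export
simulate_star <- function(params = sim_params()) {
  A <- apply_moves(random_genome(params$n, params$sigma, id = "A"),
                   params$l, params)$genome
  m <- apply_moves(A, params$l, params)
  x <- apply_moves(m$genome, params$l, params)
  y <- apply_moves(m$genome, params$l, params)
  list(A = gene_order(as_genes(A), id = "A"),
       X = gene_order(as_genes(x$genome), id = "X"),
       Y = gene_order(as_genes(y$genome), id = "Y"),
       M_true = gene_order(as_genes(m$genome), id = "M"),
       histories = list("A>M" = m$history, "M>X" = x$history,
                        "M>Y" = y$history),
       params = params)
}

#' Evaluation statistics
#'
#' `error` is the relative excess of the inferred event count over the
#' reference optimum, `(Inf - Opt)/Inf`; `accuracy` is the fraction of
#' instances on which the inferred count equals the reference.
#'
#' @param inferred inferred event count (`Inf` in the usual notation).
#' @param optimal reference optimal event count.
#' @param n_optimal,total counts for the accuracy ratio (optional).
#' @return list with `error` and (when counts are given) `accuracy`.
#' @export
evaluation_metrics <- function(inferred, optimal, n_optimal = NULL,
                               total = NULL) {
  if (inferred == 0 && optimal != 0)
    stop("inferred count is zero but the reference is not")
  err <- if (inferred == 0) 0 else (inferred - optimal) / inferred
  out <- list(error = err)
  if (!is.null(n_optimal) && !is.null(total)) {
    stopifnot(total > 0)
    out$accuracy <- n_optimal / total
  }
  out
}
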