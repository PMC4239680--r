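#' Extract the center genome and branch histories from a feasible
#' labeled alignment
#'
#' Given a feasible (cycle-free) three-row labeled alignment, the hidden
#' center M is read off the column interpretations, and each branch's
#' events are ordered into a replayable history: losses first (right to
#' left), then reversals, then duplications left to right, all in the
#' coordinates of the genome they apply to.  Every history is replayed on
#' construction and must reproduce the corresponding endpoint exactly.
#'
#' @param alignment a feasible [labeled_alignment] in `"star"` mode.
#' @param costs a [cost_scheme] used to price the labeling.
#' @return object of class `"star_solution"`: list with `center` (a
#'   [gene_order]), `histories` (named list `A>M`, `M>X`, `M>Y`), `cost`,
#'   `branch_costs` and the `alignment`.
#' @export
extract_center <- function(alignment, costs = unit_costs()) {
  stopifnot(inherits(alignment, "labeled_alignment"),
            alignment$mode == "star")
  if (length(find_cycles(build_overlap_graph(alignment))))
    stop("alignment is infeasible: resolve cycles first")
  center <- gene_order(alignment$center[alignment$center != "-"], id = "M")
  branches <- c("A>M", "M>X", "M>Y")
  histories <- lapply(branches, function(b)
    build_branch_history(alignment, b, costs))
  names(histories) <- branches
  branch_costs <- vapply(histories, attr, numeric(1), "cost")
  structure(list(center = center, histories = histories,
                 cost = labeling_cost(alignment, costs),
                 branch_costs = branch_costs, alignment = alignment),
            class = "star_solution")
}

# order the events of one branch into a replayable history and verify it
build_branch_history <- function(aln, branch, costs = unit_costs()) {
  anc_role <- branch_from(branch)
  desc_role <- branch_to(branch)
  anc <- role_row(aln, anc_role)
  desc <- role_row(aln, desc_role)
  evs <- Filter(function(e) e$branch == branch, aln$events)
  ops <- list()

  anc_pos <- cumsum(anc != "-")
  skel <- anc != "-" & desc != "-"

  losses <- Filter(function(e) e$kind == "loss", evs)
  if (length(losses)) {
    starts <- vapply(losses, function(e) anc_pos[e$cols[1L]], 1)
    for (e in losses[order(-starts)])
      ops[[length(ops) + 1L]] <- op_loss(anc_pos[e$cols[1L]], e$length)
  }
  revs <- Filter(function(e) e$kind == "reversal", evs)
  if (length(revs)) {
    starts <- vapply(revs, function(e) e$cols[1L], 1L)
    for (e in revs[order(starts)]) {
      pos <- sum(skel[seq_len(e$cols[1L] - 1L)]) + 1L
      seg_anc <- anc[e$cols]
      seg_desc <- desc[e$cols]
      if (!identical(seg_desc, reverse_of(seg_anc, signed = aln$signed)))
        stop("internal error: reversal content mismatch")
      ops[[length(ops) + 1L]] <- op_reversal(pos, e$length,
                                             signed = aln$signed)
    }
  }
  dups <- Filter(function(e) e$kind == "duplication", evs)
  if (length(dups)) {
    desc_ng <- desc != "-"
    starts <- vapply(dups, function(e) e$cols[1L], 1L)
    for (e in dups[order(starts)]) {
      tgt <- sum(desc_ng[seq_len(e$cols[1L] - 1L)]) + 1L
      content <- desc[e$cols]
      if (any(content == "-"))
        stop("internal error: duplication target crosses a gap")
      op <- op_duplication(e$length, tgt_pos = tgt, content = content)
      op$src_meta <- e$src
      ops[[length(ops) + 1L]] <- op
    }
  }
  h <- structure(ops, class = "evo_history")
  got <- as_genes(replay_history(anc[anc != "-"], h))
  want <- desc[desc != "-"]
  if (!identical(got, want))
    stop("internal error: branch history for ", branch,
         " does not replay to its endpoint")
  attr(h, "cost") <- history_cost(h, costs)
  h
}

#' Solve a 3-star instance
#'
#' The full heuristic pipeline for the directed median problem: fill the
#' DP table, backtrack to a labeled alignment, repair any duplication
#' cycles, and extract the center genome with its three branch histories.
#' The returned cost is the cost of the feasible labeling (at least the DP
#' optimum whenever repairs were needed) and is an upper bound on the true
#' optimum; the heuristic carries no optimality guarantee.
#'
#' @param instance a [star_instance].
#' @return a `star_solution`; `$dp_cost` carries the pre-repair table
#'   value.
#' @examples
#' sol <- solve_star(star_instance("ab", c("a", "b", "a", "b"),
#'                                 c("a", "b", "a", "b")))
#' sol$cost     # 1 (one duplication above the center)
#' sol$center
#' @export
solve_star <- function(instance) {
  stopifnot(inherits(instance, "star_instance"))
  tab <- compute_dp(instance)
  aln <- backtrack_alignment(tab, instance)
  aln <- resolve_cycles(aln, instance)
  sol <- extract_center(aln, costs = instance$costs)
  sol$dp_cost <- attr(aln, "dp_cost")
  sol
}

#' @export
print.star_solution <- function(x, ...) {
  cat("3-star solution: cost ", x$cost, "\n", sep = "")
  cat(" center: ", paste(as_genes(x$center), collapse = " "), "\n", sep = "")
  bc <- x$branch_costs
  cat(" branch costs:", paste(names(bc), bc, sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}
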