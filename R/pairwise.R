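#' Pairwise labeled alignment
#'
#' Two-row restrictions of the 3-star dynamic program, used to initialise
#' the tree and to price branches:
#'
#' * `align_siblings()` aligns the two children of a cherry; each column
#'   is read as a match, a block lost in one child (the parent keeps it),
#'   a block duplicated in one child (the parent lacks it; the source must
#'   occur elsewhere in either child), or a reversed block.  The implied
#'   parent is recovered with [infer_parent()].
#' * `align_directed()` aligns an ancestor A with a descendant X; every
#'   event has its source on the A side and its target on the X side.
#'   With `allow_gain = TRUE`, a block of X whose content occurs nowhere
#'   in A or elsewhere in X is priced as per-gene duplications from an
#'   unobserved lineage instead of making the instance infeasible.
#'
#' Both aligners run cycle resolution on their labeling, so the returned
#' alignment is always feasible and the branch histories replay exactly.
#'
#' @param X,Y,A gene orders.
#' @param costs a [cost_scheme].
#' @param signed signed-genome semantics for reversals.
#' @param allow_gain see above (directed mode only).
#' @return object of class `"pair_alignment"`: list with `alignment`,
#'   `cost`, `histories` (one per branch), `inferred_parent` (siblings
#'   mode) and `dp_cost`.
#' @examples
#' r <- align_siblings(c("a", "b", "a", "b"), c("a", "b"))
#' r$cost
#' infer_parent(r)
#' @name pairwise_alignment
NULL

#' @rdname pairwise_alignment
#' @export
align_directed <- function(A, X, costs = unit_costs(), signed = TRUE,
                           allow_gain = FALSE) {
  idA <- genome_id(A, "A"); idX <- genome_id(X, "X")
  A <- as_genes(A); X <- as_genes(X)
  nA <- length(A); nX <- length(X)
  maxn <- max(nA, nX, 1L)
  cd <- cost_vector(costs, "duplication", maxn)
  cl <- cost_vector(costs, "loss", maxn)
  cr <- cost_vector(costs, "reversal", maxn)
  enc <- encode_genomes(list(A, X))
  dp <- .pair_directed_dp_cpp(enc$encoded[[1L]], enc$encoded[[2L]],
                              cd, cl, cr, signed, allow_gain)
  C <- dp$cost; CS <- dp$case; MM <- dp$m
  if (!is.finite(C[nA + 1L, nX + 1L]))
    stop("no directed labeled alignment exists (a block of the ",
         "descendant occurs nowhere; consider allow_gain = TRUE)")

  # backtrack
  i <- nA; j <- nX
  blocks <- list()
  while (i > 0L || j > 0L) {
    cs <- CS[i + 1L, j + 1L]; m <- MM[i + 1L, j + 1L]
    if (cs == 0L) stop("corrupted backpointers")
    gap <- rep("-", m)
    blk <- switch(cs,
      list(a = A[i], x = X[j], evs = list(), da = 1L, dx = 1L),
      list(a = A[(i - m + 1L):i], x = gap,
           evs = list(list(kind = "loss", len = m)), da = m, dx = 0L),
      list(a = A[(i - m + 1L):i], x = X[(j - m + 1L):j],
           evs = list(list(kind = "reversal", len = m)), da = m, dx = m),
      list(a = gap, x = X[(j - m + 1L):j],
           evs = list(list(kind = "duplication", len = m)),
           da = 0L, dx = m),
      list(a = "-", x = X[j],
           evs = list(list(kind = "duplication", len = 1L, orphan = TRUE)),
           da = 0L, dx = 1L))
    blocks[[length(blocks) + 1L]] <- blk
    i <- i - blk$da; j <- j - blk$dx
  }
  blocks <- rev(blocks)
  arow <- unlist(lapply(blocks, `[[`, "a"), use.names = FALSE)
  xrow <- unlist(lapply(blocks, `[[`, "x"), use.names = FALSE)
  if (is.null(arow)) arow <- xrow <- character()
  rows <- rbind(arow, xrow)
  rownames(rows) <- make.unique(c(idA, idX))
  aln <- new_labeled_alignment(rows, "directed",
                               list(A = rownames(rows)[1L],
                                    X = rownames(rows)[2L]),
                               center = NULL, events = list(),
                               signed = signed)
  events <- list()
  at <- 0L
  for (blk in blocks) {
    w <- max(blk$da, blk$dx)
    cols <- (at + 1L):(at + w)
    for (e in blk$evs) {
      ev <- aln_event(e$kind, e$len, "A>X", cols,
                      orphan = isTRUE(e$orphan))
      if (ev$kind == "duplication" && !ev$orphan) {
        content <- xrow[cols]
        occA <- find_occurrences(content, A)
        if (length(occA)) ev$src <- list(genome = "A", start = occA[1L])
        else {
          posX <- cumsum(xrow != "-")[cols]
          occX <- find_occurrences(content, X,
                                   exclude = c(posX[1L], posX[length(posX)]))
          if (!length(occX))
            stop("internal error: no duplication source in directed DP")
          ev$src <- list(genome = "X", start = occX[1L])
        }
      } else if (ev$kind == "duplication") {
        ev$src <- list(genome = "external", start = NA_integer_)
      }
      events[[length(events) + 1L]] <- ev
    }
    at <- at + w
  }
  aln$events <- events
  attr(aln, "dp_cost") <- C[nA + 1L, nX + 1L]
  aln <- resolve_cycles(aln, instance = A, allow_orphan = allow_gain)
  h <- build_branch_history(aln, "A>X", costs)
  structure(list(alignment = aln, cost = labeling_cost(aln, costs),
                 histories = list("A>X" = h), inferred_parent = NULL,
                 dp_cost = attr(aln, "dp_cost")),
            class = "pair_alignment")
}

#' @rdname pairwise_alignment
#' @export
align_siblings <- function(X, Y, costs = unit_costs(), signed = TRUE) {
  idX <- genome_id(X, "X"); idY <- genome_id(Y, "Y")
  X <- as_genes(X); Y <- as_genes(Y)
  nX <- length(X); nY <- length(Y)
  maxn <- max(nX, nY, 1L)
  cd <- cost_vector(costs, "duplication", maxn)
  cl <- cost_vector(costs, "loss", maxn)
  cr <- cost_vector(costs, "reversal", maxn)
  # cases: 1 match, 2 loss in Y, 3 loss in X, 4 reversal, 5 dup in X,
  # 6 dup in Y; priority match > losses > reversal > duplications
  enc <- encode_genomes(list(X, Y))
  dp <- .pair_siblings_dp_cpp(enc$encoded[[1L]], enc$encoded[[2L]],
                              cd, cl, cr, signed)
  C <- dp$cost; CS <- dp$case; MM <- dp$m
  if (!is.finite(C[nX + 1L, nY + 1L]))
    stop("no sibling labeled alignment exists for these genomes")

  j <- nX; k <- nY
  blocks <- list()
  while (j > 0L || k > 0L) {
    cs <- CS[j + 1L, k + 1L]; m <- MM[j + 1L, k + 1L]
    if (cs == 0L) stop("corrupted backpointers")
    gap <- rep("-", m)
    segX <- if (j >= m) X[(j - m + 1L):j] else NULL
    segY <- if (k >= m) Y[(k - m + 1L):k] else NULL
    blk <- switch(cs,
      list(x = X[j], y = Y[k], m = X[j], evs = list(), dx = 1L, dy = 1L),
      list(x = segX, y = gap, m = segX,
           evs = list(list(kind = "loss", branch = "P>Y", len = m)),
           dx = m, dy = 0L),
      list(x = gap, y = segY, m = segY,
           evs = list(list(kind = "loss", branch = "P>X", len = m)),
           dx = 0L, dy = m),
      list(x = segX, y = segY, m = segY,
           evs = list(list(kind = "reversal", branch = "P>X", len = m)),
           dx = m, dy = m),
      list(x = segX, y = gap, m = gap,
           evs = list(list(kind = "duplication", branch = "P>X", len = m)),
           dx = m, dy = 0L),
      list(x = gap, y = segY, m = gap,
           evs = list(list(kind = "duplication", branch = "P>Y", len = m)),
           dx = 0L, dy = m))
    blocks[[length(blocks) + 1L]] <- blk
    j <- j - blk$dx; k <- k - blk$dy
  }
  blocks <- rev(blocks)
  xrow <- unlist(lapply(blocks, `[[`, "x"), use.names = FALSE)
  yrow <- unlist(lapply(blocks, `[[`, "y"), use.names = FALSE)
  center <- unlist(lapply(blocks, `[[`, "m"), use.names = FALSE)
  if (is.null(xrow)) xrow <- yrow <- center <- character()
  rows <- rbind(xrow, yrow)
  rownames(rows) <- make.unique(c(idX, idY))
  aln <- new_labeled_alignment(rows, "siblings",
                               list(X = rownames(rows)[1L],
                                    Y = rownames(rows)[2L]),
                               center = center, events = list(),
                               signed = signed)
  events <- list()
  at <- 0L
  for (blk in blocks) {
    w <- max(blk$dx, blk$dy)
    cols <- (at + 1L):(at + w)
    for (e in blk$evs) {
      ev <- aln_event(e$kind, e$len, e$branch, cols)
      if (ev$kind == "duplication") {
        child <- branch_to(ev$branch)
        own <- if (child == "X") X else Y
        oth <- if (child == "X") Y else X
        othrole <- if (child == "X") "Y" else "X"
        row <- if (child == "X") xrow else yrow
        content <- row[cols]
        pos <- cumsum(row != "-")[cols]
        occ_self <- find_occurrences(content, own,
                                     exclude = c(pos[1L], pos[length(pos)]))
        if (length(occ_self))
          ev$src <- list(genome = child, start = occ_self[1L])
        else {
          occ_oth <- find_occurrences(content, oth)
          if (!length(occ_oth))
            stop("internal error: no duplication source in sibling DP")
          ev$src <- list(genome = othrole, start = occ_oth[1L])
        }
      }
      events[[length(events) + 1L]] <- ev
    }
    at <- at + w
  }
  aln$events <- events
  attr(aln, "dp_cost") <- C[nX + 1L, nY + 1L]
  aln <- resolve_cycles(aln)
  hx <- build_branch_history(aln, "P>X", costs)
  hy <- build_branch_history(aln, "P>Y", costs)
  parent <- gene_order(aln$center[aln$center != "-"], id = "P")
  structure(list(alignment = aln, cost = labeling_cost(aln, costs),
                 histories = list("P>X" = hx, "P>Y" = hy),
                 inferred_parent = parent,
                 dp_cost = attr(aln, "dp_cost")),
            class = "pair_alignment")
}

#' Infer the parent of a cherry
#'
#' Reads the parent genome off a feasible sibling alignment: matches and
#' blocks lost in one child are kept (the parent had them), duplicated
#' blocks are dropped (the parent lacked them), and a reversed block
#' contributes the ancestral reading.
#'
#' @param x a `pair_alignment` from [align_siblings()], or a feasible
#'   sibling-mode [labeled_alignment].
#' @return the parent as a [gene_order].
#' @export
infer_parent <- function(x) {
  if (inherits(x, "pair_alignment")) return(x$inferred_parent)
  stopifnot(inherits(x, "labeled_alignment"), x$mode == "siblings")
  if (length(find_cycles(build_overlap_graph(x))))
    stop("alignment is infeasible: resolve cycles first")
  gene_order(x$center[x$center != "-"], id = "P")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat("pairwise labeled alignment: cost ", x$cost, "\n", sep = "")
  print(x$alignment)
  if (!is.null(x$inferred_parent))
    cat(" parent: ", paste(as_genes(x$inferred_parent), collapse = " "),
        "\n", sep = "")
  invisible(x)
}
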