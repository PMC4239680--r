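#' Backtrack a 3-star DP table into a labeled alignment
#'
#' Reconstructs the three-row alignment and its labeling from the
#' backpointers of a computed table, together with the column-aligned
#' center implied by the case interpretations.  Duplication sources are
#' resolved here: events inferred on the branch above the center draw
#' their source from A, while solo duplications in a child prefer a source
#' in A, then a disjoint occurrence in the child itself, then the other
#' child (the cross-genome reading that subsumes transpositions).
#'
#' The result is not necessarily feasible: circular chains of duplications
#' may remain and are removed by [resolve_cycles()].
#'
#' @param table a `dp_table` from [compute_dp()].
#' @param instance the [star_instance] the table was computed from.
#' @return a [labeled_alignment] in `"star"` mode; attribute `dp_cost`
#'   carries the table's final cell.
#' @export
backtrack_alignment <- function(table, instance = table$instance) {
  A <- instance$A; X <- instance$X; Y <- instance$Y
  i <- length(A); j <- length(X); k <- length(Y)
  final_cost <- table$cost[i + 1L, j + 1L, k + 1L]
  if (!is.finite(final_cost))
    stop("the instance admits no labeled alignment under this cost scheme")

  blocks <- list() # collected right-to-left
  while (i > 0L || j > 0L || k > 0L) {
    cs <- table$case[i + 1L, j + 1L, k + 1L]
    m <- table$m[i + 1L, j + 1L, k + 1L]
    if (cs == 0L || m == 0L) stop("corrupted backpointers")
    gap <- rep("-", m)
    segA <- if (i >= m) A[(i - m + 1L):i] else NULL
    segX <- if (j >= m) X[(j - m + 1L):j] else NULL
    segY <- if (k >= m) Y[(k - m + 1L):k] else NULL
    ev <- function(kind, branch, src_rule = NULL)
      list(kind = kind, branch = branch, src_rule = src_rule, len = m)
    blk <- switch(as.character(cs),
      "1" = list(a = A[i], x = X[j], y = Y[k], m = A[i], evs = list(),
                 da = 1L, dx = 1L, dy = 1L),
      "2" = list(a = segA, x = segX, y = segY, m = segX,
                 evs = list(ev("reversal", "A>M")),
                 da = m, dx = m, dy = m),
      "3" = list(a = segA, x = segX, y = segY, m = segA,
                 evs = list(ev("reversal", "M>X")),
                 da = m, dx = m, dy = m),
      "4" = list(a = segA, x = segX, y = segY, m = segA,
                 evs = list(ev("reversal", "M>Y")),
                 da = m, dx = m, dy = m),
      "5" = list(a = gap, x = segX, y = segY, m = segX,
                 evs = list(ev("duplication", "A>M", "A")),
                 da = 0L, dx = m, dy = m),
      "6" = list(a = segA, x = segX, y = gap, m = segX,
                 evs = list(ev("reversal", "A>M"), ev("loss", "M>Y")),
                 da = m, dx = m, dy = 0L),
      "7" = list(a = segA, x = gap, y = segY, m = segY,
                 evs = list(ev("reversal", "A>M"), ev("loss", "M>X")),
                 da = m, dx = 0L, dy = m),
      "8" = list(a = gap, x = segX, y = segY, m = segX,
                 evs = list(ev("duplication", "A>M", "A"),
                            ev("reversal", "M>Y")),
                 da = 0L, dx = m, dy = m),
      "9" = list(a = gap, x = segX, y = segY, m = segY,
                 evs = list(ev("duplication", "A>M", "A"),
                            ev("reversal", "M>X")),
                 da = 0L, dx = m, dy = m),
      "10" = list(a = segA, x = gap, y = segY, m = segA,
                  evs = list(ev("loss", "M>X")),
                  da = m, dx = 0L, dy = m),
      "11" = list(a = segA, x = segX, y = gap, m = segA,
                  evs = list(ev("loss", "M>Y")),
                  da = m, dx = m, dy = 0L),
      "12" = list(a = segA, x = gap, y = gap, m = gap,
                  evs = list(ev("loss", "A>M")),
                  da = m, dx = 0L, dy = 0L),
      "13" = list(a = gap, x = segX, y = gap, m = gap,
                  evs = list(ev("duplication", "M>X", "solo")),
                  da = 0L, dx = m, dy = 0L),
      "14" = list(a = gap, x = gap, y = segY, m = gap,
                  evs = list(ev("duplication", "M>Y", "solo")),
                  da = 0L, dx = 0L, dy = m),
      stop("unknown case id ", cs))
    blocks[[length(blocks) + 1L]] <- blk
    i <- i - blk$da; j <- j - blk$dx; k <- k - blk$dy
    if (i < 0L || j < 0L || k < 0L) stop("corrupted backpointers")
  }
  blocks <- rev(blocks)

  arow <- unlist(lapply(blocks, `[[`, "a"), use.names = FALSE)
  xrow <- unlist(lapply(blocks, `[[`, "x"), use.names = FALSE)
  yrow <- unlist(lapply(blocks, `[[`, "y"), use.names = FALSE)
  center <- unlist(lapply(blocks, `[[`, "m"), use.names = FALSE)
  if (is.null(arow)) arow <- xrow <- yrow <- center <- character()
  rows <- rbind(arow, xrow, yrow)
  rownames(rows) <- unname(instance$ids[c("A", "X", "Y")])
  roles <- list(A = rownames(rows)[1L], X = rownames(rows)[2L],
                Y = rownames(rows)[3L])

  events <- list()
  at <- 0L
  widths <- vapply(blocks, function(b) max(b$da, b$dx, b$dy), integer(1))
  for (bi in seq_along(blocks)) {
    w <- widths[bi]
    cols <- (at + 1L):(at + w)
    for (e in blocks[[bi]]$evs)
      events[[length(events) + 1L]] <-
        aln_event(e$kind, e$len, e$branch, cols)
    at <- at + w
  }
  aln <- new_labeled_alignment(rows, "star", roles, center, events,
                               signed = instance$signed)
  aln$events <- lapply(seq_along(events), function(ei) {
    resolve_dup_source(aln, events[[ei]], instance)
  })
  attr(aln, "dp_cost") <- final_cost
  aln
}

# choose and record the source occurrence of a duplication event
resolve_dup_source <- function(aln, ev, instance) {
  if (ev$kind != "duplication") return(ev)
  content <- event_content(aln, ev, branch_to(ev$branch))
  occA <- find_occurrences(content, instance$A)
  if (length(occA)) {
    ev$src <- list(genome = "A", start = occA[1L])
    return(ev)
  }
  child <- branch_to(ev$branch) # "M", "X" or "Y"
  if (child %in% c("X", "Y")) {
    own <- if (child == "X") instance$X else instance$Y
    other <- if (child == "X") "Y" else "X"
    othg <- if (child == "X") instance$Y else instance$X
    tgt <- event_target_interval(aln, ev)
    occ_self <- find_occurrences(content, own, exclude = tgt)
    if (length(occ_self)) {
      ev$src <- list(genome = child, start = occ_self[1L])
      return(ev)
    }
    occ_oth <- find_occurrences(content, othg)
    if (length(occ_oth)) {
      ev$src <- list(genome = other, start = occ_oth[1L])
      return(ev)
    }
  }
  if (ev$orphan) {
    ev$src <- list(genome = "external", start = NA_integer_)
    return(ev)
  }
  stop("internal error: no admissible duplication source found")
}
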