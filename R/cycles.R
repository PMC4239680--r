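#' Cycle detection and resolution in labeled alignments
#'
#' A labeling is a valid event history only if it is free of cycles:
#' circular chains of operations in which each operation's target overlaps
#' the next operation's source.  Because events targeting the ancestral
#' row cannot take part in such a chain, only events with both source and
#' target inside the observed children can; and in labelings produced by
#' the DP backtracking these are always duplications.  Cycles are repaired
#' by re-reading one duplication of the chain as a block that was already
#' present in the center (hence a loss in the sibling) and was gained on
#' the branch above the center through the fewest possible duplications
#' sourced in the ancestor.
#'
#' @name cycle_resolution
NULL

# leaf-internal duplications: source and target both inside X/Y
overlap_nodes <- function(aln) {
  leafroles <- switch(aln$mode,
    star = c("X", "Y"), siblings = c("X", "Y"), directed = "X")
  idx <- integer()
  tg <- character(); ts <- integer(); te <- integer()
  sg <- character(); ss <- integer(); se <- integer()
  for (ei in seq_along(aln$events)) {
    ev <- aln$events[[ei]]
    if (ev$kind != "duplication" || is.null(ev$src)) next
    if (!ev$src$genome %in% leafroles) next
    tint <- event_target_interval(aln, ev)
    idx <- c(idx, ei)
    tg <- c(tg, branch_to(ev$branch))
    ts <- c(ts, tint[1L]); te <- c(te, tint[2L])
    sg <- c(sg, ev$src$genome)
    ss <- c(ss, ev$src$start); se <- c(se, ev$src$start + ev$length - 1L)
  }
  data.frame(event = idx, tgt_genome = tg, tgt_start = ts, tgt_end = te,
             src_genome = sg, src_start = ss, src_end = se,
             stringsAsFactors = FALSE)
}

#' @rdname cycle_resolution
#' @param alignment a [labeled_alignment].
#' @return `build_overlap_graph()`: a list with the node table (`nodes`,
#'   one row per leaf-internal duplication) and the directed `igraph`
#'   object whose edge p -> q means the target of p overlaps the source of
#'   q in the same genome.
#' @export
build_overlap_graph <- function(alignment) {
  nodes <- overlap_nodes(alignment)
  n <- nrow(nodes)
  from <- integer(); to <- integer()
  if (n > 1L) {
    for (p in seq_len(n)) for (q in seq_len(n)) {
      if (p == q) next
      if (nodes$tgt_genome[p] != nodes$src_genome[q]) next
      if (max(nodes$tgt_start[p], nodes$src_start[q]) <=
          min(nodes$tgt_end[p], nodes$src_end[q])) {
        from <- c(from, p); to <- c(to, q)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  list(nodes = nodes, graph = g)
}

#' @rdname cycle_resolution
#' @param graph result of [build_overlap_graph()].
#' @return `find_cycles()`: list of integer vectors, each the event indices
#'   of one elementary cycle (empty when the labeling is feasible).
#' @export
find_cycles <- function(graph) {
  g <- graph$graph
  n <- igraph::vcount(g)
  if (n == 0L) return(list())
  comp <- igraph::components(g, mode = "strong")
  cycles <- list()
  for (ci in which(comp$csize >= 2L)) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vs)
    # one elementary cycle through the first vertex of the component
    v <- 1L
    nb <- as.integer(igraph::neighbors(sub, v, mode = "out"))
    path <- NULL
    for (u in nb) {
      sp <- suppressWarnings(
        igraph::shortest_paths(sub, from = u, to = v, mode = "out"))
      vp <- sp$vpath[[1L]]
      if (length(vp)) { path <- c(v, as.integer(vp)[-length(vp)]); break }
    }
    if (is.null(path)) path <- vs # fallback: report the whole component
    else path <- vs[path]
    cycles[[length(cycles) + 1L]] <- graph$nodes$event[path]
  }
  cycles
}

#' Minimum decomposition of a block over the ancestor
#'
#' Cuts `Z` into the fewest parts such that every part occurs (signed,
#' contiguous) in `A`; computed as a shortest-path over cut positions.
#' Ties prefer the leftmost-longest parts.
#'
#' @param Z non-empty character vector of gene tokens.
#' @param A ancestral gene order.
#' @return list of parts, each `list(start, length, occ)` with `occ` the
#'   leftmost occurrence of the part in `A`; `NULL` when some gene of `Z`
#'   does not occur in `A` at all (undecomposable).
#' @export
min_decomposition <- function(Z, A) {
  Z <- as_genes(Z); A <- as_genes(A)
  L <- length(Z)
  stopifnot(L >= 1L)
  f <- c(0L, rep(NA_integer_, L)) # f[t+1]: min parts for Z[1..t]
  back <- rep(NA_integer_, L)
  for (t in seq_len(L)) {
    for (s in 0L:(t - 1L)) { # s ascending: prefer the longest last part
      if (is.na(f[s + 1L])) next
      if (!length(find_occurrences(Z[(s + 1L):t], A))) next
      cand <- f[s + 1L] + 1L
      if (is.na(f[t + 1L]) || cand < f[t + 1L]) {
        f[t + 1L] <- cand
        back[t] <- s
      }
    }
  }
  if (is.na(f[L + 1L])) return(NULL)
  parts <- list()
  t <- L
  while (t > 0L) {
    s <- back[t]
    seg <- Z[(s + 1L):t]
    parts[[length(parts) + 1L]] <-
      list(start = s + 1L, length = t - s,
           occ = find_occurrences(seg, A)[1L])
    t <- s
  }
  rev(parts)
}

#' @rdname cycle_resolution
#' @param instance for `"star"` alignments, the [star_instance] (provides
#'   the ancestor A); for pairwise modes the ancestor gene order or `NULL`.
#' @param max_repairs safety cap on the number of repairs.
#' @param allow_orphan permit per-gene duplications from an unobserved
#'   source when a cycle member decomposes over no observed genome
#'   (directed mode only; mirrors `allow_gain` in [align_directed()]).
#' @return `resolve_cycles()`: a feasible [labeled_alignment]; idempotent
#'   on feasible input.
#' @export
resolve_cycles <- function(alignment, instance = NULL, max_repairs = NULL,
                           allow_orphan = FALSE) {
  aln <- alignment
  ancestor <- if (inherits(instance, "star_instance")) instance$A
              else as_genes(instance)
  if (is.null(max_repairs))
    max_repairs <- 4L * length(aln$events) + 16L
  for (iter in seq_len(max_repairs)) {
    og <- build_overlap_graph(aln)
    cycles <- find_cycles(og)
    if (!length(cycles)) return(aln)
    for (cyc in cycles) {
      kinds <- vapply(aln$events[cyc], `[[`, "", "kind")
      if (!all(kinds == "duplication"))
        stop("internal error: cycle contains a non-duplication event")
    }
    # smallest cycle first (total covered length), for determinism
    tot <- vapply(cycles, function(cyc)
      sum(vapply(aln$events[cyc], `[[`, 1L, "length")), integer(1))
    cyc <- cycles[[order(tot, vapply(cycles, min, 1L))[1L]]]
    aln <- repair_cycle(aln, cyc, ancestor, allow_orphan)
  }
  og <- build_overlap_graph(aln)
  if (length(find_cycles(og)))
    stop("cycle resolution failed to converge (undecomposable blocks?)")
  aln
}

# relabel one member of a cycle per the minimum-decomposition rule
repair_cycle <- function(aln, cyc, ancestor, allow_orphan = FALSE) {
  decos <- lapply(cyc, function(ei) {
    ev <- aln$events[[ei]]
    Z <- event_content(aln, ev, branch_to(ev$branch))
    if (is.null(ancestor) || !length(ancestor)) NULL
    else min_decomposition(Z, ancestor)
  })
  sizes <- vapply(decos, function(d) if (is.null(d)) NA_integer_
                  else length(d), integer(1))
  if (all(is.na(sizes))) {
    if (aln$mode == "star" || aln$mode == "directed")
      return(repair_cycle_fallback(aln, cyc, ancestor, allow_orphan))
    sizes <- rep(1L, length(cyc)) # siblings mode needs no decomposition
  }
  # pick the member with the fewest parts; ties: branch into X before Y,
  # then leftmost columns
  branches <- vapply(cyc, function(ei) aln$events[[ei]]$branch, "")
  firstcol <- vapply(cyc, function(ei) aln$events[[ei]]$cols[1L], 1L)
  ord <- order(sizes, match(branch_to(branches), c("X", "Y")), firstcol,
               na.last = TRUE)
  pick <- ord[1L]
  ei <- cyc[pick]
  ev <- aln$events[[ei]]
  cols <- ev$cols
  child <- branch_to(ev$branch)
  content <- event_content(aln, ev, child)

  keep <- aln$events[-ei]
  if (aln$mode == "directed") {
    # reinterpret the block as several duplications sourced in A
    deco <- decos[[pick]]
    if (is.null(deco))
      return(repair_cycle_fallback(aln, cyc, ancestor, allow_orphan))
    for (p in deco) {
      pcols <- cols[p$start:(p$start + p$length - 1L)]
      keep[[length(keep) + 1L]] <-
        aln_event("duplication", p$length, ev$branch, pcols,
                  src = list(genome = "A", start = p$occ))
    }
  } else {
    # the block was in the center: loss in the sibling ...
    sib <- if (child == "X") "Y" else "X"
    lossbranch <- paste0(substr(ev$branch, 1L, 2L), sib)
    keep[[length(keep) + 1L]] <- aln_event("loss", ev$length, lossbranch, cols)
    if (aln$mode == "star") {
      # ... gained above the center by the decomposition's duplications
      deco <- decos[[pick]]
      if (is.null(deco))
        return(repair_cycle_fallback(aln, cyc, ancestor, allow_orphan))
      for (p in deco) {
        pcols <- cols[p$start:(p$start + p$length - 1L)]
        keep[[length(keep) + 1L]] <-
          aln_event("duplication", p$length, "A>M", pcols,
                    src = list(genome = "A", start = p$occ))
      }
    }
    aln$center[cols] <- content
  }
  aln$events <- keep
  aln
}

# last-resort repair when no cycle member decomposes over the ancestor:
# per-gene duplications sourced wherever each gene occurs (ancestor first,
# then the other child, then a disjoint occurrence in the same child)
repair_cycle_fallback <- function(aln, cyc, ancestor, allow_orphan = FALSE) {
  ei <- cyc[1L]
  ev <- aln$events[[ei]]
  child <- branch_to(ev$branch)
  cols <- ev$cols
  content <- event_content(aln, ev, child)
  keep <- aln$events[-ei]
  if (aln$mode == "star") {
    sib <- if (child == "X") "Y" else "X"
    keep[[length(keep) + 1L]] <-
      aln_event("loss", ev$length, paste0("M>", sib), cols)
    aln$center[cols] <- content
    branch <- "A>M"
  } else branch <- ev$branch
  childrow <- role_row(aln, child)
  childpos <- cumsum(childrow != "-")
  for (t in seq_along(content)) {
    src <- NULL
    occ <- find_occurrences(content[t], ancestor)
    if (length(occ)) src <- list(genome = "A", start = occ[1L])
    if (is.null(src) && aln$mode == "star") {
      sibrole <- if (child == "X") "Y" else "X"
      occ2 <- find_occurrences(content[t], role_genome(aln, sibrole))
      if (length(occ2)) src <- list(genome = sibrole, start = occ2[1L])
    }
    if (is.null(src)) {
      gpos <- childpos[cols[t]]
      occ3 <- find_occurrences(content[t], role_genome(aln, child),
                               exclude = c(gpos, gpos))
      if (length(occ3)) src <- list(genome = child, start = occ3[1L])
    }
    orphan <- is.null(src)
    if (orphan && !allow_orphan)
      stop("cycle resolution failed: gene '", content[t],
           "' has no admissible duplication source")
    if (orphan) src <- list(genome = "external", start = NA_integer_)
    keep[[length(keep) + 1L]] <-
      aln_event("duplication", 1L, branch, cols[t], src = src,
                orphan = orphan)
  }
  aln$events <- keep
  aln
}
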