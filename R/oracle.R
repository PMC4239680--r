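#' Exact small-instance oracle
#'
#' Exhaustive exact solvers for tiny pairwise and 3-star instances, used
#' to benchmark the heuristic.  The oracle searches over event
#' *histories*: sequences of duplications, losses (single-gene or
#' any-length depending on the model) and optionally reversals, each
#' applied to the intermediate genome, at unit cost per event.  The search
#' is an iterative-deepening branch-and-bound over integer-encoded
#' genomes, with admissible content-based lower bounds (family counts,
#' new adjacency types, length doubling) and memoisation, so the returned
#' count is the true minimum number of events over all histories — a
#' lower bound on (and in practice almost always equal to) the cost of
#' the best *visible* history that a labeled alignment encodes.  Because
#' the heuristic always returns a valid visible history,
#' `solve_star()$cost >= exact_star_cost()` holds on every instance, and
#' equality certifies that the heuristic found an optimal solution.
#'
#' @param max_events largest total event count the search will prove.
#' @param max_len largest genome length accepted.
#' @return `oracle_budget()`: a budget object; solvers refuse instances
#'   that exceed it rather than silently degrading.
#' @name exact_oracle
NULL

#' @rdname exact_oracle
#' @export
oracle_budget <- function(max_events = 6L, max_len = 40L)
  structure(list(max_events = as.integer(max_events),
                 max_len = as.integer(max_len)),
            class = "oracle_budget")

# ---- integer-encoded search internals -----------------------------------
# genomes are signed integer vectors (+f / -f, f in 1..nfam)

ora_key <- function(g) paste(c(0L, g), collapse = ",")

ora_state <- function(genomes, model) {
  enc <- encode_genomes(genomes)
  st <- new.env(parent = emptyenv())
  st$nfam <- length(enc$families)
  st$enc <- enc$encoded
  st$model <- model
  st$single_loss <- model == "dup_singleloss"
  st$use_adj <- model != "dup_loss_reversal"
  st$succ <- new.env(hash = TRUE, parent = emptyenv())
  st$fail <- new.env(hash = TRUE, parent = emptyenv())
  st$tested <- new.env(hash = TRUE, parent = emptyenv())
  st
}

ora_counts <- function(g, nfam) tabulate(abs(g), nbins = nfam)

ora_adj <- function(g, nfam) {
  n <- length(g)
  if (n < 2L) return(integer())
  base <- 2L * nfam + 1L
  (g[-n] + nfam) * base + (g[-1L] + nfam)
}

# a search node: the genome plus cached count/adjacency summaries
ora_meta <- function(g, st)
  list(g = g, counts = ora_counts(g, st$nfam), adj = ora_adj(g, st$nfam))

ora_target <- function(g, st)
  list(genes = g, key = ora_key(g), counts = ora_counts(g, st$nfam),
       len = length(g), adj = unique(ora_adj(g, st$nfam)))

# admissible lower bound on the number of events turning S into the target:
#  - every family of the target must already exist (no insertions);
#  - surplus gene copies need losses (one per copy under single-gene
#    losses, at least one otherwise); a shortfall needs >= 1 duplication;
#  - every duplication or loss introduces at most 2 adjacency types
#    absent from S (reversals flip whole block interiors, so the bound is
#    skipped when they are in the model);
#  - a duplication at most doubles the length and losses only shrink it.
ora_lb <- function(meta, tgt, st) {
  d <- meta$counts - tgt$counts
  if (any(d < 0L & meta$counts == 0L)) return(Inf)
  excess <- sum(d[d > 0L])
  deficit <- any(d < 0L)
  base <- if (st$single_loss) excess + deficit
          else (excess > 0L) + deficit
  if (st$use_adj) {
    new_adj <- sum(!tgt$adj %in% meta$adj)
    if (new_adj > 2L * base) base <- (new_adj + 1L) %/% 2L
  }
  n <- length(meta$g)
  if (tgt$len > n && n) {
    dbl <- ceiling(log2(tgt$len / n))
    if (dbl > base) base <- dbl
  }
  if (base == 0L && !identical(meta$g, tgt$genes)) base <- 1L
  base
}

ora_find <- function(pattern, text, exclude = NULL) {
  m <- length(pattern); n <- length(text)
  if (m == 0L || n < m) return(integer())
  starts <- which(text == pattern[1L])
  starts <- starts[starts + m - 1L <= n]
  if (m > 1L && length(starts))
    starts <- starts[vapply(starts, function(p)
      all(text[p:(p + m - 1L)] == pattern), logical(1))]
  if (!is.null(exclude) && length(starts))
    starts <- starts[starts + m - 1L < exclude[1L] | starts > exclude[2L]]
  starts
}

# is T exactly one event away from S?
one_event_to <- function(S, T_, model) {
  nS <- length(S); nT <- length(T_)
  if (identical(S, T_)) return(FALSE)
  p <- 0L
  while (p < min(nS, nT) && S[p + 1L] == T_[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < min(nS, nT) && S[nS - s] == T_[nT - s]) s <- s + 1L
  if (nT < nS) { # one loss
    ok_len <- if (model == "dup_singleloss") nT == nS - 1L else TRUE
    if (ok_len && p + s >= nT) return(TRUE)
  }
  if (nT > nS) { # one duplication
    d <- nT - nS
    jlo <- max(0L, nS - s); jhi <- min(p, nS)
    if (jlo <= jhi) for (j in jlo:jhi) {
      ins <- T_[(j + 1L):(j + d)]
      occ <- ora_find(ins, S)
      if (any(j <= occ - 1L | j >= occ + d - 1L)) return(TRUE)
    }
  }
  if (nT == nS && model == "dup_loss_reversal") { # one reversal
    mm <- which(S != T_)
    lo <- mm[1L]; hi <- mm[length(mm)]
    for (st_ in seq_len(lo)) for (en in hi:nS) {
      if (identical(T_[st_:en], -rev(S[st_:en]))) return(TRUE)
    }
  }
  FALSE
}

# all genomes one event away from S (deduplicated)
ora_successors <- function(S, st) {
  k0 <- ora_key(S)
  cached <- st$succ[[k0]]
  if (!is.null(cached)) return(cached)
  res <- list(); seen <- new.env(hash = TRUE, parent = emptyenv())
  addg <- function(g) {
    k <- ora_key(g)
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      res[[length(res) + 1L]] <<- ora_meta(g, st)
    }
  }
  n <- length(S)
  for (k in seq_len(n)) { # duplications
    for (i in seq_len(n - k + 1L)) {
      cont <- S[i:(i + k - 1L)]
      bad <- if (k > 1L) i:(i + k - 2L) else integer()
      for (j in setdiff(0:n, bad)) addg(append(S, cont, after = j))
    }
  }
  if (st$single_loss) {
    for (i in seq_len(n)) addg(S[-i])
  } else {
    for (i in seq_len(n)) for (k in seq_len(n - i + 1L))
      addg(S[-(i:(i + k - 1L))])
  }
  if (st$model == "dup_loss_reversal") {
    for (i in seq_len(n)) for (k in seq_len(n - i + 1L)) {
      g <- S
      g[i:(i + k - 1L)] <- -rev(g[i:(i + k - 1L)])
      addg(g)
    }
  }
  st$succ[[k0]] <- res
  res
}

# can the node reach the target within b events?
ora_reach <- function(meta, b, tgt, st) {
  if (identical(meta$g, tgt$genes)) return(TRUE)
  if (b <= 0L) return(FALSE)
  lb <- ora_lb(meta, tgt, st)
  if (lb > b) return(FALSE)
  if (one_event_to(meta$g, tgt$genes, st$model)) return(TRUE)
  if (b == 1L) return(FALSE)
  key <- paste0(ora_key(meta$g), "|", b, ">", tgt$key)
  if (!is.null(st$fail[[key]])) return(FALSE)
  succ <- ora_successors(meta$g, st)
  lbs <- vapply(succ, function(s2) ora_lb(s2, tgt, st), numeric(1))
  for (gi in order(lbs)) {
    if (lbs[gi] > b - 1L) break
    if (ora_reach(succ[[gi]], b - 1L, tgt, st)) return(TRUE)
  }
  st$fail[[key]] <- TRUE
  FALSE
}

check_budget <- function(budget, ...) {
  lens <- lengths(list(...))
  if (any(lens > budget$max_len))
    stop("oracle budget exceeded: genome longer than ", budget$max_len)
}

#' @rdname exact_oracle
#' @param X,Y,A gene orders.
#' @param mode `"siblings"` (infer the best parent) or `"directed"`
#'   (`X` is the ancestor of `Y`).
#' @param model `"dup_loss"` (unit cost per duplication or any-length
#'   loss; the default), `"dup_singleloss"` (losses remove one gene) or
#'   `"dup_loss_reversal"`.
#' @param budget an `oracle_budget`.
#' @param upper known achievable cost (e.g. the heuristic's); the search
#'   stops there.
#' @return optimal event count (`Inf` if the target is unreachable); the
#'   attribute `exhausted` is `TRUE` when the budget was hit first.
#' @export
exact_pair_cost <- function(X, Y, mode = c("siblings", "directed"),
                            model = c("dup_loss", "dup_singleloss",
                                      "dup_loss_reversal"),
                            budget = oracle_budget(), upper = NULL) {
  mode <- match.arg(mode); model <- match.arg(model)
  X <- as_genes(X); Y <- as_genes(Y)
  check_budget(budget, X, Y)
  st <- ora_state(list(X, Y), model)
  Xe <- st$enc[[1L]]; Ye <- st$enc[[2L]]
  cmax <- budget$max_events
  if (!is.null(upper)) cmax <- min(cmax, upper)
  if (mode == "directed") {
    tgt <- ora_target(Ye, st)
    mX <- ora_meta(Xe, st)
    lb0 <- ora_lb(mX, tgt, st)
    if (!is.finite(lb0)) return(structure(Inf, exhausted = FALSE))
    if (lb0 <= cmax) for (ctot in lb0:cmax) {
      if (!is.null(upper) && ctot >= upper) return(upper)
      if (ora_reach(mX, ctot, tgt, st)) return(ctot)
    }
    if (!is.null(upper) && upper <= budget$max_events) return(upper)
    return(structure(Inf, exhausted = TRUE))
  }
  # siblings: minimise d(P -> X) + d(P -> Y) over parents P
  ty <- ora_target(Ye, st)
  if (!st$single_loss) { # candidate blocks for inverse any-length losses
    blocks <- list()
    for (g in list(Xe, Ye)) {
      n <- length(g)
      for (i in seq_len(n)) {
        kmax <- n - i + 1L
        if (kmax >= 2L) for (k in 2:kmax)
          blocks[[length(blocks) + 1L]] <- g[i:(i + k - 1L)]
      }
    }
    st$ins_blocks <- unique(blocks)
  }
  for (ctot in 0:cmax) {
    if (!is.null(upper) && ctot >= upper) return(upper)
    for (cX in 0:ctot) {
      cY <- ctot - cX
      if (sib_search(ora_meta(Xe, st), cX, cY, ty, st)) return(ctot)
    }
  }
  if (!is.null(upper) && upper <= budget$max_events) return(upper)
  structure(Inf, exhausted = TRUE)
}

# reverse search: ancestors P of X within `depth` events, tested against Y
sib_search <- function(cur, depth, cY, ty, st) {
  key <- paste0(ora_key(cur$g), "|", depth, "|", cY)
  if (!is.null(st$tested[[key]])) return(FALSE)
  if (ora_reach(cur, cY, ty, st)) return(TRUE)
  if (depth > 0L) {
    for (p in ora_predecessors(cur$g, st))
      if (sib_search(p, depth - 1L, cY, ty, st)) return(TRUE)
  }
  st$tested[[key]] <- TRUE
  FALSE
}

# genomes P such that one event on P yields S.  Inverse losses insert
# single genes of the observed families (and, for any-length losses,
# short blocks observed in a leaf): a minimal parent carries no other
# content.
ora_predecessors <- function(S, st) {
  k0 <- paste0("pred|", ora_key(S))
  cached <- st$succ[[k0]]
  if (!is.null(cached)) return(cached)
  res <- list(); seen <- new.env(hash = TRUE, parent = emptyenv())
  addg <- function(g) {
    k <- ora_key(g)
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      res[[length(res) + 1L]] <<- ora_meta(g, st)
    }
  }
  n <- length(S)
  # inverse duplication: remove a block that still occurs legally
  for (k in seq_len(n)) for (j in seq_len(n - k + 1L)) {
    seg <- S[j:(j + k - 1L)]
    P <- S[-(j:(j + k - 1L))]
    occ <- ora_find(seg, P)
    slot <- j - 1L
    if (any(slot <= occ - 1L | slot >= occ + k - 1L)) addg(P)
  }
  # inverse loss: insertions
  toks <- seq_len(st$nfam)
  if (st$model == "dup_loss_reversal") toks <- c(toks, -toks)
  for (f in toks) for (j in 0:n) addg(append(S, f, after = j))
  if (!st$single_loss && !is.null(st$ins_blocks)) {
    for (blk in st$ins_blocks) for (j in 0:n) addg(append(S, blk, after = j))
  }
  if (st$model == "dup_loss_reversal") {
    for (i in seq_len(n)) for (k in seq_len(n - i + 1L)) {
      g <- S
      g[i:(i + k - 1L)] <- -rev(g[i:(i + k - 1L)])
      addg(g)
    }
  }
  st$succ[[k0]] <- res
  res
}

#' @rdname exact_oracle
#' @details `exact_star_cost()` searches over candidate centers reachable
#'   from A together with exact directed distances to each child, over
#'   every split of the total budget, and is exact for the history
#'   formulation by exhaustion.
#' @export
exact_star_cost <- function(A, X, Y,
                            model = c("dup_loss", "dup_singleloss",
                                      "dup_loss_reversal"),
                            budget = oracle_budget(), upper = NULL) {
  model <- match.arg(model)
  A <- as_genes(A); X <- as_genes(X); Y <- as_genes(Y)
  check_budget(budget, A, X, Y)
  st <- ora_state(list(A, X, Y), model)
  Ae <- ora_meta(st$enc[[1L]], st)
  tx <- ora_target(st$enc[[2L]], st); ty <- ora_target(st$enc[[3L]], st)
  lbx <- ora_lb(Ae, tx, st); lby <- ora_lb(Ae, ty, st)
  if (!is.finite(lbx) || !is.finite(lby))
    return(structure(Inf, exhausted = FALSE))
  cmax <- budget$max_events
  if (!is.null(upper)) cmax <- min(cmax, upper)
  lb0 <- max(lbx, lby, 0L)
  if (lb0 > cmax) {
    if (!is.null(upper) && upper <= budget$max_events) return(upper)
    return(structure(Inf, exhausted = TRUE))
  }
  mX <- ora_meta(tx$genes, st); mY <- ora_meta(ty$genes, st)
  for (ctot in lb0:cmax) {
    if (!is.null(upper) && ctot >= upper) return(upper)
    parts <- star_partitions(ctot)
    for (r in seq_len(nrow(parts))) {
      cA <- parts[r, 1L]; cX <- parts[r, 2L]; cY <- parts[r, 3L]
      # splits with a zero collapse to directed reachability: the center
      # coincides with A, X or Y, so no center enumeration is needed
      hit <- if (cX == 0L && cY == 0L)
        identical(tx$genes, ty$genes) && ora_reach(Ae, cA, tx, st)
      else if (cX == 0L)
        ora_reach(Ae, cA, tx, st) && ora_reach(mX, cY, ty, st)
      else if (cY == 0L)
        ora_reach(Ae, cA, ty, st) && ora_reach(mY, cX, tx, st)
      else if (cA == 0L)
        ora_reach(Ae, cX, tx, st) && ora_reach(Ae, cY, ty, st)
      else
        star_center_search(Ae, cA, cX, cY, tx, ty, st)
      if (hit) return(ctot)
    }
  }
  if (!is.null(upper) && upper <= budget$max_events) return(upper)
  structure(Inf, exhausted = TRUE)
}

star_partitions <- function(ctot) {
  parts <- expand.grid(cA = 0:ctot, cX = 0:ctot, cY = 0:ctot)
  parts <- parts[rowSums(parts) == ctot, , drop = FALSE]
  spread <- apply(parts, 1L, function(v) max(v) - min(v))
  as.matrix(parts[order(spread, parts$cA), , drop = FALSE])
}

star_center_search <- function(cur, dA, cX, cY, tx, ty, st) {
  if (ora_lb(cur, tx, st) > dA + cX) return(FALSE)
  if (ora_lb(cur, ty, st) > dA + cY) return(FALSE)
  if (dA == 0L) {
    key <- paste0(ora_key(cur$g), "|", cX, "/", cY)
    if (!is.null(st$tested[[key]])) return(FALSE)
    ok <- ora_reach(cur, cX, tx, st) && ora_reach(cur, cY, ty, st)
    if (ok) return(TRUE)
    st$tested[[key]] <- TRUE
    return(FALSE)
  }
  key <- paste0(ora_key(cur$g), "|c", dA, "/", cX, "/", cY)
  if (!is.null(st$tested[[key]])) return(FALSE)
  succ <- ora_successors(cur$g, st)
  sc <- vapply(succ, function(s2)
    ora_lb(s2, tx, st) + ora_lb(s2, ty, st), numeric(1))
  for (gi in order(sc)) {
    if (!is.finite(sc[gi])) break
    if (star_center_search(succ[[gi]], dA - 1L, cX, cY, tx, ty, st))
      return(TRUE)
  }
  st$tested[[key]] <- TRUE
  FALSE
}
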