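#' 3-star instances
#'
#' A 3-star `A|XY` is the star tree with leaves A (the grandparent
#' assignment), X and Y (the two siblings) around the hidden center M whose
#' assignment is sought.  A is ancestral: no event of any labeling of the
#' instance may target A.
#'
#' @param A,X,Y gene orders (character vectors of signed tokens).
#' @param costs a [cost_scheme].
#' @param signed treat genomes as signed (reversals flip orientation).
#' @return object of class `"star_instance"`.
#' @export
star_instance <- function(A, X, Y, costs = unit_costs(), signed = TRUE) {
  structure(list(A = as_genes(A), X = as_genes(X), Y = as_genes(Y),
                 ids = c(A = genome_id(A, "A"), X = genome_id(X, "X"),
                         Y = genome_id(Y, "Y")),
                 costs = costs, signed = isTRUE(signed)),
            class = "star_instance")
}

# map token genomes to signed integer codes over the union of families
encode_genomes <- function(genomes) {
  fams <- unique(gene_family(unlist(genomes, use.names = FALSE)))
  enc <- lapply(genomes, function(g) {
    g <- as_genes(g)
    if (!length(g)) return(integer())
    as.integer(gene_sign(g) * match(gene_family(g), fams))
  })
  list(encoded = enc, families = fams)
}

#' Fill the 3-star dynamic-programming table
#'
#' Computes the cost table `C(i,j,k)` over all prefix triples of A, X, Y
#' together with one optimal backpointer (case id and block length) per
#' cell.  Cells that admit no interpretation are `Inf`.
#'
#' @param instance a [star_instance].
#' @return object of class `"dp_table"`: list with 3-dimensional arrays
#'   `cost`, `case`, `m` (indexed by prefix length + 1) and the instance.
#' @export
compute_dp <- function(instance) {
  stopifnot(inherits(instance, "star_instance"))
  enc <- encode_genomes(list(instance$A, instance$X, instance$Y))
  maxn <- max(lengths(enc$encoded), 1L)
  res <- .star_dp_cpp(enc$encoded[[1L]], enc$encoded[[2L]], enc$encoded[[3L]],
                      cost_vector(instance$costs, "duplication", maxn),
                      cost_vector(instance$costs, "loss", maxn),
                      cost_vector(instance$costs, "reversal", maxn),
                      instance$signed)
  structure(list(cost = res$cost, case = res$case, m = res$m,
                 instance = instance),
            class = "dp_table")
}

#' @rdname compute_dp
#' @param table a `dp_table` (optional for `evaluate_cases`; computed when
#'   missing).
#' @param i,j,k prefix lengths of A, X, Y (0-based counts).
#' @details `evaluate_cases()` is an R-level re-derivation of the candidate
#'   set of one cell, used to audit the compiled table: for each case it
#'   returns the best candidate cost (minimised over the admissible block
#'   lengths) given the already-computed smaller cells.  Inapplicable cases
#'   carry cost `Inf`.
#' @return `evaluate_cases()`: data frame with columns `case`, `m`, `cost`.
#' @export
evaluate_cases <- function(instance, i, j, k, table = NULL) {
  stopifnot(inherits(instance, "star_instance"))
  if (is.null(table)) table <- compute_dp(instance)
  A <- instance$A; X <- instance$X; Y <- instance$Y
  sgn <- instance$signed
  C <- function(ii, jj, kk) table$cost[ii + 1L, jj + 1L, kk + 1L]
  cs <- instance$costs
  cD <- function(m) op_cost(cs, "duplication", m)
  cL <- function(m) op_cost(cs, "loss", m)
  cR <- function(m) op_cost(cs, "reversal", m)
  seg <- function(g, to, m) g[(to - m + 1L):to]
  revm <- function(P, p, Q, q, m) # Q suffix is the reverse of P suffix
    m <= p && m <= q &&
      identical(seg(Q, q, m), reverse_of(seg(P, p, m), signed = sgn))
  csuf <- function(P, p, Q, q) {
    m <- 0L
    while (m < p && m < q && P[p - m] == Q[q - m]) m <- m + 1L
    m
  }
  out <- data.frame(case = integer(), m = integer(), cost = numeric())
  add <- function(case, m, cost) {
    if (length(m) && is.finite(cost))
      out[nrow(out) + 1L, ] <<- list(case, m, cost)
    else out[nrow(out) + 1L, ] <<- list(case, 0L, Inf)
  }
  best_over <- function(case, ms, costf) {
    if (!length(ms)) { add(case, 0L, Inf); return(invisible()) }
    costs_ <- vapply(ms, costf, numeric(1))
    b <- which.min(costs_)
    add(case, ms[b], costs_[b])
  }

  # 1 match
  add(1L, 1L, if (i > 0 && j > 0 && k > 0 && A[i] == X[j] && X[j] == Y[k])
    C(i - 1L, j - 1L, k - 1L) else Inf)
  # 2 reversal in M
  ms <- Filter(function(m) revm(A, i, X, j, m) && revm(A, i, Y, k, m),
               seq_len(min(i, j, k)))
  best_over(2L, ms, function(m) C(i - m, j - m, k - m) + cR(m))
  # 3 reversal in X
  ms <- Filter(function(m) m <= csuf(A, i, Y, k) && revm(A, i, X, j, m),
               seq_len(min(i, j, k)))
  best_over(3L, ms, function(m) C(i - m, j - m, k - m) + cR(m))
  # 4 reversal in Y
  ms <- Filter(function(m) m <= csuf(A, i, X, j) && revm(A, i, Y, k, m),
               seq_len(min(i, j, k)))
  best_over(4L, ms, function(m) C(i - m, j - m, k - m) + cR(m))
  # 5 duplication in M
  ms <- Filter(function(m) m <= csuf(X, j, Y, k) &&
                 occurs_in(seg(X, j, m), A), seq_len(min(j, k)))
  best_over(5L, ms, function(m) C(i, j - m, k - m) + cD(m))
  # 6 reversal in M + loss in Y
  ms <- Filter(function(m) revm(A, i, X, j, m), seq_len(min(i, j)))
  best_over(6L, ms, function(m) C(i - m, j - m, k) + cR(m) + cL(m))
  # 7 reversal in M + loss in X
  ms <- Filter(function(m) revm(A, i, Y, k, m), seq_len(min(i, k)))
  best_over(7L, ms, function(m) C(i - m, j, k - m) + cR(m) + cL(m))
  # 8 duplication in M (X content) + reversal in Y
  ms <- Filter(function(m) revm(X, j, Y, k, m) &&
                 occurs_in(seg(X, j, m), A), seq_len(min(j, k)))
  best_over(8L, ms, function(m) C(i, j - m, k - m) + cD(m) + cR(m))
  # 9 duplication in M (Y content) + reversal in X
  ms <- Filter(function(m) revm(Y, k, X, j, m) &&
                 occurs_in(seg(Y, k, m), A), seq_len(min(j, k)))
  best_over(9L, ms, function(m) C(i, j - m, k - m) + cD(m) + cR(m))
  # 10 loss in X
  ms <- if (i > 0 && k > 0 && A[i] == Y[k]) seq_len(csuf(A, i, Y, k))
        else integer()
  best_over(10L, ms, function(m) C(i - m, j, k - m) + cL(m))
  # 11 loss in Y
  ms <- if (i > 0 && j > 0 && A[i] == X[j]) seq_len(csuf(A, i, X, j))
        else integer()
  best_over(11L, ms, function(m) C(i - m, j - m, k) + cL(m))
  # 12 loss in M
  best_over(12L, seq_len(i), function(m) C(i - m, j, k) + cL(m))
  # 13 duplication in X (source in A, Y, or disjointly in X)
  occ13 <- function(g, to, other1, other2, m) {
    s <- seg(g, to, m)
    length(find_occurrences(s, other1)) > 0L ||
      length(find_occurrences(s, g, exclude = c(to - m + 1L, to))) > 0L ||
      length(find_occurrences(s, other2)) > 0L
  }
  ms <- Filter(function(m) occ13(X, j, A, Y, m), seq_len(j))
  best_over(13L, ms, function(m) C(i, j - m, k) + cD(m))
  # 14 duplication in Y
  ms <- Filter(function(m) occ13(Y, k, A, X, m), seq_len(k))
  best_over(14L, ms, function(m) C(i, j, k - m) + cD(m))
  out
}
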