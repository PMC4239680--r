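#' Operation cost schemes
#'
#' A cost scheme assigns a non-negative cost to each event as a function of
#' its length (number of genes).  Costs may be constants or functions of
#' the length; `Inf` disables an operation type altogether.
#'
#' `unit_costs()` charges 1 per event regardless of length — the default
#' scheme used throughout the package.  `dup_singleloss_costs()` encodes
#' the duplication / single-gene-loss model: a duplication of any length is
#' one event, the loss of a k-gene block counts as k single-gene losses,
#' and reversals are disabled.
#'
#' @param duplication,loss,reversal a non-negative number or a
#'   `function(k)` returning the cost of an event of length `k`.
#' @return an object of class `"cost_scheme"`.
#' @examples
#' sc <- dup_singleloss_costs()
#' op_cost(sc, "loss", 3) # 3
#' @export
cost_scheme <- function(duplication = 1, loss = 1, reversal = 1) {
  as_fun <- function(v) {
    if (is.function(v)) return(v)
    stopifnot(is.numeric(v), length(v) == 1L, v >= 0)
    force(v)
    function(k) rep_len(v, length(k))
  }
  structure(list(duplication = as_fun(duplication),
                 loss = as_fun(loss),
                 reversal = as_fun(reversal)),
            class = "cost_scheme")
}

#' @rdname cost_scheme
#' @export
unit_costs <- function() cost_scheme(1, 1, 1)

#' @rdname cost_scheme
#' @export
dup_singleloss_costs <- function()
  cost_scheme(duplication = 1, loss = function(k) k, reversal = Inf)

#' @rdname cost_scheme
#' @param costs a `cost_scheme`.
#' @param kind one of `"duplication"`, `"loss"`, `"reversal"`.
#' @param length event length in genes.
#' @export
op_cost <- function(costs, kind, length) {
  stopifnot(inherits(costs, "cost_scheme"))
  kind <- match.arg(kind, c("duplication", "loss", "reversal"))
  v <- as.numeric(costs[[kind]](length))
  if (any(v < 0)) stop("negative event cost")
  v
}

# cost of events of length 1..maxk as a plain vector (for the C++ core)
cost_vector <- function(costs, kind, maxk) {
  if (maxk < 1L) maxk <- 1L
  vapply(seq_len(maxk), function(k) op_cost(costs, kind, k), numeric(1))
}
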