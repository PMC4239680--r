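#' Evolutionary operations and branch histories
#'
#' Histories are ordered sequences of events acting on a genome, each event
#' expressed in the coordinates of the genome it is applied to:
#'
#' * a **duplication** inserts a copy of a block before position `tgt_pos`
#'   (so the copy occupies `tgt_pos .. tgt_pos+length-1` afterwards).  The
#'   copied content is taken from `src_start` in the current genome, or
#'   carried explicitly in `content` when the source lies in another genome
#'   (the cross-genome reading of a duplication that subsumes
#'   transpositions and transfers);
#' * a **loss** removes the block starting at `src_start`;
#' * a **reversal** replaces the block starting at `src_start` by its
#'   reverse (order flipped, signs flipped unless `signed = FALSE`).
#'
#' @param length event length in genes (positive integer).
#' @param tgt_pos insertion position of the copy, in 1..n+1.
#' @param src_start 1-based start of the affected block.
#' @param content explicit copied content (character vector of tokens).
#' @param signed whether reversal flips strand signs.
#' @return an object of class `"evo_op"`.
#' @name evo_op
NULL

new_op <- function(kind, length, src_start = NA_integer_, tgt_pos = NA_integer_,
                   content = NULL, signed = TRUE) {
  stopifnot(length >= 1L)
  structure(list(kind = kind, length = as.integer(length),
                 src_start = as.integer(src_start),
                 tgt_pos = as.integer(tgt_pos),
                 content = content, signed = isTRUE(signed)),
            class = "evo_op")
}

#' @rdname evo_op
#' @export
op_duplication <- function(length, tgt_pos, src_start = NA_integer_,
                           content = NULL) {
  if (is.na(src_start) && is.null(content))
    stop("duplication needs a local source position or explicit content")
  if (!is.null(content) && length(content) != length)
    stop("duplication content length mismatch")
  new_op("duplication", length, src_start, tgt_pos, content)
}

#' @rdname evo_op
#' @export
op_loss <- function(src_start, length)
  new_op("loss", length, src_start)

#' @rdname evo_op
#' @export
op_reversal <- function(src_start, length, signed = TRUE)
  new_op("reversal", length, src_start, signed = signed)

#' @export
print.evo_op <- function(x, ...) {
  cat(sprintf("%s(%d)", x$kind, x$length))
  if (!is.na(x$src_start)) cat(" src@", x$src_start, sep = "")
  if (!is.na(x$tgt_pos)) cat(" tgt@", x$tgt_pos, sep = "")
  cat("\n")
  invisible(x)
}

#' Replay a branch history
#'
#' Applies the events of `history` left to right to `start` and returns the
#' resulting genome.  Replays are strict: out-of-range intervals, a
#' duplication whose stated content disagrees with its source block, or a
#' copy placed inside its own source raise an error.
#'
#' @param start ancestral gene order.
#' @param history list of [evo_op] events (class `"evo_history"` or plain
#'   list).
#' @return the descendant `gene_order`.
#' @examples
#' replay_history(c("a", "b"), list(op_duplication(2, tgt_pos = 3, src_start = 1)))
#' @export
replay_history <- function(start, history) {
  g <- as_genes(start)
  for (op in history) {
    k <- op$length
    if (op$kind == "loss") {
      s <- op$src_start
      if (is.na(s) || s < 1L || s + k - 1L > length(g))
        stop("loss interval out of range")
      g <- g[-(s:(s + k - 1L))]
    } else if (op$kind == "reversal") {
      s <- op$src_start
      if (is.na(s) || s < 1L || s + k - 1L > length(g))
        stop("reversal interval out of range")
      g[s:(s + k - 1L)] <- reverse_of(g[s:(s + k - 1L)], signed = op$signed)
    } else if (op$kind == "duplication") {
      tp <- op$tgt_pos
      if (is.na(tp) || tp < 1L || tp > length(g) + 1L)
        stop("duplication target out of range")
      cont <- op$content
      s <- op$src_start
      if (!is.na(s)) {
        if (s < 1L || s + k - 1L > length(g))
          stop("duplication source out of range")
        local <- g[s:(s + k - 1L)]
        if (!is.null(cont) && !identical(as.character(cont), local))
          stop("duplication content mismatch")
        if (tp > s && tp < s + k)
          stop("duplication target inside its source interval")
        cont <- local
      }
      g <- append(g, cont, after = tp - 1L)
    } else stop("unknown operation kind: ", op$kind)
  }
  gene_order(g, id = genome_id(start))
}

#' @rdname replay_history
#' @param history list of events.
#' @param costs a [cost_scheme].
#' @export
history_cost <- function(history, costs = unit_costs()) {
  if (!length(history)) return(0)
  sum(vapply(history, function(op) op_cost(costs, op$kind, op$length),
             numeric(1)))
}
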