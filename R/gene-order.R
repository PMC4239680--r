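#' Signed gene orders
#'
#' A genome is abstracted as a *gene order*: a finite sequence of signed
#' gene-family symbols.  Several genes may belong to the same family
#' (paralogs); the sign records transcriptional orientation.  Tokens are
#' plain character strings, with a leading `"-"` denoting the reverse
#' strand, e.g. `c("a", "b", "-a")`.
#'
#' @param genes character vector of signed gene tokens (may be empty).
#' @param id optional genome identifier.
#' @return A character vector of class `"gene_order"` with an `id`
#'   attribute.
#' @examples
#' g <- gene_order(c("a", "b", "-c"), id = "g1")
#' reverse_of(g)
#' @export
gene_order <- function(genes = character(), id = NULL) {
  genes <- as.character(genes)
  if (length(genes) &&
      (anyNA(genes) || any(genes == "") || any(genes == "-")))
    stop("invalid gene tokens: each token must be a non-empty symbol, ",
         "optionally prefixed with '-'")
  structure(genes, id = id, class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  id <- attr(x, "id")
  cat("gene order", if (!is.null(id)) paste0("'", id, "'") else "",
      "with", length(x), "genes\n")
  if (length(x)) cat(" ", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

# strip class/attributes; accepts gene_order or plain character
as_genes <- function(x) {
  if (is.null(x)) return(character())
  as.character(x)
}

genome_id <- function(x, default = NULL) {
  id <- attr(x, "id")
  if (is.null(id)) default else id
}

#' @rdname gene_order
#' @param x object to query.
#' @export
gene_family <- function(x) sub("^-", "", as_genes(x))

#' @rdname gene_order
#' @export
gene_sign <- function(x) ifelse(startsWith(as_genes(x), "-"), -1L, 1L)

negate_genes <- function(g) {
  if (!length(g)) return(character())
  ifelse(startsWith(g, "-"), substring(g, 2L), paste0("-", g))
}

#' Reverse of a gene-order segment
#'
#' The reverse of a segment is the segment read right to left with every
#' sign flipped: the image of the segment under a reversal (inversion)
#' event.  With `signed = FALSE` only the reading order is reversed, which
#' models unsigned gene orders.
#'
#' @param segment character vector of gene tokens.
#' @param signed flip strand signs (default) or only reverse the order.
#' @return the reversed segment (plain character vector).
#' @examples
#' reverse_of(c("a", "b", "c")) # "-c" "-b" "-a"
#' @export
reverse_of <- function(segment, signed = TRUE) {
  segment <- as_genes(segment)
  if (!length(segment)) return(segment)
  if (signed) rev(negate_genes(segment)) else rev(segment)
}

#' Signed-exact substring search
#'
#' Tests whether `pattern` appears as a contiguous block of `text`,
#' comparing family and sign.  With mode `"forward_or_reverse"` the reverse
#' of `text` is searched as well (inverted duplications; off by default
#' because the core model does not include them).
#'
#' @param pattern non-empty character vector of gene tokens.
#' @param text gene order to search in.
#' @param mode `"forward"` (default) or `"forward_or_reverse"`.
#' @return logical scalar.
#' @export
occurs_in <- function(pattern, text, mode = c("forward", "forward_or_reverse")) {
  mode <- match.arg(mode)
  pattern <- as_genes(pattern)
  if (!length(pattern)) stop("empty pattern")
  text <- as_genes(text)
  if (length(find_occurrences(pattern, text))) return(TRUE)
  if (mode == "forward_or_reverse" &&
      length(find_occurrences(pattern, reverse_of(text))))
    return(TRUE)
  FALSE
}

# All start positions (1-based) of pattern in text; occurrences whose
# interval intersects `exclude` = c(start, end) are dropped.
find_occurrences <- function(pattern, text, exclude = NULL) {
  pattern <- as_genes(pattern)
  text <- as_genes(text)
  m <- length(pattern)
  n <- length(text)
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
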