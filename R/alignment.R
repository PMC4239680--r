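#' Labeled gene-order alignments
#'
#' A labeled alignment is a gap-padded alignment of two or three genomes
#' together with a set of events (the *labeling*) that explains every
#' non-match column pair: a match is covered by no event, a mismatch by
#' exactly one reversal, and a gap pair by exactly one duplication or loss.
#' When one row is ancestral, every event has its source on the ancestral
#' side and its target on the descendant side.
#'
#' Three modes are supported, differing in the implied topology connecting
#' the rows:
#' * `"star"` — rows A (grandparent), X, Y (siblings) with a hidden center
#'   M; events live on the branches `A>M`, `M>X`, `M>Y` and the inferred
#'   center is kept column-aligned in `$center`;
#' * `"siblings"` — rows X, Y with hidden parent P (branches `P>X`, `P>Y`);
#' * `"directed"` — rows A (ancestor) and X (branch `A>X`).
#'
#' @name labeled_alignment
NULL

new_labeled_alignment <- function(rows, mode, roles, center = NULL,
                                  events = list(), signed = TRUE) {
  stopifnot(is.matrix(rows), mode %in% c("star", "siblings", "directed"))
  structure(list(rows = rows, mode = mode, roles = roles, center = center,
                 events = events, signed = signed),
            class = "labeled_alignment")
}

# An event of a labeling.  `branch` is one of "A>M","M>X","M>Y","P>X",
# "P>Y","A>X"; `cols` are the alignment columns of the explained block
# (the copy for a duplication, the lost block for a loss, the reversed
# block for a reversal); `src` locates a duplication source as
# list(genome = role, start = genome position), or genome = "external"
# for an orphan gain.
aln_event <- function(kind, length, branch, cols, src = NULL,
                      orphan = FALSE) {
  list(kind = kind, length = as.integer(length), branch = branch,
       cols = as.integer(cols), src = src, orphan = isTRUE(orphan))
}

branch_from <- function(branch) sub(">.*$", "", branch)
branch_to <- function(branch) sub("^.*>", "", branch)

# The aligned row (with gaps) carried by a role.  "M" and "P" refer to the
# hidden center/parent row.
role_row <- function(aln, role) {
  if (role %in% c("M", "P")) {
    if (is.null(aln$center)) stop("alignment has no center row")
    return(aln$center)
  }
  rn <- aln$roles[[role]]
  if (is.null(rn)) stop("unknown role: ", role)
  unname(aln$rows[rn, ])
}

# genome position of each column for a role (NA at gaps)
role_positions <- function(aln, role) {
  v <- role_row(aln, role)
  p <- cumsum(v != "-")
  p[v == "-"] <- NA_integer_
  p
}

role_genome <- function(aln, role) {
  v <- role_row(aln, role)
  v[v != "-"]
}

# target interval of an event in the coordinates of the branch child
event_target_interval <- function(aln, ev) {
  if (ev$kind == "loss") return(NULL)
  role <- branch_to(ev$branch)
  pos <- role_positions(aln, role)[ev$cols]
  if (anyNA(pos)) stop("event target crosses a gap in its own row")
  c(pos[1L], pos[length(pos)])
}

# content shown at the event columns in a role's row
event_content <- function(aln, ev, role = branch_to(ev$branch)) {
  v <- role_row(aln, role)[ev$cols]
  if (any(v == "-")) stop("event content crosses a gap")
  v
}

#' Cost of a labeled alignment
#'
#' The sum, over the labeling events, of the scheme's cost for the event
#' kind and length.
#'
#' @param alignment a `labeled_alignment` (or a bare list of events).
#' @param costs a [cost_scheme].
#' @return non-negative number.
#' @export
labeling_cost <- function(alignment, costs = unit_costs()) {
  events <- if (inherits(alignment, "labeled_alignment")) {
    lambda <- ncol(alignment$rows)
    for (ev in alignment$events)
      if (any(ev$cols < 1L | ev$cols > lambda))
        stop("event references out-of-range columns")
    alignment$events
  } else alignment
  if (!length(events)) return(0)
  sum(vapply(events, function(ev) op_cost(costs, ev$kind, ev$length),
             numeric(1)))
}

# role pairs checked by validate_alignment, with the events admissible on
# the connecting path and, per branch, which member sits on the child side
validation_pairs <- function(mode) {
  switch(mode,
    star = list(
      list(r = c("A", "X"), branches = c("A>M", "M>X"),
           child = c("A>M" = "X", "M>X" = "X")),
      list(r = c("A", "Y"), branches = c("A>M", "M>Y"),
           child = c("A>M" = "Y", "M>Y" = "Y")),
      list(r = c("X", "Y"), branches = c("M>X", "M>Y"),
           child = c("M>X" = "X", "M>Y" = "Y"))),
    siblings = list(
      list(r = c("X", "Y"), branches = c("P>X", "P>Y"),
           child = c("P>X" = "X", "P>Y" = "Y"))),
    directed = list(
      list(r = c("A", "X"), branches = "A>X", child = c("A>X" = "X"))))
}

#' Validate a labeled alignment
#'
#' Checks the labeling clauses column by column for every pair of rows
#' (restricted to events on the path connecting the pair): matches covered
#' by no event, mismatches by exactly one reversal, gap pairs by exactly
#' one duplication or loss pointing in the right direction, no all-gap
#' column, and no event targeting the ancestral row.  Validation reports
#' violations rather than throwing.
#'
#' @param alignment a `labeled_alignment`.
#' @return character vector of violation messages; empty when valid.
#' @export
validate_alignment <- function(alignment) {
  stopifnot(inherits(alignment, "labeled_alignment"))
  rows <- alignment$rows
  lambda <- ncol(rows)
  bad <- character()
  if (lambda && any(colSums(rows != "-") == 0L))
    bad <- c(bad, paste("all-gap column at",
                        paste(which(colSums(rows != "-") == 0L),
                              collapse = ",")))
  allowed <- unique(unlist(lapply(validation_pairs(alignment$mode),
                                  `[[`, "branches")))
  for (ev in alignment$events) {
    if (!ev$branch %in% allowed)
      bad <- c(bad, paste("event on invalid branch", ev$branch,
                          "(targets the ancestral row?)"))
    if (any(ev$cols < 1L | ev$cols > lambda))
      bad <- c(bad, "event references out-of-range columns")
  }

  for (pr in validation_pairs(alignment$mode)) {
    v1 <- role_row(alignment, pr$r[1L])
    v2 <- role_row(alignment, pr$r[2L])
    evs <- Filter(function(e) e$branch %in% pr$branches, alignment$events)
    # per column, the events whose pattern explains this pair
    for (cc in seq_len(lambda)) {
      a <- v1[cc]; b <- v2[cc]
      if (a == "-" && b == "-") next
      kindhere <- character()
      for (e in evs) {
        if (!cc %in% e$cols) next
        childchar <- if (pr$child[[e$branch]] == pr$r[1L]) a else b
        otherchar <- if (pr$child[[e$branch]] == pr$r[1L]) b else a
        applies <- switch(e$kind,
          reversal = a != "-" && b != "-",
          duplication = childchar != "-" && otherchar == "-",
          loss = childchar == "-" && otherchar != "-")
        if (applies) kindhere <- c(kindhere, e$kind)
      }
      lab <- paste0("pair (", pr$r[1L], ",", pr$r[2L], ") col ", cc)
      if (a != "-" && b != "-") {
        if (a == b) {
          if (length(kindhere))
            bad <- c(bad, paste("covered match at", lab))
        } else {
          if (!length(kindhere))
            bad <- c(bad, paste("uncovered mismatch at", lab))
          else if (length(kindhere) > 1L)
            bad <- c(bad, paste("doubly covered mismatch at", lab))
          else if (kindhere != "reversal")
            bad <- c(bad, paste("mismatch covered by", kindhere, "at", lab))
        }
      } else {
        if (!length(kindhere))
          bad <- c(bad, paste("uncovered gap at", lab))
        else if (length(kindhere) > 1L)
          bad <- c(bad, paste("doubly covered gap at", lab))
        else if (kindhere == "reversal")
          bad <- c(bad, paste("gap covered by reversal at", lab))
      }
    }
  }
  bad
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("labeled alignment (", x$mode, "), ", ncol(x$rows), " columns, ",
      length(x$events), " events\n", sep = "")
  rn <- rownames(x$rows)
  for (r in seq_len(nrow(x$rows)))
    cat(sprintf(" %-8s %s\n", rn[r], paste(x$rows[r, ], collapse = " ")))
  if (!is.null(x$center))
    cat(sprintf(" %-8s %s\n", "(center)", paste(x$center, collapse = " ")))
  invisible(x)
}
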