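#' Genome, tree and result files
#'
#' Genome files are plain text, one genome per line:
#' `<id><TAB><tok1> <tok2> ...`, a token `-x` meaning family `x` on the
#' reverse strand.  Trees are newick; internal labels are allowed and
#' branch lengths, if present, are ignored (the model is event-count
#' based).  Result tables are TSV to avoid quoting gene tokens.
#'
#' @param path file path.
#' @return `parse_genomes()`: named list of [gene_order]s.
#' @name io_interface
NULL

#' @rdname io_interface
#' @export
parse_genomes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty genome file: ", path)
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    id <- parts[1L]
    if (!nzchar(id)) stop("missing genome id in line: ", ln)
    if (!is.null(out[[id]])) stop("duplicate genome id: ", id)
    toks <- if (length(parts) > 1L)
      strsplit(trimws(parts[2L]), "[ ]+")[[1L]] else character()
    toks <- toks[nzchar(toks)]
    out[[id]] <- gene_order(toks, id = id)
  }
  out
}

#' @rdname io_interface
#' @param genomes named list of gene orders.
#' @export
write_genomes <- function(genomes, path) {
  ids <- names(genomes)
  if (is.null(ids)) ids <- vapply(genomes, genome_id, "", default = "")
  lines <- vapply(seq_along(genomes), function(i)
    paste0(ids[i], "\t", paste(as_genes(genomes[[i]]), collapse = " ")),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io_interface
#' @return `parse_tree()`: a rooted binary `phylo` object.
#' @export
parse_tree <- function(path) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse newick tree: ", path)
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy))
    stop("non-binary tree: multifurcations are not supported")
  phy
}

# events of an alignment as a data frame (for the event-log TSV)
events_table <- function(alignment, branch_prefix = "") {
  evs <- alignment$events
  if (!length(evs))
    return(data.frame(branch = character(), kind = character(),
                      length = integer(), src_genome = character(),
                      src_start = integer(), cols = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    branch = paste0(branch_prefix, vapply(evs, `[[`, "", "branch")),
    kind = vapply(evs, `[[`, "", "kind"),
    length = vapply(evs, `[[`, 1L, "length"),
    src_genome = vapply(evs, function(e)
      if (is.null(e$src)) NA_character_ else e$src$genome, ""),
    src_start = vapply(evs, function(e)
      if (is.null(e$src)) NA_integer_ else as.integer(e$src$start), 1L),
    cols = vapply(evs, function(e)
      paste0(e$cols[1L], "-", e$cols[length(e$cols)]), ""),
    stringsAsFactors = FALSE)
}

#' Write the results of a steinerization run
#'
#' Writes the internal-node assignments (TSV `id` / gene tokens), the
#' per-round cost table, and the tree in newick with internal labels; all
#' files round-trip through [parse_genomes()] / [parse_tree()] /
#' `read.delim`.
#'
#' @param tree an `assigned_tree` (from [run_steinerization()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_results <- function(tree, dir) {
  stopifnot(inherits(tree, "assigned_tree"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- node_labels(tree$phy)
  paths <- c(assignments = file.path(dir, "assignments.tsv"),
             rounds = file.path(dir, "rounds.tsv"),
             tree = file.path(dir, "tree.nwk"))
  asg <- stats::setNames(lapply(seq_along(tree$assignments), function(i)
    gene_order(tree$assignments[[i]], id = labels[i])), labels)
  write_genomes(asg, paths[["assignments"]])
  rounds <- tree$rounds
  if (is.null(rounds))
    rounds <- data.frame(round = 0L, cost = tree_cost(tree),
                         n_improved = NA_integer_)
  utils::write.table(rounds, paths[["rounds"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  phy <- tree$phy
  phy$node.label <- labels[length(phy$tip.label) + seq_len(phy$Nnode)]
  ape::write.tree(phy, paths[["tree"]])
  invisible(paths)
}
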