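# split a compact string into single-character gene tokens
sp <- function(s) if (nzchar(s)) strsplit(s, "", fixed = TRUE)[[1]] else character()

collapse <- function(g) paste(as.character(g), collapse = "")

# uniform random unsigned genome over families a, b, c, ...
rnd_genome <- function(n, sigma) {
  if (n == 0L) return(character())
  letters[sample.int(sigma, n, replace = TRUE)]
}

# a random tiny 3-star instance drawn from the generative model: the
# children descend from a center that descends from the ancestor.
# (Independent uniform strings routinely admit no event history at all --
# a gene occurring nowhere else cannot be explained by any operation.)
rnd_star <- function(max_len = 6L, sigma = 3L, costs = unit_costs(),
                     l = 2L) {
  A <- rnd_genome(max(1L, sample.int(max_len, 1L)), sigma)
  p <- sim_params(n = length(A), sigma = sigma, l = l)
  M <- apply_moves(A, l, p)$genome
  star_instance(A,
                as.character(apply_moves(M, l, p)$genome),
                as.character(apply_moves(M, l, p)$genome),
                costs = costs)
}

# a random descent pair: X evolves from ancestor A
rnd_pair <- function(max_len = 6L, sigma = 3L, l = 2L) {
  A <- rnd_genome(max(1L, sample.int(max_len, 1L)), sigma)
  p <- sim_params(n = length(A), sigma = sigma, l = l)
  list(A = A, X = as.character(apply_moves(A, l, p)$genome))
}

# does every branch history of a star solution replay to its endpoint?
replays_ok <- function(sol, instance) {
  m <- as.character(sol$center)
  ok <- identical(as.character(replay_history(instance$A,
                                              sol$histories[["A>M"]])), m)
  ok && identical(as.character(replay_history(m, sol$histories[["M>X"]])),
                  instance$X) &&
    identical(as.character(replay_history(m, sol$histories[["M>Y"]])),
              instance$Y)
}

# does the labeling use a duplication sourced in a third genome (the
# transposition surrogate)?  Such an event is priced 1 by the labeling but
# needs duplication + loss (2 events) in a purely sequential history, so
# it is the one way the heuristic can undercut the sequential oracle.
has_cross_dup <- function(aln) {
  for (ev in aln$events) {
    if (ev$kind != "duplication" || is.null(ev$src)) next
    roles <- c(gordalign:::branch_from(ev$branch),
               gordalign:::branch_to(ev$branch))
    if (!ev$src$genome %in% roles) return(TRUE)
  }
  FALSE
}
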