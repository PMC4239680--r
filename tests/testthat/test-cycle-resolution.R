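# a sibling alignment with two duplications whose targets and sources
# overlap mutually (the canonical 2-cycle)
make_two_cycle <- function() {
  ae <- gordalign:::aln_event
  rows <- rbind(X = sp("abab"), Y = rep("-", 4))
  gordalign:::new_labeled_alignment(
    rows, "siblings", list(X = "X", Y = "Y"),
    center = rep("-", 4),
    events = list(
      ae("duplication", 2L, "P>X", 1:2, src = list(genome = "X", start = 3L)),
      ae("duplication", 2L, "P>X", 3:4, src = list(genome = "X", start = 1L))))
}

test_that("the overlap graph contains only leaf-internal duplications", {
  aln <- make_two_cycle()
  og <- build_overlap_graph(aln)
  expect_equal(nrow(og$nodes), 2)
  expect_equal(igraph::ecount(og$graph), 2)
  cyc <- find_cycles(og)
  expect_length(cyc, 1)
  expect_setequal(cyc[[1]], 1:2)
})

test_that("ancestor-sourced events never enter the graph", {
  ae <- gordalign:::aln_event
  rows <- rbind(A = sp("ab--"), X = sp("abab"), Y = sp("ab--"))
  aln <- gordalign:::new_labeled_alignment(
    rows, "star", list(A = "A", X = "X", Y = "Y"),
    center = sp("ab--"),
    events = list(ae("duplication", 2L, "M>X", 3:4,
                     src = list(genome = "A", start = 1L))))
  og <- build_overlap_graph(aln)
  expect_equal(nrow(og$nodes), 0)
  expect_length(find_cycles(og), 0)
})

test_that("a one-way overlap chain is acyclic", {
  ae <- gordalign:::aln_event
  rows <- rbind(X = sp("ababab"), Y = rep("-", 6))
  aln <- gordalign:::new_labeled_alignment(
    rows, "siblings", list(X = "X", Y = "Y"), center = rep("-", 6),
    events = list(
      ae("duplication", 2L, "P>X", 3:4, src = list(genome = "X", start = 1L)),
      ae("duplication", 2L, "P>X", 5:6, src = list(genome = "X", start = 3L))))
  og <- build_overlap_graph(aln)
  expect_equal(nrow(og$nodes), 2)
  expect_length(find_cycles(og), 0)
})

test_that("min_decomposition cuts into the fewest ancestor blocks", {
  d <- min_decomposition(sp("abde"), sp("abcde"))
  expect_length(d, 2)
  expect_equal(vapply(d, `[[`, 1L, "length"), c(2L, 2L))
  expect_length(min_decomposition(sp("cde"), sp("abcde")), 1)
  expect_length(min_decomposition(sp("ace"), sp("abcde")), 3)
  expect_null(min_decomposition(sp("axe"), sp("abcde")))
})

test_that("resolve_cycles repairs the 2-cycle and is idempotent", {
  aln <- make_two_cycle()
  fixed <- resolve_cycles(aln)
  expect_length(find_cycles(build_overlap_graph(fixed)), 0)
  expect_length(validate_alignment(fixed), 0)
  # one duplication became a loss in the sibling: cost goes 2 -> 2 under
  # unit costs (dup swapped for loss), and the parent gained the block
  expect_equal(labeling_cost(fixed, unit_costs()), 2)
  kinds <- sort(vapply(fixed$events, `[[`, "", "kind"))
  expect_equal(kinds, c("duplication", "loss"))
  expect_equal(collapse(infer_parent(fixed)), "ab")
  # idempotent on feasible input
  again <- resolve_cycles(fixed)
  expect_identical(again$events, fixed$events)
})

test_that("every cycle detected on backtracked labelings holds only duplications", {
  set.seed(77)
  for (rep in 1:30) {
    inst <- rnd_star(max_len = 6L, sigma = 2L)
    aln <- backtrack_alignment(compute_dp(inst), inst)
    og <- build_overlap_graph(aln)
    for (cyc in find_cycles(og)) {
      kinds <- vapply(aln$events[cyc], `[[`, "", "kind")
      expect_true(all(kinds == "duplication"))
    }
    # resolution always terminates in a feasible labeling
    fixed <- resolve_cycles(aln, inst)
    expect_length(find_cycles(build_overlap_graph(fixed)), 0)
  }
})

test_that("the worked-example cycle repairs into a loss plus two duplications", {
  inst <- star_instance(sp("abcde"), sp("acdeabdeabde"), sp("acde"))
  aln <- backtrack_alignment(compute_dp(inst), inst)
  expect_gte(length(find_cycles(build_overlap_graph(aln))), 1)
  fixed <- resolve_cycles(aln, inst)
  new_ev <- fixed$events[!(fixed$events %in% aln$events)]
  kinds <- vapply(new_ev, `[[`, "", "kind")
  expect_equal(sum(kinds == "loss"), 1)
  expect_equal(sum(kinds == "duplication"), 2)
  dup_src <- vapply(new_ev[kinds == "duplication"],
                    function(e) e$src$genome, "")
  expect_true(all(dup_src == "A"))
  expect_equal(labeling_cost(fixed, inst$costs),
               labeling_cost(aln, inst$costs) + 2)
})
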