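test_that("reverse_of flips order and sign and is an involution", {
  expect_equal(reverse_of(c("a", "b", "c")), c("-c", "-b", "-a"))
  expect_equal(reverse_of(character()), character())
  expect_equal(reverse_of(c("-a", "b")), c("-b", "a"))
  set.seed(1)
  for (i in 1:20) {
    g <- rnd_genome(sample.int(8, 1), 4)
    sgn <- sample(c("", "-"), length(g), replace = TRUE)
    g <- paste0(sgn, g)
    expect_identical(reverse_of(reverse_of(g)), g)
    expect_length(reverse_of(g), length(g))
  }
  # unsigned mode only reverses the reading order
  expect_equal(reverse_of(c("a", "b"), signed = FALSE), c("b", "a"))
})

test_that("occurs_in is signed-exact contiguous search", {
  expect_true(occurs_in(sp("ab"), sp("cabd")))
  expect_false(occurs_in(sp("ab"), sp("ba")))
  expect_false(occurs_in("a", c("-a", "b"))) # sign must match
  expect_true(occurs_in("a", c("-a", "b"), mode = "forward_or_reverse"))
  expect_error(occurs_in(character(), sp("ab")), "empty")
})

test_that("gene_order validates tokens and carries an id", {
  g <- gene_order(c("a", "-b"), id = "g1")
  expect_s3_class(g, "gene_order")
  expect_equal(gene_family(g), c("a", "b"))
  expect_equal(gene_sign(g), c(1L, -1L))
  expect_error(gene_order(c("a", "-")), "invalid")
  expect_silent(gene_order(character()))
})

test_that("cost schemes evaluate per kind and length", {
  expect_equal(op_cost(unit_costs(), "duplication", 5), 1)
  expect_equal(op_cost(dup_singleloss_costs(), "loss", 3), 3)
  expect_equal(op_cost(dup_singleloss_costs(), "reversal", 2), Inf)
  expect_equal(op_cost(cost_scheme(reversal = function(k) k), "reversal", 3), 3)
  expect_error(cost_scheme(duplication = -1))
})

test_that("replay_history applies events left to right", {
  expect_equal(as.character(replay_history(sp("ab"), list())), sp("ab"))
  expect_equal(
    as.character(replay_history(sp("ab"),
                                list(op_duplication(2, tgt_pos = 3,
                                                    src_start = 1)))),
    sp("abab"))
  expect_equal(
    as.character(replay_history(sp("abcde"), list(op_loss(2, 1)))),
    sp("acde"))
  expect_equal(
    as.character(replay_history(sp("abc"), list(op_reversal(1, 2)))),
    c("-b", "-a", "c"))
  expect_error(replay_history(sp("ab"), list(op_loss(3, 1))), "range")
  expect_error(replay_history(sp("ab"),
                              list(op_duplication(1, tgt_pos = 2,
                                                  src_start = 1,
                                                  content = "b"))),
               "mismatch")
})

test_that("replayed length follows the duplication/loss arithmetic", {
  set.seed(7)
  for (i in 1:15) {
    g0 <- rnd_genome(10, 4)
    mv <- apply_moves(g0, 4, sim_params(n = 10, sigma = 4, l = 4))
    dups <- sum(vapply(mv$history, function(o)
      if (o$kind == "duplication") o$length else 0L, 0L))
    losses <- sum(vapply(mv$history, function(o)
      if (o$kind == "loss") o$length else 0L, 0L))
    expect_equal(length(mv$genome), length(g0) + dups - losses)
    expect_identical(as.character(replay_history(g0, mv$history)),
                     as.character(mv$genome))
  }
})

test_that("labeling cost with unit costs counts the events", {
  expect_equal(labeling_cost(list()), 0)
  ae <- gordalign:::aln_event
  evs <- list(ae("duplication", 2L, "M>X", 1:2,
                 src = list(genome = "A", start = 1L)),
              ae("loss", 1L, "M>Y", 3L))
  expect_equal(labeling_cost(evs, unit_costs()), 2)
  expect_equal(labeling_cost(evs, dup_singleloss_costs()), 2)
  expect_equal(labeling_cost(list(ae("reversal", 3L, "A>M", 1:3)),
                             cost_scheme(reversal = function(k) k)), 3)
})

test_that("validate_alignment reports the labeling clauses", {
  rows <- rbind(A = sp("ab"), X = sp("ab"))
  ok <- gordalign:::new_labeled_alignment(rows, "directed",
                                          list(A = "A", X = "X"))
  expect_length(validate_alignment(ok), 0)
  # uncovered gap
  rows2 <- rbind(A = sp("ab"), X = c("a", "-"))
  bad <- gordalign:::new_labeled_alignment(rows2, "directed",
                                           list(A = "A", X = "X"))
  expect_match(validate_alignment(bad), "uncovered gap", all = FALSE)
  # covered match
  cov <- gordalign:::new_labeled_alignment(
    rows, "directed", list(A = "A", X = "X"),
    events = list(gordalign:::aln_event("reversal", 1L, "A>X", 1L)))
  expect_match(validate_alignment(cov), "covered match", all = FALSE)
  # loss covering the gap makes it valid
  fixed <- gordalign:::new_labeled_alignment(
    rows2, "directed", list(A = "A", X = "X"),
    events = list(gordalign:::aln_event("loss", 1L, "A>X", 2L)))
  expect_length(validate_alignment(fixed), 0)
})
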