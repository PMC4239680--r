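test_that("pairwise oracle solves forced instances", {
  expect_equal(as.numeric(exact_pair_cost(sp("ab"), sp("ab"))), 0)
  expect_equal(as.numeric(exact_pair_cost(sp("abcde"), sp("acde"))), 1)
  expect_equal(as.numeric(exact_pair_cost(sp("abab"), sp("ab"))), 1)
  expect_equal(as.numeric(exact_pair_cost(sp("ab"), sp("abab"),
                                          mode = "directed")), 1)
  # unreachable: the descendant has a family the ancestor never carried
  expect_equal(as.numeric(exact_pair_cost(sp("ab"), sp("azb"),
                                          mode = "directed")), Inf)
})

test_that("sibling oracle is invariant to row order", {
  set.seed(61)
  for (rep in 1:10) {
    x <- rnd_genome(sample.int(5, 1), 2)
    y <- rnd_genome(sample.int(5, 1), 2)
    expect_equal(as.numeric(exact_pair_cost(x, y, budget = oracle_budget(6, 20))),
                 as.numeric(exact_pair_cost(y, x, budget = oracle_budget(6, 20))))
  }
})

test_that("star oracle solves forced instances", {
  expect_equal(as.numeric(exact_star_cost(sp("ab"), sp("ab"), sp("ab"))), 0)
  expect_equal(as.numeric(exact_star_cost(sp("ab"), sp("abab"), sp("abab"))), 1)
  expect_equal(as.numeric(exact_star_cost(sp("abc"), sp("ac"), sp("ac"))), 1)
})

test_that("capping the search at a known achievable cost changes nothing", {
  set.seed(71)
  for (rep in 1:10) {
    inst <- rnd_star(max_len = 5L, sigma = 2L)
    sol <- solve_star(inst)
    free <- exact_star_cost(inst$A, inst$X, inst$Y,
                            budget = oracle_budget(8, 30))
    capped <- exact_star_cost(inst$A, inst$X, inst$Y,
                              budget = oracle_budget(8, 30),
                              upper = sol$cost)
    expect_equal(as.numeric(free), as.numeric(capped))
  }
})

test_that("the budget is enforced, not silently degraded", {
  expect_error(exact_pair_cost(rnd_genome(50, 5), sp("ab"),
                               budget = oracle_budget(4, 40)),
               "budget")
  out <- exact_pair_cost(sp("abcabc"), sp("cba"),
                         budget = oracle_budget(1, 40))
  expect_true(is.infinite(out))
  expect_true(isTRUE(attr(out, "exhausted")))
})

test_that("single-gene-loss and any-length-loss models are priced differently", {
  # deleting a 3-gene block: one event in the unrestricted model,
  # three single-gene losses otherwise
  expect_equal(as.numeric(exact_pair_cost(sp("abcde"), sp("ae"),
                                          mode = "directed")), 1)
  expect_equal(as.numeric(exact_pair_cost(sp("abcde"), sp("ae"),
                                          mode = "directed",
                                          model = "dup_singleloss")), 3)
})

test_that("the reversal model recognises an inverted block", {
  a <- c("a", "b", "c", "d")
  x <- c("a", "-c", "-b", "d")
  expect_equal(as.numeric(exact_pair_cost(a, x, mode = "directed",
                                          model = "dup_loss_reversal")), 1)
})
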