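test_that("sibling alignment handles forced cases", {
  r <- align_siblings(sp("abc"), sp("abc"))
  expect_equal(r$cost, 0)
  expect_equal(collapse(r$inferred_parent), "abc")

  r2 <- align_siblings(sp("abcde"), sp("acde"))
  expect_equal(r2$cost, 1)

  r3 <- align_siblings(sp("abab"), sp("ab"))
  expect_equal(r3$cost, 1)
  expect_equal(as.numeric(exact_pair_cost(sp("abab"), sp("ab"))), 1)

  r0 <- align_siblings(character(), character())
  expect_equal(r0$cost, 0)
  expect_length(as.character(r0$inferred_parent), 0)
})

test_that("sibling cost is symmetric in its inputs", {
  set.seed(21)
  for (rep in 1:20) {
    x <- rnd_genome(sample.int(7, 1), 3)
    y <- rnd_genome(sample.int(7, 1), 3)
    expect_equal(align_siblings(x, y)$cost, align_siblings(y, x)$cost)
  }
})

test_that("sibling branch histories replay onto both children", {
  set.seed(31)
  for (rep in 1:20) {
    x <- rnd_genome(sample.int(7, 1), 3)
    y <- rnd_genome(sample.int(7, 1), 3)
    r <- align_siblings(x, y)
    p <- as.character(r$inferred_parent)
    expect_identical(as.character(replay_history(p, r$histories[["P>X"]])), x)
    expect_identical(as.character(replay_history(p, r$histories[["P>Y"]])), y)
    expect_equal(r$cost, labeling_cost(r$alignment, unit_costs()))
  }
})

test_that("directed alignment respects the ancestor direction", {
  r <- align_directed(sp("abc"), sp("abc"))
  expect_equal(r$cost, 0)
  r2 <- align_directed(sp("abcde"), sp("acde"))
  expect_equal(r2$cost, 1)
  expect_equal(r2$histories[["A>X"]][[1]]$kind, "loss")
  r3 <- align_directed(sp("ab"), sp("abab"))
  expect_equal(r3$cost, 1)
  expect_equal(as.numeric(exact_pair_cost(sp("ab"), sp("abab"),
                                          mode = "directed")), 1)
  # every event's target is on the descendant row
  for (ev in r3$alignment$events) expect_equal(ev$branch, "A>X")
  # infeasible without a gain: a gene the ancestor never had
  expect_error(align_directed(sp("ab"), sp("azb")), "allow_gain")
  expect_equal(align_directed(sp("ab"), sp("azb"), allow_gain = TRUE)$cost, 1)
})

test_that("directed cost is never below the exact oracle and usually equals it", {
  set.seed(41)
  n <- 40; eq <- 0
  for (rep in seq_len(n)) {
    pr <- rnd_pair(max_len = 6L, sigma = 3L)
    a <- pr$A; x <- pr$X
    h <- tryCatch(align_directed(a, x)$cost, error = function(e) Inf)
    ex <- exact_pair_cost(a, x, mode = "directed",
                          budget = oracle_budget(8, 30))
    expect_gte(h + 1e-9, as.numeric(ex))
    if (h == ex || (is.infinite(h) && is.infinite(ex))) eq <- eq + 1
  }
  message(sprintf("align_directed == exact on %d/%d tiny instances", eq, n))
  expect_gte(eq / n, 0.95)
})

test_that("infer_parent keeps lost blocks and drops duplicated ones", {
  # loss interpretation keeps the parent maximal at equal cost
  r <- align_siblings(sp("abcde"), sp("acde"))
  expect_equal(collapse(infer_parent(r)), "abcde")
  # a duplicated block with an in-child source is absent from the parent
  r2 <- align_siblings(sp("abab"), sp("ab"), costs = dup_singleloss_costs())
  expect_equal(collapse(infer_parent(r2)), "ab")
})
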