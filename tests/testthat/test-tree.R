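balanced4 <- function() ape::read.tree(text = "((t1,t2),(t3,t4));")

test_that("initialization assigns every internal node bottom-up", {
  phy <- ape::read.tree(text = "((t1,t2),t3);")
  gen <- list(t1 = sp("ab"), t2 = sp("ab"), t3 = sp("ab"))
  tr <- initialize_assignments(phy, gen)
  expect_true(all(!vapply(tr$assignments, is.null, TRUE)))
  expect_equal(tree_cost(tr), 0)
  expect_equal(collapse(gene_order(tr$assignments[[4]])), "ab")

  gen2 <- list(t1 = sp("abc"), t2 = sp("abc"), t3 = sp("ac"), t4 = sp("ac"))
  tr2 <- initialize_assignments(balanced4(), gen2)
  expect_equal(tree_cost(tr2), 1) # one loss somewhere on the spine
})

test_that("malformed trees and genome sets are rejected", {
  multi <- ape::read.tree(text = "((t1,t2,t3),t4);")
  gen <- list(t1 = sp("a"), t2 = sp("a"), t3 = sp("a"), t4 = sp("a"))
  expect_error(initialize_assignments(multi, gen), "non-binary")
  expect_error(initialize_assignments(balanced4(),
                                      list(t1 = sp("a"), t2 = sp("a"))),
               "one-to-one")
})

test_that("identical leaves give a zero-cost tree in one round", {
  gen <- list(t1 = sp("abc"), t2 = sp("abc"), t3 = sp("abc"),
              t4 = sp("abc"))
  tr <- run_steinerization(balanced4(), gen)
  expect_equal(tr$rounds$cost[1], 0)
  expect_equal(nrow(tr$rounds), 2) # init + the round that finds no gain
  expect_equal(tree_cost(tr), 0)
})

test_that("tree cost is non-increasing across rounds on simulated data", {
  set.seed(1203)
  for (rep in 1:6) {
    si <- simulate_tree(6, sim_params(n = 18, sigma = 9, l = 2))
    tr <- run_steinerization(si$phy, si$genomes,
                             costs = dup_singleloss_costs())
    expect_true(all(diff(tr$rounds$cost) <= 1e-9))
    expect_lte(nrow(tr$rounds), 21)
    expect_equal(tr$rounds$cost[nrow(tr$rounds)], tree_cost(tr))
  }
})

test_that("a reoptimization fixed point reports no improvement", {
  gen <- list(t1 = sp("ab"), t2 = sp("ab"), t3 = sp("ab"), t4 = sp("ab"))
  tr <- initialize_assignments(balanced4(), gen)
  step <- reoptimize_round(tr)
  expect_false(step$improved)
  expect_identical(step$tree$assignments, tr$assignments)
})

test_that("the multiple alignment covers all nodes without empty columns", {
  gen <- list(t1 = sp("abc"), t2 = sp("abc"), t3 = sp("ac"), t4 = sp("ac"))
  tr <- run_steinerization(balanced4(), gen)
  ma <- build_multiple_alignment(tr)
  expect_equal(nrow(ma), 7) # 4 tips + 3 internal nodes
  expect_true(all(colSums(ma != "-") > 0))
  expect_gte(ncol(ma), 3)
  # each row's non-gaps spell the node's assignment
  labels <- rownames(ma)
  for (i in seq_len(4))
    expect_identical(ma[paste0("t", i), ][ma[paste0("t", i), ] != "-"],
                     gen[[paste0("t", i)]])
})

test_that("2-leaf parent-child merge has one gap column", {
  phy <- ape::read.tree(text = "(t1,t2);")
  gen <- list(t1 = sp("abcde"), t2 = sp("acde"))
  tr <- run_steinerization(phy, gen)
  ma <- build_multiple_alignment(tr)
  expect_equal(nrow(ma), 3)
  expect_equal(sum(ma == "-"), 1)
})
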