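test_that("random genomes are uniform over the family alphabet and seeded", {
  set.seed(5); g1 <- random_genome(100, 50)
  set.seed(5); g2 <- random_genome(100, 50)
  expect_identical(as.character(g1), as.character(g2))
  expect_length(g1, 100)
  expect_true(all(gene_family(g1) %in% paste0("g", 1:50)))
  expect_length(random_genome(0, 5), 0)
  expect_error(random_genome(3, 0), "sigma")
})

test_that("moves follow the stated event model", {
  set.seed(8)
  p <- sim_params(n = 30, sigma = 10, l = 200)
  mv <- apply_moves(random_genome(30, 10), 200, p)
  expect_length(mv$history, 200)
  kinds <- vapply(mv$history, `[[`, "", "kind")
  expect_setequal(unique(kinds), c("duplication", "loss"))
  # single-gene losses only in this model
  lens <- vapply(mv$history, `[[`, 1L, "length")
  expect_true(all(lens[kinds == "loss"] == 1L))
  # l = 0 is the identity
  mv0 <- apply_moves(sp("ab"), 0)
  expect_identical(as.character(mv0$genome), sp("ab"))
  expect_length(mv0$history, 0)
})

test_that("duplication lengths follow the geometric law with mean 1/p", {
  set.seed(12)
  p <- sim_params(n = 400, sigma = 100, l = 3000, dup_length_p = 0.5)
  mv <- apply_moves(random_genome(400, 100), 3000, p)
  kinds <- vapply(mv$history, `[[`, "", "kind")
  lens <- vapply(mv$history, `[[`, 1L, "length")[kinds == "duplication"]
  expect_gt(length(lens), 1000)
  expect_equal(mean(lens), 2, tolerance = 0.08) # Monte-Carlo tolerance
  expect_true(all(lens >= 1))
})

test_that("simulated trees carry exactly l true events per branch", {
  set.seed(33)
  si <- simulate_tree(8, sim_params(n = 20, sigma = 10, l = 3))
  expect_length(si$histories, nrow(si$phy$edge))
  expect_true(all(lengths(si$histories) == 3L))
  expect_equal(si$true_total, 3L * nrow(si$phy$edge))
  # replay of every true history reproduces the child genome
  for (r in seq_len(nrow(si$phy$edge))) {
    parent <- si$truth[[si$phy$edge[r, 1]]]
    child <- si$truth[[si$phy$edge[r, 2]]]
    expect_identical(as.character(replay_history(parent, si$histories[[r]])),
                     child)
  }
})

test_that("the same seed regenerates instances bit for bit", {
  set.seed(99); a <- simulate_star(sim_params(n = 20, sigma = 10, l = 2))
  set.seed(99); b <- simulate_star(sim_params(n = 20, sigma = 10, l = 2))
  expect_identical(as.character(a$X), as.character(b$X))
  expect_identical(as.character(a$Y), as.character(b$Y))
  expect_identical(as.character(a$M_true), as.character(b$M_true))
})

test_that("star instances replay their ground truth", {
  set.seed(17)
  inst <- simulate_star(sim_params(n = 15, sigma = 8, l = 2))
  expect_identical(
    as.character(replay_history(inst$A, inst$histories[["A>M"]])),
    as.character(inst$M_true))
  expect_identical(
    as.character(replay_history(inst$M_true, inst$histories[["M>X"]])),
    as.character(inst$X))
})

test_that("evaluation metrics follow their defining formulas", {
  expect_equal(evaluation_metrics(100, 100)$error, 0)
  expect_equal(evaluation_metrics(101, 100)$error, 1 / 101)
  expect_equal(evaluation_metrics(10, 8, n_optimal = 48,
                                  total = 50)$accuracy, 0.96)
  expect_error(evaluation_metrics(0, 3), "zero")
})
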