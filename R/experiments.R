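#' Accuracy experiment: heuristic median vs exact optimum
#'
#' Generates seeded 3-star instances under the duplication /
#' single-gene-loss protocol (ancestor by the root procedure, center and
#' children by `l` moves per branch), runs the 3-star heuristic on each,
#' and compares its event count with the exact minimum from the
#' small-instance oracle.  The per-instance relative excess
#' `(Inf - Opt)/Inf` and the match indicator feed the usual accuracy /
#' error summaries.
#'
#' @param reps number of replicate instances.
#' @param n root genome length; the alphabet is `n/2` families and each
#'   branch receives `max(1, round(n/20))` moves unless overridden.
#' @param sigma,l protocol overrides.
#' @param seed optional RNG seed set once before the replicate stream.
#' @param model event model (see [sim_params()]).
#' @return data frame with one row per replicate: `inferred`, `optimal`,
#'   `match`, `error`; the summary attributes `accuracy` (fraction of
#'   matches) and `mean_error`.
#' @examples
#' \donttest{
#' r <- star_accuracy_experiment(reps = 5, n = 20, seed = 1)
#' attr(r, "accuracy")
#' }
#' @export
star_accuracy_experiment <- function(reps = 50L, n = 20L,
                                     sigma = max(1L, round(n / 2)),
                                     l = max(1L, round(n / 20)),
                                     seed = NULL,
                                     model = "dup_singleloss") {
  if (!is.null(seed)) set.seed(seed)
  params <- sim_params(n = n, sigma = sigma, l = l, model = model)
  costs <- if (model == "dup_singleloss") dup_singleloss_costs()
           else unit_costs()
  omodel <- if (model == "dup_singleloss") "dup_singleloss" else "dup_loss"
  out <- data.frame(rep = seq_len(reps), inferred = NA_real_,
                    optimal = NA_real_, match = NA, error = NA_real_)
  for (i in seq_len(reps)) {
    inst <- simulate_star(params)
    sol <- solve_star(star_instance(inst$A, inst$X, inst$Y, costs = costs))
    bud <- oracle_budget(max_events = max(10L, ceiling(sol$cost)),
                         max_len = 4L * params$n + 8L)
    ex <- exact_star_cost(inst$A, inst$X, inst$Y, model = omodel,
                          budget = bud, upper = sol$cost)
    out$inferred[i] <- sol$cost
    out$optimal[i] <- as.numeric(ex)
    out$match[i] <- isTRUE(sol$cost == as.numeric(ex))
    out$error[i] <- if (sol$cost > 0)
      (sol$cost - as.numeric(ex)) / sol$cost else 0
  }
  attr(out, "accuracy") <- mean(out$match)
  attr(out, "mean_error") <- mean(out$error)
  out
}
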