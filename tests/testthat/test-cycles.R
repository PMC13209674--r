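test_that("library screening drops exclusions and attaches costs", {
  m <- random_effects(n_genes = 5, n_drugs = 5, seed = 10)
  # identity without lists
  s0 <- screen_library(m)
  expect_equal(s0$effects$weights, m$weights)
  expect_equal(unname(s0$costs), rep(0, 5))
  s1 <- suppressMessages(
    screen_library(m, exclusions = c("d01", "D03"), costs = c(d02 = -1))
  )
  expect_setequal(s1$effects$drugs, c("d02", "d04", "d05"))
  expect_equal(s1$costs[["d02"]], -1)
  expect_equal(s1$costs[["d04"]], 0)
  expect_error(screen_library(m, exclusions = m$drugs), "every drug")
})

test_that("a one-cycle pipeline equals plain GA search plus dedup", {
  m <- random_effects(n_genes = 8, n_drugs = 8, seed = 20)
  scn <- random_scenario(m, 5, seed = 21, name = "only")
  ga <- ga_config(runs = 2, seed = 42)
  sched <- cycle_schedule(30, 10, 0, 3)
  cyc <- run_cycles(m, list(only = scn), schedule = sched, ga = ga)
  plain <- ga_optimize(m, scn,
    config = ga_config(
      population_size = 30, iterations = 10, runs = 2,
      max_drugs = 3, seed = 42
    ),
    costs = setNames(rep(0, 8), m$drugs)
  )
  expect_equal(
    dplyr::select(cyc$solutions, -"cycle"),
    plain$solutions
  )
})

test_that("the drug library never grows across cycles", {
  m <- random_effects(n_genes = 10, n_drugs = 12, seed = 30)
  s1 <- random_scenario(m, 4, seed = 31, name = "s1")
  s2 <- random_scenario(m, 4, seed = 32, name = "s2")
  cyc <- run_cycles(m, list(s1 = s1, s2 = s2),
    schedule = cycle_schedule(c(30, 20, 15), c(8, 6, 4), c(0, 1, 1), c(4, 3, 3)),
    ga = ga_config(runs = 2, seed = 7)
  )
  sizes <- lengths(cyc$libraries)
  expect_length(sizes, 3)
  expect_true(all(diff(sizes) <= 0))
  for (i in 2:3) {
    expect_true(all(cyc$libraries[[i]] %in% cyc$libraries[[i - 1]]))
  }
  # cycle tags present and within range
  expect_setequal(unique(cyc$solutions$cycle), 1:3)
})

test_that("cycle one prunes drugs that never contribute", {
  # planted two-drug optimum plus a certified null player: the null drug
  # can never be credited and must not survive the coarse cycle
  pl <- plant_scenario(
    n_genes = 4, planted_size = 2, n_null = 1,
    n_opposing = 2, n_partial = 0, seed = 12
  )
  null_drug <- pl$effects$drugs[colSums(pl$effects$weights != 0) == 0]
  expect_length(null_drug, 1)
  cyc <- run_cycles(pl$effects, list(planted = pl$scenario),
    schedule = cycle_schedule(c(40, 30), c(10, 6), c(0, 1), c(3, 3)),
    ga = ga_config(runs = 3, seed = 5)
  )
  expect_false(null_drug %in% cyc$libraries[[2]])
})

test_that("Pareto filter keeps best-per-size and marks non-dominated points", {
  sols <- tibble::tibble(
    scenario = "s",
    drug_set = c("a", "b", "a+b", "c+d", "a+b+c", "c+d+e"),
    drug_count = c(1, 1, 2, 2, 3, 3),
    mae = c(0.8, 0.9, 0.5, 0.6, 0.5, 0.7),
    composite_j = c(0.8, 0.9, 0.45, 0.6, 0.5, 0.7)
  )
  pf <- pareto_filter(sols)
  expect_equal(nrow(pf), 3) # one per size
  expect_equal(pf$mae, c(0.8, 0.5, 0.5))
  # the 3-drug point ties the 2-drug MAE: dominated
  expect_equal(pf$on_frontier, c(TRUE, TRUE, FALSE))
  # single record is its own frontier
  pf1 <- pareto_filter(sols[1, ])
  expect_true(pf1$on_frontier)
})

test_that("Pareto frontier is non-dominated on random solution sets", {
  set.seed(99)
  for (rep in 1:5) {
    sols <- tibble::tibble(
      scenario = "s",
      drug_set = as.character(1:30),
      drug_count = sample(1:6, 30, replace = TRUE),
      mae = round(runif(30, 0, 1), 2),
      composite_j = runif(30)
    )
    pf <- pareto_filter(sols)
    fr <- pf[pf$on_frontier, ]
    for (i in seq_len(nrow(fr))) {
      dominated <- any(
        fr$drug_count <= fr$drug_count[i] & fr$mae < fr$mae[i] |
          fr$drug_count < fr$drug_count[i] & fr$mae <= fr$mae[i]
      )
      expect_false(dominated)
    }
  }
})

test_that("frontier terminates where the planted optimum reaches zero error", {
  pl <- plant_scenario(
    n_genes = 6, planted_size = 3, n_null = 1,
    n_opposing = 2, n_partial = 2, seed = 14, max_drugs = 3
  )
  # enumeration oracle: three drugs reach MAE 0, nothing larger is needed
  enum <- pl$enumeration
  best_by_count <- enum |>
    dplyr::summarise(mae = min(.data$mae), .by = "drug_count") |>
    dplyr::arrange(.data$drug_count)
  expect_gt(min(best_by_count$mae[best_by_count$drug_count < 3]), 0)
  expect_equal(best_by_count$mae[best_by_count$drug_count == 3], 0)
  res <- ga_optimize(pl$effects, pl$scenario, ga_config(
    population_size = 80, iterations = 15, runs = 4, max_drugs = 5, seed = 3
  ))
  pf <- pareto_filter(res$solutions)
  fr <- pf[pf$on_frontier, ]
  expect_equal(max(fr$drug_count), 3)
  expect_equal(fr$mae[fr$drug_count == 3], 0)
})

test_that("comparison grid has one cell per scenario and size", {
  m <- random_effects(n_genes = 9, n_drugs = 8, seed = 40)
  s1 <- random_scenario(m, 4, seed = 41, name = "s1")
  s2 <- random_scenario(m, 4, seed = 42, name = "s2")
  grid <- compare_mae_only(m, list(s1 = s1, s2 = s2),
    sizes = 1:3,
    config = ga_config(population_size = 15, iterations = 4, runs = 1, seed = 1)
  )
  expect_equal(nrow(grid), 6)
  expect_setequal(grid$outcome, intersect(grid$outcome, c("lower", "equal", "higher")))
  expect_equal(nrow(dplyr::distinct(grid, .data$scenario, .data$drug_count)), 6)
})

test_that("identical weight vectors give an all-equal comparison grid", {
  m <- random_effects(n_genes = 6, n_drugs = 6, seed = 45)
  s1 <- random_scenario(m, 3, seed = 46, name = "s1")
  grid <- compare_mae_only(m, list(s1 = s1),
    sizes = 1:2,
    config = ga_config(population_size = 15, iterations = 4, runs = 1, seed = 2),
    weights = mae_only_weights()
  )
  expect_true(all(grid$outcome == "equal"))
  expect_equal(grid$mae_full, grid$mae_baseline)
})
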