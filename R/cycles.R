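#' Screen the drug library with exclusion and cost lists
#'
#' Drops banned drugs from the effect matrix and attaches a cost scalar to
#' every surviving drug (positive = avoid, negative = prefer, absent = 0).
#' This is the list-driven stand-in for regulatory screening sources
#' (carcinogenicity monographs, banned-substance lists, withdrawn status):
#' the caller supplies the lists, the screen applies them.
#'
#' @param x An [effect_matrix()].
#' @param exclusions Character vector of banned drug ids (case-insensitive).
#' @param costs Named numeric vector / list of drug costs.
#' @return List with `effects` (reduced matrix) and `costs` (named vector
#'   over the surviving drugs).
#' @export
screen_library <- function(x, exclusions = NULL, costs = NULL) {
  stopifnot(inherits(x, "effect_matrix"))
  exclusions <- tolower(exclusions %||% character())
  keep <- setdiff(x$drugs, exclusions)
  if (length(keep) == 0) abort("screening excluded every drug in the library")
  n_drop <- length(x$drugs) - length(keep)
  if (n_drop > 0) {
    inform(paste0("screen_library: excluded ", n_drop, " drug(s)"))
  }
  reduced <- subset_effects(x, drugs = keep)
  list(effects = reduced, costs = cost_lookup(costs, keep))
}

#' Coarse-to-fine cycle schedule
#'
#' The default three-cycle schedule: a coarse screen over the unified
#' scenario (large population, many iterations, cost term off, combination
#' ceiling raised to 7), then two per-scenario refinement cycles over the
#' shrinking library with the cost term active.
#'
#' @param population_sizes,iterations Integer vectors, one entry per cycle.
#' @param kappas Cost weights per cycle.
#' @param max_drugs Combination ceiling per cycle.
#' @return List of per-cycle setting lists.
#' @export
cycle_schedule <- function(population_sizes = c(500, 250, 150),
                           iterations = c(100, 70, 10),
                           kappas = c(0, 1, 1),
                           max_drugs = c(7, 6, 6)) {
  n <- length(population_sizes)
  stopifnot(
    n >= 1, length(iterations) == n, length(kappas) == n,
    length(max_drugs) == n
  )
  purrr::map(seq_len(n), function(i) {
    list(
      cycle = i,
      population_size = as.integer(population_sizes[i]),
      iterations = as.integer(iterations[i]),
      kappa = kappas[i],
      max_drugs = as.integer(max_drugs[i])
    )
  })
}

# drugs credited above epsilon in at least one retained solution
contributing_drugs <- function(x, solutions, scn, epsilon = 1e-9) {
  used <- character()
  for (i in seq_len(nrow(solutions))) {
    drugs <- solutions$drugs[[i]]
    A <- attribute_credit(x, drugs, method = "proportional")
    cvec <- vectorize_scenario(scn, x$genes)
    phi <- drug_usage(cvec, A, epsilon = epsilon)$phi
    used <- union(used, names(phi)[phi > epsilon])
  }
  sort(used)
}

#' Run the cyclic coarse-to-fine combination search
#'
#' Cycle 1 searches the unified (all-scenario) module to weed out drugs
#' that never contribute; drugs whose credited usage stays below `epsilon`
#' in every retained cycle-1 solution are dropped from the library. Later
#' cycles search each scenario separately over the surviving library with
#' the cost term switched on. The library can only shrink from cycle to
#' cycle.
#'
#' @param x An [effect_matrix()].
#' @param scenarios Named list of [scenario()] objects.
#' @param schedule A [cycle_schedule()].
#' @param ga A [ga_config()] supplying rates, runs, tournament/elitism and
#'   the base seed; population size, iteration count and chromosome length
#'   are overridden per cycle by the schedule.
#' @param weights A [fitness_weights()]; its `kappa` is overridden per
#'   cycle by the schedule.
#' @param exclusions,costs Passed to [screen_library()] before cycle 1.
#' @param epsilon Usage threshold defining a "contributing" drug.
#' @return A `cycle_result`: list with `solutions` (tibble over all cycles,
#'   deduplicated within scenario and cycle), `libraries` (drug ids
#'   entering each cycle), `convergence` (per cycle/scenario/run best-J
#'   traces) and `schedule`.
#' @export
run_cycles <- function(x, scenarios, schedule = cycle_schedule(),
                       ga = ga_config(), weights = fitness_weights(),
                       exclusions = NULL, costs = NULL, epsilon = 1e-9) {
  if (inherits(scenarios, "scenario")) {
    scenarios <- setNames(list(scenarios), scenarios$name)
  }
  stopifnot(length(scenarios) >= 1, length(schedule) >= 1)
  screened <- screen_library(x, exclusions = exclusions, costs = costs)
  lib_matrix <- screened$effects
  cost_vec <- screened$costs
  union_scn <- union_scenario(scenarios)
  all_solutions <- list()
  all_curves <- list()
  libraries <- list()
  for (ci in seq_along(schedule)) {
    cyc <- schedule[[ci]]
    libraries[[ci]] <- lib_matrix$drugs
    wts <- weights
    wts[["kappa"]] <- cyc$kappa
    cfg <- ga_config(
      population_size = cyc$population_size,
      iterations = cyc$iterations,
      crossover_rate = ga$crossover_rate,
      mutation_rate = ga$mutation_rate,
      max_drugs = min(cyc$max_drugs, length(lib_matrix$drugs)),
      runs = ga$runs,
      tournament_size = ga$tournament_size,
      elitism = ga$elitism,
      seed = ga$seed + (ci - 1L) * 1009L
    )
    scns <- if (ci == 1 && length(schedule) > 1) {
      setNames(list(union_scn), union_scn$name)
    } else {
      scenarios
    }
    retained <- list()
    for (si in seq_along(scns)) {
      cfg_s <- cfg
      cfg_s$seed <- cfg$seed + (si - 1L) * 131L
      res <- ga_optimize(lib_matrix, scns[[si]],
        config = cfg_s, weights = wts,
        costs = cost_vec, epsilon = epsilon
      )
      sol <- dplyr::mutate(res$solutions, cycle = ci, .before = 1)
      retained[[si]] <- sol
      all_curves[[length(all_curves) + 1]] <- dplyr::mutate(
        res$convergence,
        cycle = ci, scenario = scns[[si]]$name, .before = 1
      )
    }
    retained <- dplyr::bind_rows(retained)
    all_solutions[[ci]] <- retained
    # survivor rule: keep only drugs that contribute in retained solutions
    survivors <- character()
    for (si in seq_along(scns)) {
      sub <- retained[retained$scenario == scns[[si]]$name, , drop = FALSE]
      survivors <- union(
        survivors,
        contributing_drugs(lib_matrix, sub, scns[[si]], epsilon = epsilon)
      )
    }
    if (length(survivors) > 0 && ci < length(schedule)) {
      lib_matrix <- subset_effects(lib_matrix, drugs = sort(survivors))
      cost_vec <- cost_vec[sort(survivors)]
    }
  }
  structure(
    list(
      solutions = dplyr::bind_rows(all_solutions),
      libraries = libraries,
      convergence = dplyr::bind_rows(all_curves),
      schedule = schedule
    ),
    class = "cycle_result"
  )
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(
    "<cycle_result> ", length(x$libraries), " cycle(s); library sizes: ",
    paste(lengths(x$libraries), collapse = " -> "), "\n",
    sep = ""
  )
  cat("  ", nrow(x$solutions), " retained solution record(s)\n", sep = "")
  invisible(x)
}

#' Pareto-filter solutions over (MAE, combination size)
#'
#' For each scenario, keeps the best-MAE record at every combination size
#' (ties broken by lower composite J, then drug-set label) and marks the
#' non-dominated points: a point is on the frontier when no smaller
#' combination achieves an equal or lower MAE.
#'
#' @param solutions Solution tibble (from [ga_optimize()] or
#'   [run_cycles()]) with `scenario`, `drug_count`, `mae`, `composite_j`,
#'   `drug_set` columns.
#' @return Tibble of best-per-size records with logical `on_frontier`.
#' @export
pareto_filter <- function(solutions) {
  stopifnot(nrow(solutions) >= 1)
  best <- solutions |>
    dplyr::arrange(.data$mae, .data$composite_j, .data$drug_set) |>
    dplyr::distinct(.data$scenario, .data$drug_count, .keep_all = TRUE) |>
    dplyr::arrange(.data$scenario, .data$drug_count)
  best |>
    dplyr::mutate(
      on_frontier = .data$mae < cummin(dplyr::lag(.data$mae, default = Inf)),
      .by = "scenario"
    )
}

#' Compare the full composite objective with an MAE-only baseline
#'
#' Runs the fixed-size GA twice per (scenario, combination size) cell —
#' once with the full contribution-aware weights and once with
#' [mae_only_weights()] — under the same seeds and budget, and compares
#' the best MAE each search attains. Outcome `"lower"` means the full
#' objective found a strictly better MAE, `"equal"` the same, `"higher"`
#' a worse one (the cost of the secondary terms in that cell).
#'
#' @param x An [effect_matrix()].
#' @param scenarios Named list of [scenario()] objects.
#' @param sizes Integer vector of combination sizes to test (default 1:6).
#' @param config A [ga_config()] (population/iterations/runs apply to every
#'   cell; `max_drugs` is ignored in favour of the cell size).
#' @param weights Full-objective [fitness_weights()].
#' @param costs Named drug cost vector.
#' @param tol Equality tolerance on MAE.
#' @return Tibble with one row per cell: `scenario`, `drug_count`,
#'   `mae_full`, `mae_baseline`, `outcome`.
#' @export
compare_mae_only <- function(x, scenarios, sizes = 1:6,
                             config = ga_config(), weights = fitness_weights(),
                             costs = NULL, tol = 1e-9) {
  if (inherits(scenarios, "scenario")) {
    scenarios <- setNames(list(scenarios), scenarios$name)
  }
  base_w <- mae_only_weights()
  grid <- tidyr::expand_grid(
    scenario_i = seq_along(scenarios),
    size = as.integer(sizes)
  )
  purrr::pmap_dfr(grid, function(scenario_i, size) {
    scn <- scenarios[[scenario_i]]
    cfg <- config
    cfg$max_drugs <- size
    cfg$seed <- config$seed + (scenario_i - 1L) * 613L + size * 7L
    full <- ga_optimize(x, scn,
      config = cfg, weights = weights,
      costs = costs, fixed_size = size
    )
    base <- ga_optimize(x, scn,
      config = cfg, weights = base_w,
      costs = costs, fixed_size = size
    )
    mae_full <- min(full$solutions$mae)
    mae_base <- min(base$solutions$mae)
    tibble::tibble(
      scenario = scn$name,
      drug_count = size,
      mae_full = mae_full,
      mae_baseline = mae_base,
      outcome = dplyr::case_when(
        mae_full < mae_base - tol ~ "lower",
        mae_full > mae_base + tol ~ "higher",
        .default = "equal"
      )
    )
  })
}
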