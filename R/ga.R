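#' Genetic-algorithm configuration
#'
#' Search settings for the categorical GA over drug-combination
#' chromosomes. A chromosome is a fixed-length vector of `max_drugs` slots,
#' each holding a drug id or the empty sentinel; the empty sentinel gives
#' variable combination size within the fixed length, and duplicate alleles
#' collapse to one active drug at evaluation. Defaults: crossover 0.9,
#' mutation 0.2, tournament size 3, one elite individual (which makes the
#' best-so-far curve monotone non-increasing), 10 repeated runs.
#'
#' @param population_size Number of chromosomes per generation.
#' @param iterations Number of generations.
#' @param crossover_rate Probability a selected pair undergoes uniform
#'   crossover.
#' @param mutation_rate Per-slot probability of replacement by a uniformly
#'   random allele (drug or empty).
#' @param max_drugs Chromosome length K (maximum combination size).
#' @param runs Number of independent seeded repeats.
#' @param tournament_size Tournament size for parent selection.
#' @param elitism Number of best individuals copied unchanged.
#' @param seed Base integer seed; run `i` uses `seed + i - 1`.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 150, iterations = 50,
                      crossover_rate = 0.9, mutation_rate = 0.2,
                      max_drugs = 6, runs = 10, tournament_size = 3,
                      elitism = 1, seed = 1) {
  stopifnot(
    population_size >= 2, iterations >= 1,
    crossover_rate >= 0, crossover_rate <= 1,
    mutation_rate >= 0, mutation_rate <= 1,
    max_drugs >= 1, runs >= 1, tournament_size >= 1, elitism >= 0
  )
  structure(
    list(
      population_size = as.integer(population_size),
      iterations = as.integer(iterations),
      crossover_rate = crossover_rate,
      mutation_rate = mutation_rate,
      max_drugs = as.integer(max_drugs),
      runs = as.integer(runs),
      tournament_size = as.integer(tournament_size),
      elitism = as.integer(elitism),
      seed = as.integer(seed)
    ),
    class = "ga_config"
  )
}

# fast composite evaluation of one active drug-index set on the masked
# (scenario-gene) effect matrix; returns terms + J as a named numeric vector
fast_eval <- function(rm, cm, idx, wt, costs_vec, epsilon, kslots,
                      omega_vec, attribution, permutations) {
  r <- rm[, idx, drop = FALSE]
  S <- rowSums(r)
  e <- clip1(S)
  A <- if (attribution == "proportional") {
    r * ifelse(S == 0, 0, e / S)
  } else {
    shapley_exact(r)
  }
  absA <- abs(A)
  sgn_match <- (sign(A) == sign(cm)) & A != 0
  same_mass <- rowSums(absA * sgn_match)
  gprime <- length(cm)
  mae <- mean(abs(cm - e))
  waste <- sum(pmax(0, same_mass - abs(cm)))
  mis <- sum(absA[A != 0 & !sgn_match])
  pos <- same_mass > 0
  ent <- if (any(pos)) {
    pr <- (absA * sgn_match)[pos, , drop = FALSE] / same_mass[pos]
    0 - sum(pr[pr > 0] * log(pr[pr > 0])) + 0
  } else {
    0
  }
  cov <- sum(omega_vec * pmin(abs(cm), same_mass) / abs(cm))
  phi <- colSums(absA)
  used <- phi > epsilon
  r_count <- sum(used)
  r_cost <- sum(costs_vec[idx][used])
  j <- wt[["alpha"]] * mae + wt[["beta"]] * waste / gprime +
    wt[["gamma"]] * mis / gprime + wt[["eta"]] * ent / gprime +
    wt[["lambda_count"]] * r_count / kslots + wt[["kappa"]] * r_cost -
    wt[["tau"]] * cov / sum(omega_vec)
  c(
    mae = mae, r_waste = waste, r_mismatch = mis, r_entropy = ent,
    coverage = cov, r_count = r_count, r_cost = r_cost, composite_j = j
  )
}

# evaluation context shared by all GA entry points: masks the matrix to
# scenario genes once and memoizes evaluations per distinct active set
make_evaluator <- function(x, scn, weights, costs = NULL, omega = 1,
                           epsilon = 1e-9, kslots = 6,
                           attribution = "proportional",
                           permutations = 256) {
  cvec <- if (inherits(scn, "scenario")) {
    vectorize_scenario(scn, x$genes)
  } else {
    stopifnot(length(scn) == length(x$genes))
    setNames(as.numeric(scn), x$genes)
  }
  mask <- cvec != 0
  if (!any(mask)) abort("scenario shares no genes with the effect matrix")
  rm_ <- x$weights[mask, , drop = FALSE]
  cm <- cvec[mask]
  costs_vec <- cost_lookup(costs, x$drugs)
  omega_vec <- rep_len(omega, length(cm))
  cache <- new.env(parent = emptyenv(), size = 4096L)
  eval_set <- function(idx) {
    key <- paste(idx, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    val <- fast_eval(
      rm_, cm, idx, weights, costs_vec, epsilon, kslots,
      omega_vec, attribution, permutations
    )
    cache[[key]] <- val
    val
  }
  list(
    eval_set = eval_set, drugs = x$drugs, n_drugs = length(x$drugs),
    scenario_name = if (inherits(scn, "scenario")) scn$name else "custom"
  )
}

active_cols <- function(chrom) sort(unique(chrom[chrom > 0L]))

redraw_empty <- function(pop, n_drugs) {
  dead <- which(colSums(pop > 0L) == 0L)
  if (length(dead)) {
    slot <- sample.int(nrow(pop), length(dead), replace = TRUE)
    pop[cbind(slot, dead)] <- sample.int(n_drugs, length(dead), replace = TRUE)
  }
  pop
}

# one seeded GA run over variable-size chromosomes (0 = empty slot)
ga_run_once <- function(ev, config, run_seed) {
  set.seed(run_seed)
  np <- config$population_size
  k <- config$max_drugs
  nd <- ev$n_drugs
  pop <- matrix(
    sample.int(nd + 1L, k * np, replace = TRUE) - 1L,
    nrow = k, ncol = np
  )
  pop <- redraw_empty(pop, nd)
  evaluate <- function(p) {
    vapply(seq_len(ncol(p)), function(i) {
      ev$eval_set(active_cols(p[, i]))[["composite_j"]]
    }, numeric(1))
  }
  fit <- evaluate(pop)
  best_i <- which.min(fit)
  best <- list(chrom = pop[, best_i], j = fit[best_i])
  curve <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    # tournament selection
    contenders <- matrix(
      sample.int(np, np * config$tournament_size, replace = TRUE),
      nrow = np
    )
    sel <- contenders[cbind(
      seq_len(np),
      max.col(-matrix(fit[contenders], nrow = np), ties.method = "first")
    )]
    children <- pop[, sel, drop = FALSE]
    # uniform crossover on consecutive pairs
    n_pairs <- np %/% 2L
    do_cx <- runif(n_pairs) < config$crossover_rate
    for (pr in which(do_cx)) {
      i1 <- 2L * pr - 1L
      i2 <- 2L * pr
      mix <- runif(k) < 0.5
      c1 <- children[, i1]
      c2 <- children[, i2]
      children[mix, i1] <- c2[mix]
      children[mix, i2] <- c1[mix]
    }
    # per-slot mutation to a random allele (drug or empty)
    mut <- matrix(runif(k * np) < config$mutation_rate, k, np)
    nmut <- sum(mut)
    if (nmut > 0) {
      children[mut] <- sample.int(nd + 1L, nmut, replace = TRUE) - 1L
    }
    children <- redraw_empty(children, nd)
    # elitism: carry over the best of the previous generation
    if (config$elitism > 0) {
      keep <- order(fit)[seq_len(min(config$elitism, np))]
      children[, seq_along(keep)] <- pop[, keep, drop = FALSE]
    }
    pop <- children
    fit <- evaluate(pop)
    gen_best <- which.min(fit)
    if (fit[gen_best] < best$j) {
      best <- list(chrom = pop[, gen_best], j = fit[gen_best])
    }
    curve[it] <- best$j
  }
  list(pop = pop, fit = fit, best = best, curve = curve)
}

# one seeded GA run with a fixed number of distinct active drugs
ga_run_fixed <- function(ev, config, run_seed, size) {
  set.seed(run_seed)
  np <- config$population_size
  nd <- ev$n_drugs
  if (size > nd) abort("fixed combination size exceeds library size")
  pop <- replicate(np, sample.int(nd, size))
  pop <- matrix(pop, nrow = size)
  evaluate <- function(p) {
    vapply(seq_len(ncol(p)), function(i) {
      ev$eval_set(sort(p[, i]))[["composite_j"]]
    }, numeric(1))
  }
  fit <- evaluate(pop)
  best_i <- which.min(fit)
  best <- list(chrom = pop[, best_i], j = fit[best_i])
  curve <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    contenders <- matrix(
      sample.int(np, np * config$tournament_size, replace = TRUE),
      nrow = np
    )
    sel <- contenders[cbind(
      seq_len(np),
      max.col(-matrix(fit[contenders], nrow = np), ties.method = "first")
    )]
    children <- pop[, sel, drop = FALSE]
    n_pairs <- np %/% 2L
    do_cx <- runif(n_pairs) < config$crossover_rate
    for (pr in which(do_cx)) {
      i1 <- 2L * pr - 1L
      i2 <- 2L * pr
      u <- unique(c(children[, i1], children[, i2]))
      children[, i1] <- if (length(u) == size) u else sample(u, size)
      children[, i2] <- if (length(u) == size) u else sample(u, size)
    }
    if (nd > size) {
      for (i in seq_len(np)) {
        hits <- which(runif(size) < config$mutation_rate)
        for (sl in hits) {
          pool <- setdiff(seq_len(nd), children[, i])
          if (length(pool)) children[sl, i] <- pool[sample.int(length(pool), 1)]
        }
      }
    }
    if (config$elitism > 0) {
      keep <- order(fit)[seq_len(min(config$elitism, np))]
      children[, seq_along(keep)] <- pop[, keep, drop = FALSE]
    }
    pop <- children
    fit <- evaluate(pop)
    gen_best <- which.min(fit)
    if (fit[gen_best] < best$j) {
      best <- list(chrom = pop[, gen_best], j = fit[gen_best])
    }
    curve[it] <- best$j
  }
  list(pop = pop, fit = fit, best = best, curve = curve)
}

solution_row <- function(ev, idx, run, source) {
  terms <- ev$eval_set(idx)
  tibble::tibble(
    scenario = ev$scenario_name,
    run = run,
    source = source,
    drugs = list(ev$drugs[idx]),
    drug_set = paste(ev$drugs[idx], collapse = "+"),
    drug_count = length(idx),
    mae = terms[["mae"]],
    r_waste = terms[["r_waste"]],
    r_mismatch = terms[["r_mismatch"]],
    r_entropy = terms[["r_entropy"]],
    coverage = terms[["coverage"]],
    r_count = terms[["r_count"]],
    r_cost = terms[["r_cost"]],
    composite_j = terms[["composite_j"]]
  )
}

#' Search for drug combinations with the genetic algorithm
#'
#' Runs the categorical GA `config$runs` times with consecutive seeds and
#' collects, per run, the best combination found plus the distinct
#' combinations in the final population. Chromosomes are `max_drugs` slots
#' over the drug library plus an empty sentinel; evaluation uses the
#' distinct active drugs. Fitness evaluations are memoized per active set,
#' so repeated visits to the same combination are free.
#'
#' @param x An [effect_matrix()].
#' @param scn A [scenario()] or counteraction vector over `x$genes`.
#' @param config A [ga_config()].
#' @param weights A [fitness_weights()].
#' @param costs Named drug cost vector (positive = avoid, negative =
#'   prefer).
#' @param attribution Credit scheme used inside the fitness
#'   (`"proportional"`, the fast search default, or `"shapley"` exact).
#' @param omega,epsilon See [composite_fitness()].
#' @param fixed_size If non-`NULL`, constrain every chromosome to exactly
#'   this many distinct drugs (used by the fixed-size comparison harness).
#' @return A `ga_result`: list with `solutions` (tibble of deduplicated
#'   combination records, one per distinct drug set, best J kept),
#'   `best_per_run` (one undeduplicated record per run: that run's best),
#'   `convergence` (tibble `run`, `iteration`, `best_j`; non-increasing in
#'   `iteration` by elitism), `best` (the single best record) and `config`.
#' @examples
#' m <- effect_matrix(matrix(c(-1, 0, 0, -1), 2, 2,
#'   dimnames = list(c("G1", "G2"), c("d1", "d2"))
#' ))
#' scn <- scenario("demo", c(G1 = -1, G2 = -1))
#' res <- ga_optimize(m, scn, ga_config(
#'   population_size = 20,
#'   iterations = 5, runs = 2, max_drugs = 2, seed = 1
#' ))
#' res$best$drug_set
#' @export
ga_optimize <- function(x, scn, config = ga_config(),
                        weights = fitness_weights(), costs = NULL,
                        attribution = c("proportional", "shapley"),
                        omega = 1, epsilon = 1e-9, fixed_size = NULL) {
  attribution <- match.arg(attribution)
  ev <- make_evaluator(
    x, scn, weights,
    costs = costs, omega = omega,
    epsilon = epsilon, kslots = config$max_drugs, attribution = attribution
  )
  sols <- list()
  curves <- list()
  for (run in seq_len(config$runs)) {
    run_seed <- config$seed + run - 1L
    out <- if (is.null(fixed_size)) {
      ga_run_once(ev, config, run_seed)
    } else {
      ga_run_fixed(ev, config, run_seed, as.integer(fixed_size))
    }
    sets <- unique(lapply(
      seq_len(ncol(out$pop)),
      function(i) {
        if (is.null(fixed_size)) {
          active_cols(out$pop[, i])
        } else {
          sort(out$pop[, i])
        }
      }
    ))
    best_idx <- if (is.null(fixed_size)) {
      active_cols(out$best$chrom)
    } else {
      sort(out$best$chrom)
    }
    rows <- c(
      list(solution_row(ev, best_idx, run, "best")),
      purrr::map(sets, solution_row, ev = ev, run = run, source = "final_pop")
    )
    sols[[run]] <- dplyr::bind_rows(rows)
    curves[[run]] <- tibble::tibble(
      run = run, iteration = seq_along(out$curve), best_j = out$curve
    )
  }
  all_rows <- dplyr::bind_rows(sols)
  best_per_run <- all_rows |>
    dplyr::filter(.data$source == "best") |>
    dplyr::arrange(.data$run)
  solutions <- dedup_solutions(all_rows)
  convergence <- dplyr::bind_rows(curves)
  best <- solutions[which.min(solutions$composite_j), ]
  structure(
    list(
      solutions = solutions, best_per_run = best_per_run,
      convergence = convergence, best = best, config = config
    ),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat(
    "<ga_result> ", nrow(x$solutions), " distinct combination(s) from ",
    x$config$runs, " run(s)\n",
    sep = ""
  )
  cat(
    "  best: {", x$best$drug_set, "}  MAE ", sprintf("%.4f", x$best$mae),
    "  J ", sprintf("%.4f", x$best$composite_j), "\n",
    sep = ""
  )
  invisible(x)
}

#' Remove duplicate combinations
#'
#' Solutions are identical when their unordered active-drug sets match
#' within the same scenario (and cycle, when a `cycle` column is present);
#' the record with the best (lowest) composite J survives, ties broken by
#' MAE then drug set label.
#'
#' @param solutions Solution tibble with at least `scenario`, `drug_set`,
#'   `mae`, `composite_j` columns.
#' @return Deduplicated tibble.
#' @export
dedup_solutions <- function(solutions) {
  keys <- intersect(c("scenario", "cycle", "drug_set"), names(solutions))
  solutions |>
    dplyr::arrange(.data$composite_j, .data$mae, .data$drug_set) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(keys)), .keep_all = TRUE)
}
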