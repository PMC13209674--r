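#' Assemble and validate a pipeline run configuration
#'
#' Bundles every knob of the end-to-end workflow — input paths, fitness
#' weights, GA settings, cycle schedule, attribution mode and the base
#' seed — into a validated list. A serialized copy is written into the
#' output directory by [run_pipeline()] so every run is reproducible from
#' its provenance config plus seed.
#'
#' @param interactions Path to the delimited interaction file.
#' @param scenarios `"luad"` for the packaged scenarios, or a path to a
#'   YAML/JSON scenario file.
#' @param out_dir Output directory (created if missing).
#' @param costs Optional path to a two-column delimited file
#'   (`drug_id`, `cost`).
#' @param exclusions Optional path to a one-drug-id-per-line exclusion
#'   list.
#' @param weights A [fitness_weights()].
#' @param ga A [ga_config()].
#' @param schedule A [cycle_schedule()].
#' @param attribution `"proportional"` or `"shapley"`.
#' @param permutations Monte-Carlo permutations when auditing with Shapley.
#' @param min_evidence,ambiguity_threshold Conflict-resolution thresholds
#'   for [build_effect_matrix()].
#' @param seed Base integer seed (overrides `ga$seed`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(interactions, scenarios = "luad", out_dir = "ctdcombo_out",
                       costs = NULL, exclusions = NULL,
                       weights = fitness_weights(), ga = ga_config(),
                       schedule = cycle_schedule(), attribution = "proportional",
                       permutations = 256, min_evidence = 1,
                       ambiguity_threshold = 0.2, seed = 1) {
  cfg <- list(
    interactions = interactions, scenarios = scenarios, out_dir = out_dir,
    costs = costs, exclusions = exclusions, weights = weights, ga = ga,
    schedule = schedule, attribution = attribution,
    permutations = as.integer(permutations), min_evidence = min_evidence,
    ambiguity_threshold = ambiguity_threshold, seed = as.integer(seed)
  )
  problems <- character()
  if (!is.character(cfg$interactions) || !file.exists(cfg$interactions)) {
    problems <- c(problems, "interactions: file does not exist")
  }
  if (!identical(cfg$scenarios, "luad") &&
    (!is.character(cfg$scenarios) || !file.exists(cfg$scenarios))) {
    problems <- c(problems, "scenarios: must be \"luad\" or an existing file")
  }
  for (fld in c("costs", "exclusions")) {
    if (!is.null(cfg[[fld]]) && !file.exists(cfg[[fld]])) {
      problems <- c(problems, paste0(fld, ": file does not exist"))
    }
  }
  if (!cfg$attribution %in% c("proportional", "shapley")) {
    problems <- c(problems, "attribution: must be proportional or shapley")
  }
  if (cfg$permutations < 1) problems <- c(problems, "permutations: must be >= 1")
  if (length(problems) > 0) {
    abort(paste0(
      "invalid run configuration:\n  ",
      paste(problems, collapse = "\n  ")
    ))
  }
  cfg$ga$seed <- cfg$seed
  structure(cfg, class = "run_config")
}

read_cost_file <- function(path) {
  tab <- readr::read_delim(path,
    delim = if (grepl("\t", readLines(path, n = 1))) "\t" else ",",
    col_names = c("drug_id", "cost"), col_types = "cd", progress = FALSE,
    comment = "#"
  )
  setNames(tab$cost, tolower(tab$drug_id))
}

#' Execute the full combination-search pipeline
#'
#' Ingests interactions, builds the effect matrix, loads scenarios and
#' cost/exclusion lists, runs the cyclic GA search, Pareto-filters the
#' results and writes all artifact tables (solutions, Pareto points,
#' convergence traces, grouped alternatives, the effect matrix and a
#' provenance copy of the configuration) into `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return The `cycle_result`, invisibly, with `pareto` and `groups`
#'   attached.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_interactions(config$interactions)
  effects <- build_effect_matrix(records,
    min_evidence = config$min_evidence,
    ambiguity_threshold = config$ambiguity_threshold
  )
  scns <- if (identical(config$scenarios, "luad")) {
    luad_scenarios()
  } else {
    read_scenarios(config$scenarios)
  }
  costs <- if (!is.null(config$costs)) read_cost_file(config$costs)
  excl <- if (!is.null(config$exclusions)) readLines(config$exclusions)
  result <- run_cycles(effects, scns,
    schedule = config$schedule, ga = config$ga, weights = config$weights,
    exclusions = excl, costs = costs
  )
  final_cycle <- max(result$solutions$cycle)
  final <- result$solutions[result$solutions$cycle == final_cycle, ]
  pareto <- pareto_filter(final)
  groups <- purrr::map_dfr(scns, function(scn) {
    sub <- pareto[pareto$scenario == scn$name, ]
    if (nrow(sub) == 0) {
      return(tibble::tibble())
    }
    drugs <- unique(unlist(sub$drugs))
    lib <- result$libraries[[final_cycle]]
    group_alternatives(
      subset_effects(effects, drugs = lib), scn, intersect(drugs, lib)
    )
  })
  out <- function(name) file.path(config$out_dir, name)
  readr::write_tsv(
    dplyr::select(result$solutions, -"drugs"), out("solutions.tsv"),
    progress = FALSE
  )
  readr::write_tsv(
    dplyr::select(pareto, -"drugs"), out("pareto.tsv"),
    progress = FALSE
  )
  readr::write_tsv(result$convergence, out("convergence.tsv"), progress = FALSE)
  if (nrow(groups) > 0) {
    readr::write_tsv(groups, out("grouped_alternatives.tsv"), progress = FALSE)
  }
  write_effect_matrix(effects, out("effect_matrix.tsv"),
    min_evidence = config$min_evidence,
    ambiguity_threshold = config$ambiguity_threshold
  )
  provenance <- list(
    interactions = config$interactions, scenarios = config$scenarios,
    costs = config$costs, exclusions = config$exclusions,
    attribution = config$attribution, permutations = config$permutations,
    min_evidence = config$min_evidence,
    ambiguity_threshold = config$ambiguity_threshold,
    seed = config$seed,
    weights = as.list(unclass(config$weights)),
    ga = unclass(config$ga),
    schedule = config$schedule
  )
  yaml::write_yaml(provenance, out("run_config.yaml"))
  result$pareto <- pareto
  result$groups <- groups
  invisible(result)
}

#' Write a self-contained demo workspace
#'
#' Generates a synthetic interaction file, a scenario file, a cost table
#' and an exclusion list under `dir`, ready for [run_config()] /
#' [run_pipeline()] or the command-line wrapper.
#'
#' @param dir Target directory.
#' @param spec A [fixture_spec()] for the interaction data.
#' @return Named list of the paths written.
#' @export
write_demo_workspace <- function(dir, spec = fixture_spec(
                                   n_genes = 10,
                                   n_drugs = 15, seed = 42
                                 )) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inter <- file.path(dir, "interactions.tsv")
  gen <- generate_interaction_file(spec, inter, malformed = 1)
  genes <- gen$truth$genes
  set.seed(spec$seed)
  scn_list <- list(
    module_a = as.list(setNames(
      sample(c(-1, 1), 4, replace = TRUE),
      genes[1:4]
    )),
    module_b = as.list(setNames(
      sample(c(-1, 1), 4, replace = TRUE),
      genes[5:8]
    ))
  )
  scn_path <- file.path(dir, "scenarios.yaml")
  yaml::write_yaml(scn_list, scn_path)
  cost_path <- file.path(dir, "costs.tsv")
  writeLines(
    c(paste0(gen$truth$drugs[1], "\t1"), paste0(gen$truth$drugs[2], "\t-0.5")),
    cost_path
  )
  excl_path <- file.path(dir, "exclusions.txt")
  writeLines(gen$truth$drugs[length(gen$truth$drugs)], excl_path)
  list(
    interactions = inter, scenarios = scn_path,
    costs = cost_path, exclusions = excl_path
  )
}
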