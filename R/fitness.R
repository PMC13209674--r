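#' Weights of the composite fitness
#'
#' The composite objective is
#' \deqn{J = \alpha\,\mathrm{MAE} + \beta R_{waste} + \gamma R_{mis} +
#'   \eta R_{entropy} + \lambda R_{count} + \kappa R_{cost} - \tau\,Cov.}
#' Defaults are the shipped search setting: MAE dominates
#' (`alpha = 1`), waste/mismatch/coverage carry moderate weight (0.2) and
#' entropy/parsimony small weight (0.05). The cost term is off
#' (`kappa = 0`) in the coarse first cycle and switched to 1 in later
#' cycles by the cycle schedule.
#'
#' @param alpha MAE weight.
#' @param beta Waste (same-sign overshoot) weight.
#' @param gamma Mismatch (opposing credit) weight.
#' @param eta Entropy (credit dispersion) weight.
#' @param lambda_count Parsimony (drug count) weight.
#' @param kappa Cost weight.
#' @param tau Coverage reward weight.
#' @return A named numeric vector of class `fitness_weights`.
#' @export
fitness_weights <- function(alpha = 1, beta = 0.2, gamma = 0.2, eta = 0.05,
                            lambda_count = 0.05, kappa = 0, tau = 0.2) {
  w <- c(
    alpha = alpha, beta = beta, gamma = gamma, eta = eta,
    lambda_count = lambda_count, kappa = kappa, tau = tau
  )
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("all fitness weights must be finite and >= 0")
  }
  structure(w, class = c("fitness_weights", "numeric"))
}

#' MAE-only weights (baseline objective)
#'
#' Convenience constructor for the baseline objective that scores a
#' combination by mean absolute error alone.
#' @return A [fitness_weights()] with `alpha = 1` and all other weights 0.
#' @export
mae_only_weights <- function() {
  fitness_weights(
    alpha = 1, beta = 0, gamma = 0, eta = 0,
    lambda_count = 0, kappa = 0, tau = 0
  )
}

# --- individual terms -------------------------------------------------------
# All term functions take the counteraction vector `cvec` over the same gene
# order as the rows of the contribution matrix `A`; genes with c = 0 are
# outside the scenario and excluded from every sum.

term_parts <- function(cvec, A) {
  mask <- cvec != 0
  if (!any(mask)) abort("counteraction vector has no nonzero (scenario) genes")
  cm <- cvec[mask]
  Am <- A[mask, , drop = FALSE]
  sgn_match <- sweep(sign(Am), 1, sign(cm), "==") & Am != 0
  absA <- abs(Am)
  same_mass <- rowSums(absA * sgn_match)
  list(
    cm = cm, Am = Am, absA = absA,
    sgn_match = sgn_match, same_mass = same_mass
  )
}

#' Mean absolute error to the counteraction vector
#'
#' @param cvec Counteraction vector (named, entries in `c(-1, 0, 1)`);
#'   genes with 0 are outside the scenario and excluded.
#' @param evec Net combination effect vector aligned to `cvec` (see
#'   [combination_effect()]).
#' @return Mean of `|c_g - e_g|` over scenario genes.
#' @export
mae_error <- function(cvec, evec) {
  stopifnot(length(cvec) == length(evec))
  mask <- cvec != 0
  if (!any(mask)) abort("counteraction vector has no nonzero (scenario) genes")
  mean(abs(cvec[mask] - evec[mask]))
}

#' Contribution-aware penalty and reward terms
#'
#' Raw (unnormalized) secondary terms computed from a per-gene credit
#' allocation `A` (see [attribute_credit()]):
#'
#' * `waste_penalty()`: same-direction credited magnitude in excess of the
#'   target magnitude `|C_i|` — overshoot in the correct direction.
#' * `mismatch_penalty()`: credited magnitude opposing the target
#'   direction.
#' * `entropy_penalty()`: Shannon entropy (natural log) of each gene's
#'   same-direction credit shares, summed over genes; penalizes diffuse,
#'   redundant credit. A gene with a single contributor scores 0, `n` equal
#'   contributors score `log(n)`.
#' * `coverage_reward()`: per-gene direction-correct fulfillment
#'   `omega_i * min(|C_i|, same-direction mass) / |C_i|`, summed; capped at
#'   `omega_i` per gene so overshoot earns nothing.
#' * `drug_usage()`: credited usage `phi_j = sum_i |a_ij|` per drug, the
#'   parsimony count `R_count = #{phi_j > epsilon}` and the cost
#'   `R_cost = sum of c_j over drugs with phi_j > epsilon`.
#'
#' @inheritParams mae_error
#' @param A Contribution matrix aligned to `cvec` (genes x drugs).
#' @param omega Non-negative per-gene reward weights over scenario genes
#'   (recycled scalar allowed; default 1).
#' @param costs Named cost vector/list (drug id -> scalar; positive = avoid,
#'   negative = prefer; missing = 0).
#' @param epsilon Usage threshold above which a drug counts as active.
#' @return `waste_penalty`, `mismatch_penalty`, `entropy_penalty`,
#'   `coverage_reward`: a single number. `drug_usage`: a list with `phi`
#'   (named per-drug usage), `r_count` and `r_cost`.
#' @name fitness_terms
NULL

#' @rdname fitness_terms
#' @export
waste_penalty <- function(cvec, A) {
  p <- term_parts(cvec, A)
  sum(pmax(0, p$same_mass - abs(p$cm)))
}

#' @rdname fitness_terms
#' @export
mismatch_penalty <- function(cvec, A) {
  p <- term_parts(cvec, A)
  opposing <- p$Am != 0 & !p$sgn_match
  sum(p$absA * opposing)
}

#' @rdname fitness_terms
#' @export
entropy_penalty <- function(cvec, A) {
  p <- term_parts(cvec, A)
  share <- p$absA * p$sgn_match
  pos <- p$same_mass > 0
  if (!any(pos)) {
    return(0)
  }
  pr <- share[pos, , drop = FALSE] / p$same_mass[pos]
  plogp <- ifelse(pr > 0, pr * log(pr), 0)
  0 - sum(plogp) + 0 # "+ 0" avoids IEEE negative zero
}

#' @rdname fitness_terms
#' @export
coverage_reward <- function(cvec, A, omega = 1) {
  p <- term_parts(cvec, A)
  n <- length(p$cm)
  omega <- rep_len(omega, n)
  if (any(omega < 0)) abort("omega weights must be >= 0")
  sum(omega * pmin(abs(p$cm), p$same_mass) / abs(p$cm))
}

#' @rdname fitness_terms
#' @export
drug_usage <- function(cvec, A, costs = NULL, epsilon = 1e-9) {
  if (epsilon <= 0) abort("epsilon must be > 0")
  p <- term_parts(cvec, A)
  phi <- colSums(p$absA)
  names(phi) <- colnames(A)
  used <- phi > epsilon
  cj <- cost_lookup(costs, colnames(A))
  list(phi = phi, r_count = sum(used), r_cost = sum(cj[used]))
}

cost_lookup <- function(costs, drug_ids) {
  out <- setNames(numeric(length(drug_ids)), drug_ids)
  if (is.null(costs) || length(costs) == 0) {
    return(out)
  }
  costs <- unlist(costs)
  if (is.null(names(costs))) abort("costs must be named by drug id")
  names(costs) <- tolower(names(costs))
  hit <- intersect(drug_ids, names(costs))
  out[hit] <- costs[hit]
  out
}

# --- composite --------------------------------------------------------------

#' Score a drug combination with the composite fitness
#'
#' Computes the net combination effect, allocates per-gene credit with the
#' chosen attribution scheme, and assembles MAE plus the six secondary
#' terms into the weighted composite J (lower is better). Secondary
#' penalties are normalized by the number of scenario genes, coverage by
#' the total reward weight and the parsimony count by the slot budget
#' `max_drugs`, so all weighted terms live on comparable scales.
#'
#' @param x An [effect_matrix()].
#' @param scn A [scenario()] (or a counteraction vector over `x$genes`).
#' @param drug_ids Combination: character vector of drug ids (empty/`NA`
#'   slots and duplicates allowed).
#' @param weights A [fitness_weights()].
#' @param costs Named drug cost vector (see [fitness_terms]).
#' @param attribution `"proportional"` or `"shapley"`.
#' @param mode,permutations,seed Passed to [attribute_credit()] for Shapley.
#' @param omega Per-gene coverage weights over scenario genes.
#' @param epsilon Usage threshold for the parsimony/cost terms.
#' @param max_drugs Slot budget K used to normalize the count term.
#' @return A `fitness_breakdown` object; see [glance.fitness_breakdown()].
#' @examples
#' m <- effect_matrix(matrix(c(-1, 0, 0, -1), 2, 2,
#'   dimnames = list(c("G1", "G2"), c("d1", "d2"))
#' ))
#' scn <- scenario("demo", c(G1 = -1, G2 = -1))
#' glance(composite_fitness(m, scn, c("d1", "d2")))
#' @export
composite_fitness <- function(x, scn, drug_ids, weights = fitness_weights(),
                              costs = NULL,
                              attribution = c("proportional", "shapley"),
                              mode = "exact", permutations = 256, seed = NULL,
                              omega = 1, epsilon = 1e-9, max_drugs = 6) {
  stopifnot(inherits(x, "effect_matrix"))
  attribution <- match.arg(attribution)
  cvec <- if (inherits(scn, "scenario")) {
    vectorize_scenario(scn, x$genes)
  } else {
    stopifnot(length(scn) == length(x$genes))
    setNames(as.numeric(scn), x$genes)
  }
  s <- check_combo(x, drug_ids)
  A <- attribute_credit(x, s,
    method = attribution, mode = mode,
    permutations = permutations, seed = seed
  )
  e <- combination_effect(x, s)
  breakdown_from_parts(
    cvec = cvec, evec = e, A = unclass(A), active = s,
    weights = weights, costs = costs, omega = omega, epsilon = epsilon,
    max_drugs = max_drugs,
    scenario_name = if (inherits(scn, "scenario")) scn$name else NA_character_,
    attribution = attribution
  )
}

# shared by composite_fitness() and the GA fast path
breakdown_from_parts <- function(cvec, evec, A, active, weights, costs,
                                 omega, epsilon, max_drugs,
                                 scenario_name = NA_character_,
                                 attribution = "proportional") {
  mask <- cvec != 0
  gprime <- sum(mask)
  mae <- mean(abs(cvec[mask] - evec[mask]))
  waste <- waste_penalty(cvec, A)
  mis <- mismatch_penalty(cvec, A)
  ent <- entropy_penalty(cvec, A)
  n_omega <- rep_len(omega, gprime)
  cov <- coverage_reward(cvec, A, omega = omega)
  usage <- drug_usage(cvec, A, costs = costs, epsilon = epsilon)
  norm <- c(
    waste = waste / gprime, mismatch = mis / gprime,
    entropy = ent / gprime, count = usage$r_count / max_drugs,
    coverage = if (sum(n_omega) > 0) cov / sum(n_omega) else 0
  )
  j <- weights[["alpha"]] * mae +
    weights[["beta"]] * norm[["waste"]] +
    weights[["gamma"]] * norm[["mismatch"]] +
    weights[["eta"]] * norm[["entropy"]] +
    weights[["lambda_count"]] * norm[["count"]] +
    weights[["kappa"]] * usage$r_cost -
    weights[["tau"]] * norm[["coverage"]]
  structure(
    list(
      scenario = scenario_name, drugs = active,
      drug_count = length(active), attribution = attribution,
      mae = mae, r_waste = waste, r_mismatch = mis, r_entropy = ent,
      coverage = cov, r_count = usage$r_count, r_cost = usage$r_cost,
      phi = usage$phi, normalized = norm, composite_j = unname(j)
    ),
    class = "fitness_breakdown"
  )
}

#' @export
print.fitness_breakdown <- function(x, ...) {
  cat("<fitness_breakdown> {", paste(x$drugs, collapse = ", "), "}",
    if (!is.na(x$scenario)) paste0(" on ", x$scenario), "\n",
    sep = ""
  )
  cat(sprintf(
    "  MAE %.4f | waste %.4f | mismatch %.4f | entropy %.4f\n",
    x$mae, x$r_waste, x$r_mismatch, x$r_entropy
  ))
  cat(sprintf(
    "  coverage %.4f | count %d | cost %.3f  =>  J = %.4f\n",
    x$coverage, x$r_count, x$r_cost, x$composite_j
  ))
  invisible(x)
}

#' Tidiers for fitness breakdowns
#'
#' `tidy()` returns one row per fitness term (raw and normalized value);
#' `glance()` returns a one-row tibble with every term and the composite J.
#'
#' @param x A `fitness_breakdown` from [composite_fitness()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fitness_breakdown
#' @export
tidy.fitness_breakdown <- function(x, ...) {
  tibble::tibble(
    term = c("mae", "waste", "mismatch", "entropy", "coverage", "count", "cost"),
    raw = c(
      x$mae, x$r_waste, x$r_mismatch, x$r_entropy, x$coverage,
      x$r_count, x$r_cost
    ),
    normalized = c(
      x$mae, unname(x$normalized["waste"]), unname(x$normalized["mismatch"]),
      unname(x$normalized["entropy"]), unname(x$normalized["coverage"]),
      unname(x$normalized["count"]), x$r_cost
    )
  )
}

#' @rdname tidy.fitness_breakdown
#' @method glance fitness_breakdown
#' @export
glance.fitness_breakdown <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario,
    drugs = paste(x$drugs, collapse = "+"),
    drug_count = x$drug_count,
    mae = x$mae,
    r_waste = x$r_waste,
    r_mismatch = x$r_mismatch,
    r_entropy = x$r_entropy,
    coverage = x$coverage,
    r_count = x$r_count,
    r_cost = x$r_cost,
    composite_j = x$composite_j
  )
}
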