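# Shared fixture builders and independent oracles for the test suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# tiny effect matrix from a plain matrix with default names
tiny_effects <- function(w, genes = NULL, drugs = NULL) {
  w <- as.matrix(w)
  genes <- genes %||% sprintf("G%02d", seq_len(nrow(w)))
  drugs <- drugs %||% sprintf("d%02d", seq_len(ncol(w)))
  dimnames(w) <- list(genes, drugs)
  effect_matrix(w)
}

# random dense signed matrix (continuous weights, for property tests)
random_effects <- function(n_genes, n_drugs, seed) {
  set.seed(seed)
  w <- matrix(runif(n_genes * n_drugs, -1, 1), n_genes, n_drugs)
  w[runif(length(w)) < 0.3] <- 0
  tiny_effects(w)
}

# random scenario over a subset of a matrix's genes
random_scenario <- function(x, n_targets, seed, name = "rand") {
  set.seed(seed)
  genes <- sample(x$genes, n_targets)
  scenario(name, setNames(sample(c(-1, 1), n_targets, replace = TRUE), genes))
}

# Independent Shapley oracle: literal average of marginal contributions of
# the clipped-sum game over all n! orderings (no subset enumeration).
all_orderings <- function(v) {
  if (length(v) <= 1) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_orderings(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

shapley_ordering_oracle <- function(r) {
  n <- ncol(r)
  perms <- all_orderings(seq_len(n))
  phi <- matrix(0, nrow(r), n)
  for (ord in perms) {
    prev <- rep(0, nrow(r))
    run <- rep(0, nrow(r))
    for (k in seq_len(n)) {
      run <- run + r[, ord[k]]
      val <- pmin(1, pmax(-1, run))
      phi[, ord[k]] <- phi[, ord[k]] + (val - prev)
      prev <- val
    }
  }
  phi / length(perms)
}

# small GA settings (fine-search budget) used across tests
test_ga <- function(...) {
  ga_config(population_size = 60, iterations = 10, runs = 3, seed = 1, ...)
}
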