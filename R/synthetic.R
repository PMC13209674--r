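# Evidence-count representations for the bias grid used by the generators.
# Counts are capped at 9 per direction; regulation_bias() recovers each
# magnitude exactly: (3-0)/3 = 1, (9-1)/10 = 0.8, (4-1)/5 = 0.6,
# (3-1)/4 = 0.5, (2-1)/3 = 1/3.
bias_grid <- function() {
  tibble::tibble(
    magnitude = c(1, 0.8, 0.6, 0.5, 1 / 3),
    up = c(3L, 9L, 4L, 3L, 2L),
    down = c(0L, 1L, 1L, 1L, 1L)
  )
}

#' Specify a synthetic interaction fixture
#'
#' Describes a CTD-like synthetic dataset: a ground-truth signed effect
#' matrix whose cells sit on an evidence-representable bias grid, so that
#' an interaction file emitted from it round-trips through
#' [read_interactions()] + [build_effect_matrix()] back to the ground
#' truth cell-for-cell.
#'
#' @param n_genes,n_drugs Matrix dimensions.
#' @param density Fraction of drug-gene pairs with a directional effect.
#' @param conflict_rate Fraction of nonzero pairs given opposing reports
#'   (i.e. `|bias| < 1`), emulating conflicting evidence across studies.
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 8, n_drugs = 12, density = 0.5,
                         conflict_rate = 0.3, seed = 1) {
  stopifnot(
    n_genes >= 1, n_drugs >= 1,
    density > 0, density <= 1,
    conflict_rate >= 0, conflict_rate <= 1
  )
  structure(
    list(
      n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
      density = density, conflict_rate = conflict_rate,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Simulate a ground-truth effect matrix
#'
#' Draws a random signed effect matrix on the evidence-representable bias
#' grid (magnitudes 1, 0.8, 0.6, 0.5, 1/3): with probability
#' `conflict_rate` a nonzero pair gets a conflicted magnitude (< 1), else
#' a clean single-direction `|bias| = 1`.
#'
#' @param spec A [fixture_spec()].
#' @return An [effect_matrix()] with genes `G01...` and drugs `d01...`.
#' @export
simulate_effect_matrix <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  genes <- sprintf("G%02d", seq_len(spec$n_genes))
  drugs <- sprintf("d%02d", seq_len(spec$n_drugs))
  grid <- bias_grid()
  w <- matrix(0, spec$n_genes, spec$n_drugs, dimnames = list(genes, drugs))
  nonzero <- runif(length(w)) < spec$density
  n <- sum(nonzero)
  if (n > 0) {
    mag <- ifelse(
      runif(n) < spec$conflict_rate,
      sample(grid$magnitude[-1], n, replace = TRUE),
      1
    )
    w[nonzero] <- mag * sample(c(-1, 1), n, replace = TRUE)
  }
  effect_matrix(w)
}

evidence_for_bias <- function(bias) {
  grid <- bias_grid()
  i <- match(round(abs(bias), 10), round(grid$magnitude, 10))
  if (any(is.na(i))) abort("bias value off the representable grid")
  up <- ifelse(bias > 0, grid$up[i], grid$down[i])
  down <- ifelse(bias > 0, grid$down[i], grid$up[i])
  list(up = up, down = down)
}

#' Write a synthetic CTD-style interaction file
#'
#' Emits one delimited interaction file realizing a ground-truth effect
#' matrix: every nonzero cell becomes an up-report row and (for conflicted
#' cells) a down-report row with evidence counts chosen so that
#' [regulation_bias()] reproduces the cell exactly; all-zero drugs are
#' registered through non-directional rows. Optionally appends malformed
#' rows (missing gene) to exercise the parser's skip rule.
#'
#' @param spec A [fixture_spec()], or an [effect_matrix()] to realize
#'   directly (its cells must sit on the representable bias grid).
#' @param path Output path (TSV with default CTD-style column names).
#' @param malformed Number of malformed rows to append.
#' @param taxonomy A [direction_taxonomy()] supplying the labels to draw.
#' @return List with `path`, `truth` (the ground-truth [effect_matrix()])
#'   and `n_rows` (data rows written, malformed included).
#' @export
generate_interaction_file <- function(spec, path, malformed = 0,
                                      taxonomy = direction_taxonomy()) {
  truth <- if (inherits(spec, "effect_matrix")) spec else simulate_effect_matrix(spec)
  if (inherits(spec, "fixture_spec")) set.seed(spec$seed + 1L)
  long <- tidy(truth, keep_zero = TRUE)
  nz <- dplyr::filter(long, .data$weight != 0)
  rows <- list()
  if (nrow(nz) > 0) {
    ev <- evidence_for_bias(nz$weight)
    up_rows <- tibble::tibble(
      ChemicalName = nz$drug_id, GeneSymbol = nz$gene_symbol,
      InteractionActions = sample(taxonomy$up_labels, nrow(nz), replace = TRUE),
      `PubMedIDs-count` = ev$up
    )
    down_rows <- tibble::tibble(
      ChemicalName = nz$drug_id, GeneSymbol = nz$gene_symbol,
      InteractionActions = sample(taxonomy$down_labels, nrow(nz), replace = TRUE),
      `PubMedIDs-count` = ev$down
    )
    rows <- list(
      up_rows[ev$up > 0, ], down_rows[ev$down > 0, ]
    )
  }
  # all-zero drugs still appear in the file via non-directional actions
  zero_drugs <- truth$drugs[colSums(truth$weights != 0) == 0]
  if (length(zero_drugs) > 0) {
    rows <- c(rows, list(tibble::tibble(
      ChemicalName = zero_drugs,
      GeneSymbol = truth$genes[1],
      InteractionActions = "affects^binding",
      `PubMedIDs-count` = 1L
    )))
  }
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) abort("fixture has no interactions to write")
  if (malformed > 0) {
    tab <- dplyr::bind_rows(tab, tibble::tibble(
      ChemicalName = sprintf("broken%02d", seq_len(malformed)),
      GeneSymbol = "",
      InteractionActions = "increases^expression",
      `PubMedIDs-count` = 1L
    ))
  }
  readr::write_tsv(tab, path, progress = FALSE)
  list(path = path, truth = truth, n_rows = nrow(tab))
}

#' Generate a planted-optimum benchmark
#'
#' Builds a scenario plus a drug library in which a known combination of
#' `planted_size` drugs reproduces the counteraction vector exactly
#' (MAE 0), surrounded by decoys that each fail somewhere: null players
#' (no effect on any gene), opposing drugs (push one scenario gene the
#' wrong way) and partial drugs (cover some genes but oppose another).
#' Uniqueness of the optimum is certified at generation time by exhaustive
#' enumeration of all combinations up to `max_drugs`; seeds are retried
#' until certification succeeds.
#'
#' @param n_genes Number of scenario genes.
#' @param planted_size Size of the planted optimal combination.
#' @param n_null,n_opposing,n_partial Decoy counts by type.
#' @param max_drugs Enumeration ceiling for the uniqueness certificate
#'   (default: the planted size).
#' @param seed Integer seed.
#' @param retries Seeds to try before giving up.
#' @return List with `scenario`, `effects` (the library as an
#'   [effect_matrix()]), `planted` (drug ids of the optimum) and
#'   `enumeration` (tibble of all enumerated sets with their MAE).
#' @export
plant_scenario <- function(n_genes = 6, planted_size = 2, n_null = 2,
                           n_opposing = 3, n_partial = 3,
                           max_drugs = planted_size, seed = 1, retries = 20) {
  stopifnot(
    n_genes >= planted_size, planted_size >= 1,
    max_drugs >= planted_size
  )
  for (attempt in seq_len(retries)) {
    set.seed(seed + attempt - 1L)
    out <- build_planted(n_genes, planted_size, n_null, n_opposing, n_partial)
    enum <- enumerate_mae(out$effects, out$scenario, max_drugs)
    zero <- enum$mae < 1e-12
    if (sum(zero) == 1 &&
      identical(enum$drugs[[which(zero)]], sort(out$planted))) {
      out$enumeration <- enum
      return(out)
    }
  }
  abort("could not certify a unique planted optimum within the retry budget")
}

build_planted <- function(n_genes, planted_size, n_null, n_opposing,
                          n_partial) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  cdir <- sample(c(-1, 1), n_genes, replace = TRUE)
  scn <- scenario("planted", setNames(cdir, genes))
  # partition scenario genes across the planted drugs
  blocks <- split(seq_len(n_genes), sort(rep_len(seq_len(planted_size), n_genes)))
  n_total <- planted_size + n_null + n_opposing + n_partial
  drugs <- sprintf("d%02d", seq_len(n_total))
  w <- matrix(0, n_genes, n_total, dimnames = list(genes, drugs))
  for (k in seq_len(planted_size)) {
    w[blocks[[k]], k] <- cdir[blocks[[k]]]
  }
  col <- planted_size
  for (i in seq_len(n_null)) {
    col <- col + 1 # all-zero column
  }
  for (i in seq_len(n_opposing)) {
    col <- col + 1
    g <- sample.int(n_genes, 1)
    w[g, col] <- -cdir[g]
  }
  for (i in seq_len(n_partial)) {
    col <- col + 1
    good <- sample.int(n_genes, max(1, n_genes %/% 3))
    bad <- sample(setdiff(seq_len(n_genes), good), 1)
    w[good, col] <- cdir[good]
    w[bad, col] <- -cdir[bad]
  }
  list(
    scenario = scn, effects = effect_matrix(w),
    planted = drugs[seq_len(planted_size)]
  )
}

#' Exhaustively score all combinations up to a size limit
#'
#' Brute-force enumeration oracle: evaluates every drug subset of size
#' 1..`max_drugs` and returns its MAE and composite J. Used to certify
#' planted optima and to benchmark the GA against the true optimum on
#' small libraries.
#'
#' @param x An [effect_matrix()].
#' @param scn A [scenario()].
#' @param max_drugs Largest subset size to enumerate.
#' @param weights A [fitness_weights()] for the J column.
#' @param costs Optional named cost vector.
#' @return Tibble with `drugs` (list), `drug_set`, `drug_count`, `mae`,
#'   `composite_j`, sorted by `composite_j`.
#' @export
enumerate_mae <- function(x, scn, max_drugs = 3,
                          weights = fitness_weights(), costs = NULL) {
  stopifnot(inherits(x, "effect_matrix"))
  ev <- make_evaluator(x, scn, weights, costs = costs, kslots = max_drugs)
  sets <- purrr::list_flatten(purrr::map(
    seq_len(min(max_drugs, ev$n_drugs)),
    function(k) {
      m <- combn(ev$n_drugs, k)
      purrr::map(seq_len(ncol(m)), function(i) m[, i])
    }
  ))
  rows <- purrr::map_dfr(sets, function(idx) {
    terms <- ev$eval_set(idx)
    tibble::tibble(
      drugs = list(ev$drugs[idx]),
      drug_set = paste(ev$drugs[idx], collapse = "+"),
      drug_count = length(idx),
      mae = terms[["mae"]],
      composite_j = terms[["composite_j"]]
    )
  })
  dplyr::arrange(rows, .data$composite_j, .data$mae, .data$drug_set)
}
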