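#' Read CTD-style drug-gene interaction records
#'
#' Parses a delimited interaction table (one row per reported interaction)
#' into a tidy record tibble. Rows with a missing drug id, gene symbol or
#' action label are skipped and counted; the skip count is reported via a
#' message and attached as an attribute.
#'
#' @param path Path to a tab- or comma-delimited file with a header row.
#' @param drug_col,gene_col,action_col,evidence_col Column names holding the
#'   chemical identifier, gene symbol, direction-of-effect action label and
#'   (optionally) the supporting-reference count. If `evidence_col` is
#'   missing from the file every row counts as one report.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A tibble with columns `drug_id` (lowercased), `gene_symbol`
#'   (uppercased, trimmed), `action_label`, `evidence_count` (integer >= 1),
#'   with attribute `skipped` = number of dropped rows.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "ChemicalName\tGeneSymbol\tInteractionActions\tPubMedIDs-count",
#'   "aspirin\tEGFR\tdecreases^expression\t3"
#' ), tf)
#' read_interactions(tf)
#' @export
read_interactions <- function(path,
                              drug_col = "ChemicalName",
                              gene_col = "GeneSymbol",
                              action_col = "InteractionActions",
                              evidence_col = "PubMedIDs-count",
                              delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("interaction file not found: ", path))
  }
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE
  )
  needed <- c(drug_col, gene_col, action_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "interaction file lacks required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  ev <- if (evidence_col %in% names(raw)) {
    suppressWarnings(as.integer(raw[[evidence_col]]))
  } else {
    rep(NA_integer_, nrow(raw))
  }
  rec <- tibble::tibble(
    drug_id = tolower(trimws(raw[[drug_col]])),
    gene_symbol = toupper(trimws(raw[[gene_col]])),
    action_label = trimws(raw[[action_col]]),
    evidence_count = ev
  )
  ok <- !is.na(rec$drug_id) & rec$drug_id != "" &
    !is.na(rec$gene_symbol) & rec$gene_symbol != "" &
    !is.na(rec$action_label) & rec$action_label != ""
  skipped <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  # absent or unusable evidence counts default to one report per row
  rec$evidence_count <- pmax(1L, dplyr::coalesce(rec$evidence_count, 1L))
  if (nrow(rec) == 0) {
    abort(paste0("no parsable interaction rows in ", path))
  }
  if (skipped > 0) {
    inform(paste0(
      "read_interactions: skipped ", skipped,
      " row(s) with missing drug/gene/action fields"
    ))
  }
  attr(rec, "skipped") <- skipped
  rec
}

#' Net reported regulation direction for one drug-gene pair
#'
#' Conflicting reports for the same drug-gene pair (some saying the drug
#' raises the gene product, others that it lowers it) are resolved into a
#' single signed weight, the *regulation bias*
#' \deqn{b = (U - V) / (U + V),}
#' where `U` and `V` are the evidence counts supporting up- and
#' downregulation. The bias is bounded in \[-1, 1\], sign-preserving and
#' antisymmetric in its two arguments. Pairs with too little total evidence
#' (`U + V < min_evidence`) or too balanced a conflict
#' (`|b| < ambiguity_threshold`) are conservatively zeroed.
#'
#' @param up_evidence,down_evidence Non-negative evidence totals per
#'   direction (vectorized).
#' @param min_evidence Minimum total directional evidence to retain a pair.
#' @param ambiguity_threshold Minimum `|bias|` to retain a pair; conflicts
#'   more balanced than this are dropped as ambiguous.
#' @return Numeric vector of signed weights in \[-1, 1\].
#' @examples
#' regulation_bias(3, 0) # +1
#' regulation_bias(2, 2) # 0: perfectly conflicting
#' regulation_bias(3, 1) # +0.5
#' @export
regulation_bias <- function(up_evidence, down_evidence,
                            min_evidence = 1, ambiguity_threshold = 0.2) {
  stopifnot(
    all(up_evidence >= 0), all(down_evidence >= 0),
    min_evidence >= 0, ambiguity_threshold >= 0, ambiguity_threshold <= 1
  )
  total <- up_evidence + down_evidence
  bias <- ifelse(total > 0, (up_evidence - down_evidence) / total, 0)
  bias[total < min_evidence | abs(bias) < ambiguity_threshold] <- 0
  bias
}

#' Construct an effect matrix
#'
#' Low-level constructor for the signed gene-by-drug weight matrix
#' \eqn{r_{g,j}} of per-drug regulation effects.
#'
#' @param weights Numeric matrix, genes as rows, drugs as columns, entries
#'   in \[-1, 1\].
#' @param genes,drugs Optional character vectors naming rows/columns;
#'   default taken from `dimnames(weights)`.
#' @return An `effect_matrix` object.
#' @export
effect_matrix <- function(weights, genes = rownames(weights),
                          drugs = colnames(weights)) {
  weights <- as.matrix(weights)
  if (is.null(genes) || is.null(drugs)) {
    abort("effect_matrix needs gene and drug names")
  }
  genes <- as.character(genes)
  drugs <- as.character(drugs)
  if (anyDuplicated(genes)) abort("duplicate gene symbols in effect matrix")
  if (anyDuplicated(drugs)) abort("duplicate drug ids in effect matrix")
  stopifnot(
    nrow(weights) == length(genes), ncol(weights) == length(drugs),
    all(is.finite(weights)), all(abs(weights) <= 1 + 1e-12)
  )
  dimnames(weights) <- list(genes, drugs)
  structure(
    list(weights = weights, genes = genes, drugs = drugs),
    class = "effect_matrix"
  )
}

#' Build the signed drug-gene effect matrix from interaction records
#'
#' Classifies each record's action label, sums evidence per direction for
#' every observed drug-gene pair, and resolves each pair with
#' [regulation_bias()]. The result is the dense matrix of signed weights
#' \eqn{r_{g,j}} over the union of observed genes and drugs; a cell is zero
#' exactly when the pair has no retained directional evidence.
#'
#' @param records Record tibble as returned by [read_interactions()] (needs
#'   columns `drug_id`, `gene_symbol`, `action_label`, `evidence_count`).
#' @param taxonomy A [direction_taxonomy()].
#' @inheritParams regulation_bias
#' @param prune If `TRUE`, drop genes and drugs whose entire row/column is
#'   zero after conflict resolution.
#' @return An [effect_matrix()].
#' @export
build_effect_matrix <- function(records, taxonomy = direction_taxonomy(),
                                min_evidence = 1, ambiguity_threshold = 0.2,
                                prune = FALSE) {
  stopifnot(nrow(records) >= 1)
  dir <- classify_direction(records$action_label, taxonomy)
  ev <- records$evidence_count %||% rep(1L, nrow(records))
  tab <- tibble::tibble(
    drug_id = tolower(records$drug_id),
    gene_symbol = toupper(records$gene_symbol),
    up = ifelse(dir > 0, ev, 0),
    down = ifelse(dir < 0, ev, 0)
  ) |>
    dplyr::summarise(
      up = sum(.data$up), down = sum(.data$down),
      .by = c("gene_symbol", "drug_id")
    ) |>
    dplyr::mutate(bias = regulation_bias(
      .data$up, .data$down,
      min_evidence = min_evidence, ambiguity_threshold = ambiguity_threshold
    ))
  genes <- sort(unique(tab$gene_symbol))
  drugs <- sort(unique(tab$drug_id))
  w <- matrix(0, length(genes), length(drugs), dimnames = list(genes, drugs))
  w[cbind(
    match(tab$gene_symbol, genes),
    match(tab$drug_id, drugs)
  )] <- tab$bias
  if (prune) {
    keep_g <- rowSums(w != 0) > 0
    keep_d <- colSums(w != 0) > 0
    if (!any(keep_g) || !any(keep_d)) {
      abort("pruning removed every gene or drug (no directional evidence)")
    }
    w <- w[keep_g, keep_d, drop = FALSE]
  }
  effect_matrix(w)
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat(
    "<effect_matrix> ", length(x$genes), " genes x ", length(x$drugs),
    " drugs; ", sum(x$weights != 0), " nonzero effects\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as.matrix.effect_matrix <- function(x, ...) x$weights

#' @export
dim.effect_matrix <- function(x) dim(x$weights)

#' Tidy an effect matrix into long format
#'
#' @param x An [effect_matrix()].
#' @param keep_zero Keep cells with zero weight? Default drops them.
#' @param ... Unused.
#' @return Tibble with columns `gene_symbol`, `drug_id`, `weight`.
#' @method tidy effect_matrix
#' @export
tidy.effect_matrix <- function(x, keep_zero = FALSE, ...) {
  out <- tibble::as_tibble(as.table(x$weights), .name_repair = "minimal")
  names(out) <- c("gene_symbol", "drug_id", "weight")
  if (!keep_zero) out <- dplyr::filter(out, .data$weight != 0)
  out
}

#' Restrict an effect matrix to given genes and/or drugs
#'
#' @param x An [effect_matrix()].
#' @param genes,drugs Character vectors to keep (order respected);
#'   `NULL` keeps all.
#' @return A smaller [effect_matrix()].
#' @export
subset_effects <- function(x, genes = NULL, drugs = NULL) {
  stopifnot(inherits(x, "effect_matrix"))
  genes <- genes %||% x$genes
  drugs <- drugs %||% x$drugs
  bad_g <- setdiff(genes, x$genes)
  bad_d <- setdiff(drugs, x$drugs)
  if (length(bad_g)) abort(paste0("unknown gene(s): ", paste(bad_g, collapse = ", ")))
  if (length(bad_d)) abort(paste0("unknown drug(s): ", paste(bad_d, collapse = ", ")))
  effect_matrix(x$weights[genes, drugs, drop = FALSE])
}

#' Write / read an effect matrix as delimited text
#'
#' The matrix is stored genes-as-rows, drugs-as-columns with a `gene` key
#' column; a JSON sidecar (`<path>.json`) records the taxonomy and
#' thresholds used to build it, for provenance.
#'
#' @param x An [effect_matrix()].
#' @param path Output path for the matrix TSV.
#' @param taxonomy,min_evidence,ambiguity_threshold Provenance recorded in
#'   the sidecar.
#' @return `path`, invisibly.
#' @export
write_effect_matrix <- function(x, path, taxonomy = direction_taxonomy(),
                                min_evidence = 1, ambiguity_threshold = 0.2) {
  stopifnot(inherits(x, "effect_matrix"))
  out <- tibble::as_tibble(x$weights, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(gene = x$genes), out)
  readr::write_tsv(out, path, progress = FALSE)
  side <- list(
    up_labels = taxonomy$up_labels,
    down_labels = taxonomy$down_labels,
    min_evidence = min_evidence,
    ambiguity_threshold = ambiguity_threshold
  )
  jsonlite::write_json(side, paste0(path, ".json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_effect_matrix
#' @export
read_effect_matrix <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  w <- as.matrix(tab[, -1, drop = FALSE])
  rownames(w) <- tab$gene
  effect_matrix(w)
}
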