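#' Define a counteraction scenario
#'
#' A scenario is a small disease module: a set of genes together with the
#' desired direction of therapeutic change for each, `-1` to suppress an
#' activated oncogenic signal and `+1` to restore a depleted protective
#' function. Magnitudes are always exactly 1.
#'
#' @param name Scenario name.
#' @param targets Named numeric vector, gene symbol -> direction in
#'   `c(-1, 1)`. Names are uppercased.
#' @return A `scenario` object.
#' @examples
#' scenario("demo", c(EGFR = -1, PTEN = 1))
#' @export
scenario <- function(name, targets) {
  if (length(targets) < 1) abort("scenario needs at least one target gene")
  genes <- toupper(trimws(names(targets)))
  if (is.null(names(targets)) || any(genes == "")) {
    abort("targets must be a named vector (gene symbol -> direction)")
  }
  if (anyDuplicated(genes)) {
    abort(paste0(
      "duplicate gene(s) in scenario '", name, "': ",
      paste(unique(genes[duplicated(genes)]), collapse = ", ")
    ))
  }
  dir <- as.numeric(targets)
  if (!all(dir %in% c(-1, 1))) {
    abort("scenario directions must be exactly -1 or +1")
  }
  structure(
    list(name = as.character(name), targets = setNames(dir, genes)),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$name, ": ", length(x$targets), " gene(s)\n", sep = "")
  up <- names(x$targets)[x$targets > 0]
  dn <- names(x$targets)[x$targets < 0]
  if (length(dn)) cat("  suppress (-1): ", paste(dn, collapse = ", "), "\n", sep = "")
  if (length(up)) cat("  restore  (+1): ", paste(up, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy scenario
#' @export
tidy.scenario <- function(x, ...) {
  tibble::tibble(
    scenario = x$name,
    gene_symbol = names(x$targets),
    direction = unname(x$targets)
  )
}

#' The ten packaged LUAD driver scenarios
#'
#' Ten literature-derived lung adenocarcinoma driver modules, each encoding
#' a set of dysregulated genes and the desired direction of counteraction:
#' suppression (`-1`) of activated oncogenic signaling or restoration
#' (`+1`) of depleted tumor-suppressive function. The modules cover RTK
#' activation, EGFR exon-20 insertions, KRAS-MAPK, STK11/KEAP1
#' co-alteration, BRAF-MAPK, PI3K/AKT/mTOR, ERBB3-NRG1, DNA-damage-response
#' dysfunction with ATR dependency, RET/NTRK fusions and SMARCA4-deficient
#' LUAD; together they span 44 distinct genes. Genes shared between
#' scenarios always carry the same direction, so the modules can be merged
#' with [union_scenario()] into a single coarse-search scenario.
#'
#' @return Named list of 10 [scenario()] objects (`"scenario_01"` ...
#'   `"scenario_10"`).
#' @examples
#' scns <- luad_scenarios()
#' scns$scenario_04
#' length(union_scenario(scns)$targets) # 44 genes
#' @export
luad_scenarios <- function() {
  defs <- list(
    scenario_01 = list(
      # suppress activated RTK signaling
      c(EGFR = -1, ERBB2 = -1, MET = -1, ALK = -1, ROS1 = -1)
    ),
    scenario_02 = list(
      # suppress ERBB signaling in EGFR exon-20-driven tumors
      c(EGFR = -1, ERBB2 = -1, ERBB3 = -1)
    ),
    scenario_03 = list(
      # suppress KRAS-MAPK signaling
      c(
        KRAS = -1, PTPN11 = -1, SOS1 = -1, MAP2K1 = -1, MAP2K2 = -1,
        MAPK1 = -1, MAPK3 = -1
      )
    ),
    scenario_04 = list(
      # restore STK11/AMPK and KEAP1; suppress NRF2/GLS adaptation
      c(
        STK11 = 1, PRKAA1 = 1, PRKAA2 = 1, KEAP1 = 1, NFE2L2 = -1,
        GLS = -1
      )
    ),
    scenario_05 = list(
      # suppress BRAF-MAPK signaling
      c(BRAF = -1, MAP2K1 = -1, MAP2K2 = -1, MAPK1 = -1, MAPK3 = -1)
    ),
    scenario_06 = list(
      # suppress PI3K/AKT/mTOR; restore PTEN
      c(
        PIK3CA = -1, AKT1 = -1, AKT2 = -1, AKT3 = -1, MTOR = -1,
        RPS6KB1 = -1, PTEN = 1
      )
    ),
    scenario_07 = list(
      # suppress HER3-centered escape signaling
      c(ERBB3 = -1, ERBB2 = -1, NRG1 = -1, PIK3CA = -1)
    ),
    scenario_08 = list(
      # suppress checkpoint rescue; restore major DDR functions
      c(
        ATR = -1, CHEK1 = -1, WEE1 = -1, PARP1 = -1, ATM = 1,
        BRCA1 = 1, BRCA2 = 1
      )
    ),
    scenario_09 = list(
      # suppress fusion-driven kinase signaling
      c(
        RET = -1, NTRK1 = -1, NTRK2 = -1, NTRK3 = -1, MAP2K1 = -1,
        MAP2K2 = -1
      )
    ),
    scenario_10 = list(
      # restore SMARCA4-related function; suppress compensatory dependencies
      c(SMARCA4 = 1, SMARCA2 = -1, EZH2 = -1, CDK4 = -1, CDK6 = -1)
    )
  )
  purrr::imap(defs, function(d, nm) scenario(nm, d[[1]]))
}

#' Merge scenarios into a single coarse-search scenario
#'
#' Unions the target gene sets of several scenarios, preserving each gene's
#' direction. Used to build the unified coarse-search module ("scenario 11")
#' run in the first screening cycle. Genes carried by more than one input
#' scenario must agree in direction; a conflict is a fatal consistency
#' error naming the gene.
#'
#' @param scenarios A list of [scenario()] objects (or a single scenario).
#' @param name Name for the merged scenario.
#' @return A [scenario()] over the union of all target genes.
#' @export
union_scenario <- function(scenarios, name = "scenario_union") {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1)
  tab <- purrr::map_dfr(scenarios, tidy)
  agg <- dplyr::summarise(tab,
    n_dir = dplyr::n_distinct(.data$direction),
    direction = .data$direction[1],
    .by = "gene_symbol"
  )
  bad <- agg$gene_symbol[agg$n_dir > 1]
  if (length(bad) > 0) {
    abort(paste0(
      "conflicting desired direction across scenarios for gene(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  scenario(name, setNames(agg$direction, agg$gene_symbol))
}

#' Expand a scenario into a counteraction vector over a gene universe
#'
#' @param scn A [scenario()].
#' @param genes Ordered gene universe (typically `effects$genes`). Scenario
#'   genes absent from the universe are dropped with a warning.
#' @return Named numeric vector `c_g` over `genes`: the desired direction at
#'   scenario genes, 0 elsewhere.
#' @export
vectorize_scenario <- function(scn, genes) {
  stopifnot(inherits(scn, "scenario"), length(genes) >= 1)
  genes <- as.character(genes)
  cvec <- setNames(numeric(length(genes)), genes)
  hit <- intersect(names(scn$targets), genes)
  if (length(hit) == 0) {
    abort(paste0(
      "scenario '", scn$name, "' shares no genes with the gene universe"
    ))
  }
  missing <- setdiff(names(scn$targets), genes)
  if (length(missing) > 0) {
    warn(paste0(
      "scenario '", scn$name, "': gene(s) absent from universe dropped: ",
      paste(missing, collapse = ", ")
    ))
  }
  cvec[hit] <- scn$targets[hit]
  cvec
}

#' Read scenarios from a YAML or JSON file
#'
#' Expected layout: a mapping of scenario name to a gene -> direction
#' mapping, e.g. `{"rtk": {"EGFR": -1, "MET": -1}}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of [scenario()] objects.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) abort(paste0("scenario file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw) || is.null(names(raw)) || length(raw) == 0) {
    abort("scenario file must map scenario names to {gene: direction} tables")
  }
  purrr::imap(raw, function(tgts, nm) scenario(nm, unlist(tgts)))
}
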