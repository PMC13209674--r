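#' Hierarchically cluster genes and drugs by regulation effect
#'
#' Agglomerative clustering of the signed effect matrix along both axes,
#' for heatmap ordering and redundancy inspection (drugs with near-identical
#' regulation profiles merge early). Rows and columns are sorted by label
#' before distances are computed so the result is invariant to input order.
#'
#' @param x An [effect_matrix()] (restrict with [subset_effects()] first if
#'   needed).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param metric Distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @return An `effect_clustering`: list with `gene_order`, `drug_order`
#'   (leaf-ordered labels), `gene_hclust`, `drug_hclust` (dendrograms;
#'   `NULL` for degenerate single-row/column input) and `weights` (the
#'   matrix reordered to the leaf orders).
#' @export
cluster_effects <- function(x, linkage = "average", metric = "euclidean") {
  stopifnot(inherits(x, "effect_matrix"))
  w <- x$weights[
    order(x$genes), order(x$drugs),
    drop = FALSE
  ]
  cluster_axis <- function(m) {
    if (nrow(m) < 2) {
      return(list(order = rownames(m), hc = NULL))
    }
    hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
    list(order = rownames(m)[hc$order], hc = hc)
  }
  g <- cluster_axis(w)
  d <- cluster_axis(t(w))
  structure(
    list(
      gene_order = g$order, drug_order = d$order,
      gene_hclust = g$hc, drug_hclust = d$hc,
      weights = w[g$order, d$order, drop = FALSE]
    ),
    class = "effect_clustering"
  )
}

#' @export
print.effect_clustering <- function(x, ...) {
  cat(
    "<effect_clustering> ", length(x$gene_order), " genes x ",
    length(x$drug_order), " drugs\n",
    sep = ""
  )
  invisible(x)
}

#' Cut a clustering at its largest merge gap
#'
#' Utility for recovering block structure: cuts the dendrogram where the
#' merge-height increase is largest, yielding the "natural" partition.
#'
#' @param hc An `hclust` object.
#' @return Named integer vector of cluster memberships.
#' @export
cut_largest_gap <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  h <- sort(hc$height)
  if (length(h) == 1) {
    return(stats::cutree(hc, k = 2))
  }
  gaps <- diff(c(0, h))
  # cutting just below merge i leaves n_leaves - (i - 1) clusters
  k <- length(h) + 2L - which.max(gaps)
  stats::cutree(hc, k = k)
}

#' Group interchangeable drug alternatives per gene cluster
#'
#' Builds the grouped-alternatives table: scenario genes are partitioned by
#' their coverage pattern (which of the candidate drugs support them in the
#' desired direction), and each candidate drug is listed under every gene
#' cluster it fully supports. Two drugs with identical sign patterns over
#' the scenario genes land in the same groups, exposing interchangeable
#' candidates. Groups are lettered A, B, C, ... by decreasing gene-cluster
#' size, ties broken alphabetically by first gene.
#'
#' @param x An [effect_matrix()].
#' @param scn A [scenario()].
#' @param drugs Candidate drug ids (e.g. drugs appearing in Pareto
#'   solutions for the scenario).
#' @param tolerance Minimum `|effect|` for a drug to count as supporting a
#'   gene.
#' @return Tibble with columns `scenario`, `reg` (`"Down"`/`"Up"`),
#'   `gene_cluster`, `drug_alternatives`, `group`. Groups mixing both
#'   directions produce one row per direction, sharing the group letter.
#' @export
group_alternatives <- function(x, scn, drugs, tolerance = 0) {
  stopifnot(inherits(x, "effect_matrix"), inherits(scn, "scenario"))
  drugs <- sort(unique(tolower(drugs)))
  unknown <- setdiff(drugs, x$drugs)
  if (length(unknown)) {
    abort(paste0("unknown drug id(s): ", paste(unknown, collapse = ", ")))
  }
  genes <- sort(intersect(names(scn$targets), x$genes))
  if (length(genes) == 0) abort("scenario shares no genes with the matrix")
  w <- x$weights[genes, drugs, drop = FALSE]
  cdir <- scn$targets[genes]
  # support[g, d]: drug pushes gene in the desired direction, above tolerance
  support <- (sign(w) == sign(cdir)) & (abs(w) > tolerance)
  pattern <- apply(support, 1, paste, collapse = "")
  clusters <- split(genes, pattern)
  ord <- order(-lengths(clusters), purrr::map_chr(clusters, 1))
  clusters <- clusters[ord]
  purrr::imap_dfr(clusters, function(members, pat) {
    covered <- colSums(!support[members, , drop = FALSE]) == 0
    alt <- drugs[covered]
    grp <- LETTERS[match(pat, names(clusters))]
    dirs <- split(members, ifelse(cdir[members] < 0, "Down", "Up"))
    purrr::imap_dfr(dirs, function(gg, reg) {
      tibble::tibble(
        scenario = scn$name,
        reg = reg,
        gene_cluster = paste(sort(gg), collapse = ", "),
        drug_alternatives = paste(alt, collapse = ", "),
        group = grp
      )
    })
  })
}
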