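#' Direction-of-effect label taxonomy
#'
#' CTD-style interaction records carry action labels such as
#' `"increases^expression"`. Only some of these labels say something about
#' the direction in which a chemical pushes a gene product; the taxonomy
#' splits those into an upregulation set and a downregulation set. Labels in
#' neither set (e.g. `"affects^binding"`) are non-directional and ignored.
#'
#' The defaults are the ten labels used throughout the package:
#' upregulation is increased expression/stability/abundance or decreased
#' degradation/ubiquitination; downregulation is the mirror image. Note that
#' *increasing* ubiquitination or degradation lowers protein abundance and
#' therefore counts as downregulation.
#'
#' @param up_labels Character vector of labels treated as upregulation.
#' @param down_labels Character vector of labels treated as downregulation.
#' @return An object of class `direction_taxonomy`: a list with elements
#'   `up_labels` and `down_labels`.
#' @examples
#' tax <- direction_taxonomy()
#' classify_direction("increases^expression", tax)
#' classify_direction("increases^ubiquitination", tax)
#' @export
direction_taxonomy <- function(up_labels = c(
                                 "increases^expression",
                                 "increases^stability",
                                 "increases^abundance",
                                 "decreases^degradation",
                                 "decreases^ubiquitination"
                               ),
                               down_labels = c(
                                 "decreases^expression",
                                 "decreases^stability",
                                 "increases^degradation",
                                 "decreases^abundance",
                                 "increases^ubiquitination"
                               )) {
  up_labels <- unique(as.character(up_labels))
  down_labels <- unique(as.character(down_labels))
  clash <- intersect(up_labels, down_labels)
  if (length(clash) > 0) {
    abort(paste0(
      "up_labels and down_labels must be disjoint; shared: ",
      paste(clash, collapse = ", ")
    ))
  }
  structure(
    list(up_labels = up_labels, down_labels = down_labels),
    class = "direction_taxonomy"
  )
}

#' @export
print.direction_taxonomy <- function(x, ...) {
  cat("<direction_taxonomy>\n")
  cat("  up   (", length(x$up_labels), "): ",
    paste(x$up_labels, collapse = ", "), "\n",
    sep = ""
  )
  cat("  down (", length(x$down_labels), "): ",
    paste(x$down_labels, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Classify an action label as up, down, or non-directional
#'
#' @param action_label Character vector of action labels.
#' @param taxonomy A [direction_taxonomy()].
#' @return Integer vector: `+1` for upregulation labels, `-1` for
#'   downregulation labels, `0` otherwise. Unknown labels are not an error:
#'   interaction databases carry many non-directional action types.
#' @export
classify_direction <- function(action_label, taxonomy = direction_taxonomy()) {
  stopifnot(inherits(taxonomy, "direction_taxonomy"))
  out <- integer(length(action_label))
  out[action_label %in% taxonomy$up_labels] <- 1L
  out[action_label %in% taxonomy$down_labels] <- -1L
  out
}
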