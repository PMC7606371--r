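#' Quality rating levels
#'
#' Three-level quality rating used at every level of the hierarchy (slice,
#' volume, subject), ordered by artifact severity: `pass` (no or minor
#' artifacts) < `questionable` (moderate artifacts) < `fail` (heavy
#' artifacts).
#'
#' @return Character vector `c("pass", "questionable", "fail")`, in severity
#'   order.
#' @export
#' @examples
#' quality_levels()
quality_levels <- function() c("pass", "questionable", "fail")

#' Coerce to an ordered quality factor
#'
#' @param x Character vector (or factor) of quality ratings. `NA` is kept.
#' @return An ordered factor with levels `pass < questionable < fail`.
#' @export
#' @examples
#' quality_factor(c("fail", "pass")) > "questionable"
quality_factor <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% quality_levels()
  if (any(bad)) {
    abort(paste0("invalid quality label(s): ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  factor(x, levels = quality_levels(), ordered = TRUE)
}

# integer codes 1/2/3 used for class indexing in losses and networks
label_to_class <- function(x) {
  match(as.character(x), quality_levels())
}

class_to_label <- function(i) {
  quality_levels()[i]
}

#' Provenance states for labels
#'
#' Where a record's current label came from: `given` (expert annotation),
#' `inherited` (slice label copied from its volume's annotation — the weak
#' labeling that introduces label noise), `pseudo` (confident model
#' prediction adopted during semi-supervised learning), `relabeled`
#' (replaced by a high-confidence prediction during self-training), or
#' `removed` (excluded from training by self-training).
#'
#' @return Character vector of the five provenance states.
#' @export
provenance_levels <- function() {
  c("given", "inherited", "pseudo", "relabeled", "removed")
}
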