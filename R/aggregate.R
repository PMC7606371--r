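#' Initial volume label from its slice labels
#'
#' Decision rule used to seed volume-wise training from slice ratings,
#' evaluated in order:
#' 1. `pass` if strictly more than 60% of the slices are `pass`;
#' 2. `fail` if more slices are `fail` than `pass` and `questionable`;
#' 3. `questionable` otherwise.
#'
#' Rule 2 is ambiguous in natural language; by default `fail` must strictly
#' exceed *each* of the other two counts (`rule2 = "each"`). Set
#' `rule2 = "sum"` to require it to exceed their combined count instead
#' (kept for sensitivity analysis).
#'
#' @param labels Character vector (or factor) of slice quality labels.
#' @param rule2 `"each"` (default) or `"sum"`; see Description.
#' @return A single quality label string.
#' @export
#' @examples
#' init_volume_label(rep(c("pass", "fail"), c(37, 23)))   # 61.7% > 60%
init_volume_label <- function(labels, rule2 = c("each", "sum")) {
  rule2 <- match.arg(rule2)
  labels <- as.character(labels)
  if (length(labels) == 0) abort("empty slice label list")
  if (anyNA(labels)) abort("missing slice label")
  n <- length(labels)
  np <- sum(labels == "pass")
  nq <- sum(labels == "questionable")
  nf <- sum(labels == "fail")
  if (np + nq + nf != n) abort("invalid slice label")
  if (np > 0.6 * n) return("pass")
  fail_fires <- if (rule2 == "each") nf > np && nf > nq else nf > np + nq
  if (fail_fires) return("fail")
  "questionable"
}

#' Subject label from its volume labels
#'
#' Decision rule applied to the volume ratings of one subject, evaluated in
#' order with strict inequalities:
#' 1. `pass` if more than 80% of the volumes are `pass`;
#' 2. `fail` if more than 20% of the volumes are `fail`;
#' 3. `questionable` otherwise.
#'
#' Rules 1 and 2 can never both fire: a pass fraction above 0.8 forces the
#' fail fraction below 0.2.
#'
#' @param labels Character vector (or factor) of volume quality labels.
#' @return A single quality label string.
#' @export
#' @examples
#' subject_label(rep(c("pass", "questionable"), c(121, 30)))  # 121/151 > 0.8
subject_label <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) abort("empty volume label list")
  if (anyNA(labels)) abort("missing volume label")
  if (!all(labels %in% quality_levels())) abort("invalid volume label")
  n <- length(labels)
  if (sum(labels == "pass") > 0.8 * n) return("pass")
  if (sum(labels == "fail") > 0.2 * n) return("fail")
  "questionable"
}

#' Aggregate slice labels into volume labels
#'
#' Tidy wrapper over [init_volume_label()]: groups a slice table by volume
#' and applies the volume decision rule to the chosen label column.
#'
#' @param slices Tibble with `volume_id` and a label column.
#' @param label_col Name of the slice label column to aggregate (default
#'   `"label"`).
#' @param rule2 Passed to [init_volume_label()].
#' @return Tibble with columns `volume_id`, `label`.
#' @export
aggregate_volume_labels <- function(slices, label_col = "label",
                                    rule2 = c("each", "sum")) {
  rule2 <- match.arg(rule2)
  slices |>
    dplyr::summarise(
      label = init_volume_label(.data[[label_col]], rule2 = rule2),
      .by = "volume_id"
    )
}

#' Aggregate volume labels into subject labels
#'
#' @param volumes Tibble with `subject_id` and a label column.
#' @param label_col Name of the volume label column (default `"label"`).
#' @return Tibble with columns `subject_id`, `label`.
#' @export
aggregate_subject_labels <- function(volumes, label_col = "label") {
  volumes |>
    dplyr::summarise(
      label = subject_label(.data[[label_col]]),
      .by = "subject_id"
    )
}
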