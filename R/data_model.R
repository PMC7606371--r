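#' Build the slice, volume, and subject tables of a dataset split
#'
#' A split bundles three tidy tables plus a name. Slices carry their image as
#' a list-column of numeric matrices; volumes and subjects carry labels and
#' (when known, e.g. from the simulator) ground-truth labels. IDs are opaque
#' hierarchical strings (`subj/vol/slice`) so joins are stable across stages.
#'
#' @param name One of `"labeled_train"`, `"unlabeled"`, `"test"`.
#' @param subjects,volumes,slices Tibbles as produced by [generate_split()]
#'   or [read_split()]; see Details.
#'
#' @details Required columns:
#' * `subjects`: `subject_id`, `label`, `true_label`
#' * `volumes`: `volume_id`, `subject_id`, `label`, `provenance`,
#'   `p_pass`, `p_ques`, `p_fail`, `true_label`
#' * `slices`: `slice_id`, `volume_id`, `subject_id`, `slice_index`,
#'   `label`, `provenance`, `p_pass`, `p_ques`, `p_fail`, `severity`,
#'   `true_label`, `image`
#'
#' `slice_index` preserves anatomical slice order within a volume; the
#' volume-wise network consumes slices in this order. `provenance = "removed"`
#' records stay in the table but are never sampled for training, so
#' self-training bookkeeping remains auditable.
#'
#' @return An object of class `qa_split`.
#' @export
qa_split <- function(name, subjects, volumes, slices) {
  name <- match.arg(name, c("labeled_train", "unlabeled", "test"))
  out <- structure(
    list(name = name,
         subjects = as_tibble(subjects),
         volumes = as_tibble(volumes),
         slices = as_tibble(slices)),
    class = "qa_split"
  )
  out
}

#' @export
print.qa_split <- function(x, ...) {
  cat(sprintf("<qa_split '%s': %d subjects, %d volumes, %d slices>\n",
              x$name, nrow(x$subjects), nrow(x$volumes), nrow(x$slices)))
  lab <- table(factor(x$volumes$label, levels = quality_levels()),
               useNA = "ifany")
  cat("volume labels:", paste(names(lab), lab, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Validate a dataset split
#'
#' Checks the structural invariants of a split and reports every violation as
#' a human-readable message. An empty return value means the split is
#' well-formed.
#'
#' @param split A [qa_split()] object.
#' @return Character vector of violation messages (length 0 if valid).
#' @export
#' @examples
#' s <- generate_split(sim_config(n_subjects = 1, n_volumes_per_subject = 2,
#'                                n_slices_per_volume = 4, size = 32, seed = 1))
#' validate_split(s)
validate_split <- function(split) {
  stopifnot(inherits(split, "qa_split"))
  msgs <- character()
  say <- function(...) msgs[[length(msgs) + 1L]] <<- sprintf(...)

  su <- split$subjects; vo <- split$volumes; sl <- split$slices

  if (anyDuplicated(su$subject_id)) say("duplicated subject_id")
  if (anyDuplicated(vo$volume_id)) say("duplicated volume_id")
  if (anyDuplicated(sl$slice_id)) say("duplicated slice_id")

  for (bad in setdiff(vo$subject_id, su$subject_id)) {
    say("volume %s references missing subject %s",
        vo$volume_id[vo$subject_id == bad][1], bad)
  }
  for (bad in setdiff(sl$volume_id, vo$volume_id)) {
    say("slice %s references missing volume %s",
        sl$slice_id[sl$volume_id == bad][1], bad)
  }
  for (v in setdiff(vo$volume_id, sl$volume_id)) {
    say("missing slice records for volume %s", v)
  }

  chk_labels <- function(x, what) {
    bad <- !is.na(x) & !x %in% quality_levels()
    if (any(bad)) say("invalid %s label(s): %s", what,
                      paste(unique(x[bad]), collapse = ", "))
  }
  chk_labels(vo$label, "volume")
  chk_labels(sl$label, "slice")
  bad_prov <- !is.na(sl$provenance) & !sl$provenance %in% provenance_levels()
  if (any(bad_prov)) say("invalid slice provenance value(s)")

  # label = none forbids expert/weak provenance
  orphan <- is.na(sl$label) & sl$provenance %in% c("given", "inherited")
  for (id in sl$slice_id[which(orphan)]) {
    say("slice %s has no label but provenance given/inherited", id)
  }

  # per-volume slice order must be complete and unique
  ord_bad <- sl |>
    dplyr::summarise(ok = !anyDuplicated(.data$slice_index),
                     .by = "volume_id") |>
    dplyr::filter(!.data$ok)
  for (v in ord_bad$volume_id) say("duplicated slice_index in volume %s", v)

  if (split$name == "labeled_train" && anyNA(vo$label)) {
    for (v in vo$volume_id[is.na(vo$label)]) {
      say("unlabeled volume %s in labeled split", v)
    }
  }
  if (split$name == "unlabeled" && any(!is.na(vo$label))) {
    say("labeled volume(s) present in unlabeled split")
  }

  img_ok <- vapply(sl$image, function(m) {
    is.matrix(m) && is.numeric(m) && all(is.finite(m))
  }, logical(1))
  if (!all(img_ok)) say("non-finite or non-matrix slice image(s)")

  msgs
}

#' Expected record counts for a split geometry
#'
#' The counting identity of the hierarchical layout: `S` subjects each
#' scanned with `V` volumes of `n` slices yield `S*V` volumes and `S*V*n`
#' slices. Used both as a sanity check on loaded data and to compute
#' dataset-scale arithmetic (e.g. 24 test subjects x 151 volumes = 3624
#' volumes; 3624 x 60 sagittal slices = 217440 slices).
#'
#' @param n_subjects,n_volumes_per_subject,n_slices_per_volume Integers.
#' @return A tibble with columns `subjects`, `volumes`, `slices`.
#' @export
#' @examples
#' split_geometry(24, 151, 60)
split_geometry <- function(n_subjects, n_volumes_per_subject,
                           n_slices_per_volume) {
  stopifnot(n_subjects >= 1, n_volumes_per_subject >= 1,
            n_slices_per_volume >= 1)
  tibble(
    subjects = as.double(n_subjects),
    volumes = as.double(n_subjects) * n_volumes_per_subject,
    slices = as.double(n_subjects) * n_volumes_per_subject *
      n_slices_per_volume
  )
}

# slices eligible for a training batch: labeled and not removed
training_slices <- function(slices) {
  dplyr::filter(slices, !is.na(.data$label),
                is.na(.data$provenance) | .data$provenance != "removed")
}

training_volumes <- function(volumes) {
  dplyr::filter(volumes, !is.na(.data$label),
                is.na(.data$provenance) | .data$provenance != "removed")
}
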