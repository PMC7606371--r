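#' Write a dataset split to disk
#'
#' Persists the three label tables as CSV, the slice images as one NIfTI-1
#' volume per acquisition (slices stacked along the first, sagittal axis),
#' and an `index.json` mapping volume IDs to image paths. The layout is the
#' same one [read_split()] consumes and the simulator emits.
#'
#' @param split A [qa_split()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "qa_split"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)

  readr::write_csv(split$subjects, file.path(dir, "subjects.csv"), na = "")
  readr::write_csv(split$volumes, file.path(dir, "volumes.csv"), na = "")
  readr::write_csv(dplyr::select(split$slices, -"image"),
                   file.path(dir, "slices.csv"), na = "")

  index <- list()
  for (v in split$volumes$volume_id) {
    sl <- split$slices[split$slices$volume_id == v, ]
    sl <- sl[order(sl$slice_index), ]
    h <- nrow(sl$image[[1]]); w <- ncol(sl$image[[1]])
    arr <- array(0, dim = c(length(sl$image), h, w))
    for (i in seq_along(sl$image)) arr[i, , ] <- sl$image[[i]]
    path <- file.path("images", paste0(gsub("/", "_", v), ".nii.gz"))
    RNifti::writeNifti(arr, file.path(dir, path), datatype = "double")
    index[[v]] <- path
  }
  jsonlite::write_json(
    list(name = split$name, images = index),
    file.path(dir, "index.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' Read a dataset split from disk
#'
#' @param dir Directory previously written by [write_split()] (CSV label
#'   tables + NIfTI-1 images + `index.json`).
#' @return A [qa_split()] object.
#' @export
read_split <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "index.json"))
  subjects <- readr::read_csv(
    file.path(dir, "subjects.csv"), show_col_types = FALSE,
    col_types = readr::cols(subject_id = "c", label = "c", true_label = "c")
  )
  volumes <- readr::read_csv(
    file.path(dir, "volumes.csv"), show_col_types = FALSE,
    col_types = readr::cols(volume_id = "c", subject_id = "c", label = "c",
                            provenance = "c", true_label = "c",
                            .default = "d")
  )
  slices <- readr::read_csv(
    file.path(dir, "slices.csv"), show_col_types = FALSE,
    col_types = readr::cols(slice_id = "c", volume_id = "c",
                            subject_id = "c", label = "c", provenance = "c",
                            true_label = "c", slice_index = "i",
                            .default = "d")
  )

  images <- vector("list", nrow(slices))
  for (v in names(index$images)) {
    arr <- RNifti::readNifti(file.path(dir, index$images[[v]]))
    arr <- unclass(arr)[, , , drop = FALSE]
    rows <- which(slices$volume_id == v)
    rows <- rows[order(slices$slice_index[rows])]
    for (i in seq_along(rows)) {
      images[[rows[i]]] <- matrix(arr[i, , ], dim(arr)[2], dim(arr)[3])
    }
  }
  slices$image <- images
  qa_split(index$name, subjects, volumes, slices)
}
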