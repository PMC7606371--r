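#' Extract sagittal slices from a 3D volume
#'
#' Motion artifacts are most apparent on sagittal sections, so the pipeline
#' rates 2D sagittal slices. Slices are returned in acquisition order along
#' the sagittal axis.
#'
#' @param volume 3D numeric array.
#' @param axis Index of the sagittal axis (default 1).
#' @return List of 2D matrices, one per sagittal index.
#' @export
extract_sagittal_slices <- function(volume, axis = 1) {
  if (!(is.array(volume) && length(dim(volume)) == 3)) {
    abort("volume must be a 3D array")
  }
  stopifnot(axis %in% 1:3)
  n <- dim(volume)[axis]
  lapply(seq_len(n), function(i) {
    switch(axis,
           matrix(volume[i, , ], dim(volume)[2], dim(volume)[3]),
           matrix(volume[, i, ], dim(volume)[1], dim(volume)[3]),
           matrix(volume[, , i], dim(volume)[1], dim(volume)[2]))
  })
}

#' Zero-pad and min-max normalize a slice
#'
#' Centers the slice on a `target x target` zero canvas (any odd leftover
#' margin goes to the bottom/right), then rescales the *padded* array to
#' `[0, 1]` by `(x - min) / (max - min)`. Padding first means background
#' zeros participate in the normalization, matching the preprocessing order
#' used for acquisition data. A constant-valued slice maps to all zeros
#' (the continuous limit of a black background).
#'
#' @param slice 2D numeric matrix, both dimensions `<= target`.
#' @param target Canvas size (default 144).
#' @return `target x target` matrix with values in `[0, 1]`.
#' @export
#' @examples
#' pad_and_normalize(matrix(c(2, 4, 6, 4), 2, 2), target = 4)
pad_and_normalize <- function(slice, target = 144) {
  stopifnot(is.matrix(slice), is.numeric(slice))
  h <- nrow(slice); w <- ncol(slice)
  if (h > target || w > target) {
    abort("slice exceeds target size; cropping is not supported")
  }
  top <- floor((target - h) / 2)
  left <- floor((target - w) / 2)
  out <- matrix(0, target, target)
  out[top + seq_len(h), left + seq_len(w)] <- slice
  rng <- range(out)
  if (rng[2] == rng[1]) return(matrix(0, target, target))
  (out - rng[1]) / (rng[2] - rng[1])
}

#' Augment a slice for training
#'
#' Random rotation by an angle drawn uniformly from `[0, max_angle]` degrees
#' (bilinear interpolation, zero fill, about the image center) followed by a
#' horizontal flip with probability `flip_prob`. Used at training time only;
#' labels are untouched. Pass `angle`/`flip` explicitly for deterministic
#' behavior, otherwise both are drawn from the current RNG state.
#'
#' @param slice Preprocessed 2D matrix.
#' @param max_angle Maximum rotation in degrees (default 30).
#' @param flip_prob Probability of a horizontal flip (default 0.5).
#' @param angle,flip Optional explicit rotation angle / flip indicator.
#' @return Matrix of the same dimensions.
#' @export
augment_slice <- function(slice, max_angle = 30, flip_prob = 0.5,
                          angle = NULL, flip = NULL) {
  stopifnot(is.matrix(slice))
  angle <- angle %||% runif(1, 0, max_angle)
  flip <- flip %||% (runif(1) < flip_prob)
  out <- slice
  if (angle != 0) {
    out <- EBImage::rotate(out, angle, filter = "bilinear",
                           output.dim = dim(slice), bg.col = 0)
    out <- matrix(out, nrow(slice), ncol(slice))
  }
  if (isTRUE(flip)) out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  out
}
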