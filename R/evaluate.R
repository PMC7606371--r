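#' Confusion matrix over quality labels
#'
#' @param actual,predicted Equal-length vectors of quality labels.
#' @return A 3x3 integer matrix of class `qa_confusion`; rows are actual,
#'   columns predicted, both in pass/questionable/fail order.
#' @export
#' @examples
#' qa_confusion(c("pass", "fail"), c("pass", "questionable"))
qa_confusion <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) == 0) {
    abort("actual and predicted must have equal positive length")
  }
  cm <- table(factor(as.character(actual), levels = quality_levels()),
              factor(as.character(predicted), levels = quality_levels()))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(actual = quality_levels(),
                               predicted = quality_levels()))
  structure(cm, class = c("qa_confusion", class(cm)))
}

#' Treat an existing 3x3 count matrix as a confusion matrix
#'
#' @param m Numeric 3x3 matrix, rows actual / columns predicted in
#'   pass/questionable/fail order.
#' @return A `qa_confusion` object.
#' @export
as_qa_confusion <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 3), all(m >= 0))
  m <- matrix(as.integer(round(m)), 3, 3,
              dimnames = list(actual = quality_levels(),
                              predicted = quality_levels()))
  structure(m, class = c("qa_confusion", class(m)))
}

#' Per-class sensitivity/specificity and overall accuracy
#'
#' Each class is scored one-vs-rest: `SEN = TP / (TP + FN)`,
#' `SPE = TN / (TN + FP)`. The overall accuracy is the multi-class
#' accuracy `trace / total` (the single accuracy figure reported per
#' stage). A metric with a zero denominator (e.g. a class with no actual
#' examples) is returned as `NA` rather than raising an error.
#'
#' @param cm A [qa_confusion()] matrix.
#' @return List of class `qa_metrics` with `by_class` (tibble: `class`,
#'   `sen`, `spe`) and `accuracy`.
#' @export
#' @examples
#' cm <- as_qa_confusion(diag(c(5, 3, 2)))
#' qa_metrics(cm)
qa_metrics <- function(cm) {
  stopifnot(inherits(cm, "qa_confusion"))
  tot <- sum(cm)
  rows <- lapply(1:3, function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, -k])
    fp <- sum(cm[-k, k])
    tn <- tot - tp - fn - fp
    tibble(class = quality_levels()[k],
           sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           spe = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  structure(list(by_class = dplyr::bind_rows(rows),
                 accuracy = sum(diag(cm)) / tot,
                 confusion = cm),
            class = "qa_metrics")
}

#' @export
print.qa_metrics <- function(x, digits = 4, ...) {
  cat("Per-class metrics (one-vs-rest):\n")
  print(dplyr::mutate(x$by_class,
                      dplyr::across(c("sen", "spe"), ~ round(.x, digits))))
  cat(sprintf("Overall accuracy: %.4f\n", x$accuracy))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qa_metrics <- function(x, ...) x$by_class

#' @exportS3Method generics::glance
glance.qa_metrics <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = sum(x$confusion))
}

#' @exportS3Method generics::tidy
tidy.qa_confusion <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "n")) |>
    dplyr::mutate(dplyr::across(c("actual", "predicted"), as.character))
}

#' @exportS3Method ggplot2::autoplot
autoplot.qa_confusion <- function(object, ...) {
  df <- tidy.qa_confusion(object)
  df$actual <- factor(df$actual, levels = rev(quality_levels()))
  df$predicted <- factor(df$predicted, levels = quality_levels())
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$actual,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "Predicted", y = "Actual", fill = "Count") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.qa_pipeline <- function(object, ...) {
  h <- object$sqa$history
  ggplot2::ggplot(h, ggplot2::aes(seq_along(.data$loss), .data$loss,
                                  colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch (cumulative)", y = "Training loss",
                  colour = "Stage") +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.qa_pipeline <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.qa_pipeline <- function(x, ...) {
  tibble(
    n_slices = nrow(x$slices),
    n_volumes = nrow(x$volumes),
    slices_removed = sum(x$slices$provenance == "removed", na.rm = TRUE),
    slices_relabeled = sum(x$slices$provenance == "relabeled",
                           na.rm = TRUE),
    volumes_removed = sum(x$volumes$provenance == "removed", na.rm = TRUE)
  )
}

#' Read a prediction table and compute its metrics
#'
#' @param path CSV with columns `id`, `actual`, `predicted`.
#' @return A [qa_metrics()] object.
#' @export
evaluate_predictions_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  stopifnot(all(c("actual", "predicted") %in% names(df)))
  qa_metrics(qa_confusion(df$actual, df$predicted))
}

#' Write metrics as JSON
#'
#' @param metrics A [qa_metrics()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(
    list(accuracy = metrics$accuracy,
         by_class = metrics$by_class,
         confusion = unclass(metrics$confusion)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Reference confusion matrices from the published evaluation
#'
#' Loads the printed volume- and subject-level confusion matrices of the
#' four network variants (DSR, DSR+NLR, NLDR+NLR, and the full
#' DSR+NLDR+NLR model) bundled as a plain-text fixture, for reproducing
#' the published metric table.
#'
#' @return Named list of `qa_confusion` matrices; names are
#'   `<variant>_<level>` (e.g. `"dsr_nldr_nlr_volume"`).
#' @export
reference_confusion_matrices <- function() {
  path <- system.file("extdata", "reference_confusion_matrices.csv",
                      package = "dmriqa")
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(variant = "c", level = "c",
                                                actual = "c",
                                                .default = "i"))
  out <- list()
  for (key in unique(paste(df$variant, df$level, sep = "_"))) {
    sub <- df[paste(df$variant, df$level, sep = "_") == key, ]
    sub <- sub[match(quality_levels(), sub$actual), ]
    out[[key]] <- as_qa_confusion(as.matrix(sub[, quality_levels()]))
  }
  out
}
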