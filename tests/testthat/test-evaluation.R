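test_that("confusion matrices count pairs and conserve totals", {
  a <- rep(quality_levels(), c(4, 3, 3))
  cm <- qa_confusion(a, a)
  expect_equal(diag(unclass(cm)), c(pass = 4, questionable = 3, fail = 3))
  expect_equal(sum(cm), 10)

  cm1 <- qa_confusion("pass", "fail")
  expect_equal(cm1["pass", "fail"], 1)
  expect_equal(sum(cm1), 1)

  expect_error(qa_confusion(c("pass", "fail"), "pass"), "equal")
})

test_that("perfect agreement yields unit metrics", {
  m <- qa_metrics(as_qa_confusion(diag(3)))
  expect_equal(m$by_class$sen, rep(1, 3))
  expect_equal(m$by_class$spe, rep(1, 3))
  expect_equal(m$accuracy, 1)
})

# Metric table reproduced from the published confusion matrices. One
# printed subject-level sensitivity (DSR, questionable) is inconsistent
# with its own matrix (row (1, 9, 0) gives 0.9); the matrix-derived value
# is asserted there.
published <- list(
  dsr_volume = list(sen = c(0.5838, 0.8547, 0.7647),
                    spe = c(0.9038, 0.6112, 0.9879), acc = 0.6865),
  dsr_subject = list(sen = c(0.4000, 0.9000, 0.7500),
                     spe = c(0.9286, 0.5000, 1.0000), acc = 0.6667),
  dsr_nlr_volume = list(sen = c(0.7304, 0.9419, 0.7255),
                        spe = c(0.9451, 0.7372, 0.9985), acc = 0.7983),
  dsr_nlr_subject = list(sen = c(0.7000, 0.9000, 0.7500),
                         spe = c(0.9286, 0.7143, 1.0000), acc = 0.7917),
  nldr_nlr_volume = list(sen = c(0.9088, 0.9701, 0.9510),
                         spe = c(0.9776, 0.9140, 0.9994), acc = 0.9321),
  nldr_nlr_subject = list(sen = c(0.9000, 1.0000, 1.0000),
                          spe = c(1.0000, 0.9286, 1.0000), acc = 0.9583),
  dsr_nldr_nlr_volume = list(sen = c(0.9935, 0.9803, 1.0000),
                             spe = c(0.9844, 0.9943, 1.0000), acc = 0.9898),
  dsr_nldr_nlr_subject = list(sen = c(1, 1, 1), spe = c(1, 1, 1), acc = 1)
)

test_that("published metric tables are reproduced from the matrices", {
  cms <- reference_confusion_matrices()
  expect_setequal(names(cms), names(published))
  for (key in names(published)) {
    m <- qa_metrics(cms[[key]])
    expect_equal(round(m$by_class$sen, 4), published[[key]]$sen,
                 tolerance = 1e-8, label = paste(key, "sen"))
    expect_equal(round(m$by_class$spe, 4), published[[key]]$spe,
                 tolerance = 1e-8, label = paste(key, "spe"))
    expect_equal(round(m$accuracy, 4), published[[key]]$acc,
                 tolerance = 1e-8, label = paste(key, "acc"))
  }
})

test_that("metrics agree with a brute-force recount on random label sets", {
  set.seed(6)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    a <- sample(quality_levels(), n, replace = TRUE)
    p <- sample(quality_levels(), n, replace = TRUE)
    m <- qa_metrics(qa_confusion(a, p))
    expect_equal(m$accuracy, mean(a == p))
    for (k in 1:3) {
      cls <- quality_levels()[k]
      pos <- a == cls
      sen <- if (any(pos)) mean(p[pos] == cls) else NA_real_
      spe <- if (any(!pos)) mean(p[!pos] != cls) else NA_real_
      expect_equal(m$by_class$sen[k], sen)
      expect_equal(m$by_class$spe[k], spe)
    }
  }
})

test_that("overall accuracy is the prevalence-weighted mean of recalls", {
  set.seed(7)
  for (i in 1:20) {
    a <- sample(quality_levels(), 60, replace = TRUE)
    p <- sample(quality_levels(), 60, replace = TRUE)
    m <- qa_metrics(qa_confusion(a, p))
    prev <- table(factor(a, quality_levels())) / length(a)
    recalls <- m$by_class$sen
    recalls[is.na(recalls)] <- 0
    expect_equal(m$accuracy, sum(prev * recalls))
  }
})

test_that("degenerate classes flag metrics as undefined", {
  cm <- qa_confusion(rep("pass", 5), rep("pass", 5))
  m <- qa_metrics(cm)
  expect_true(is.na(m$by_class$sen[2]))   # no actual questionable
  expect_true(is.na(m$by_class$spe[1]))   # no actual non-pass
})

test_that("prediction CSVs evaluate end to end and metrics serialize", {
  dir <- withr::local_tempdir()
  df <- tibble::tibble(id = as.character(1:6),
                       actual = rep(quality_levels(), 2),
                       predicted = c("pass", "questionable", "fail",
                                     "pass", "pass", "fail"))
  readr::write_csv(df, file.path(dir, "preds.csv"))
  m <- evaluate_predictions_csv(file.path(dir, "preds.csv"))
  expect_equal(m$accuracy, 5 / 6)
  write_metrics_json(m, file.path(dir, "metrics.json"))
  back <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(back$accuracy, 5 / 6)
})

test_that("tidiers and plots expose the confusion matrix", {
  cm <- qa_confusion(rep(quality_levels(), c(3, 2, 1)),
                     rep("pass", 6))
  td <- tidy(cm)
  expect_equal(sum(td$n), 6)
  gg <- autoplot(cm)
  expect_s3_class(gg, "ggplot")
  m <- qa_metrics(cm)
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(glance(m)$n, 6)
})
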