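test_that("volume rule fires in order with strict thresholds", {
  expect_equal(init_volume_label(rep(c("pass", "fail"), c(37, 23))), "pass")
  expect_equal(
    init_volume_label(rep(c("pass", "questionable", "fail"),
                          c(10, 20, 30))), "fail")
  # exactly 60% pass is not enough
  expect_equal(
    init_volume_label(rep(c("pass", "questionable", "fail"),
                          c(36, 12, 12))), "questionable")
  expect_error(init_volume_label(character()), "empty")
})

test_that("subject rule fires in order with strict thresholds", {
  expect_equal(subject_label(rep("pass", 151)), "pass")
  # 121/151 = 80.13% > 80%
  expect_equal(subject_label(rep(c("pass", "questionable"), c(121, 30))),
               "pass")
  # 40/151 = 26.5% > 20%
  expect_equal(subject_label(rep(c("questionable", "fail"), c(111, 40))),
               "fail")
  expect_error(subject_label(character()), "empty")
})

# independent brute-force oracles working on count triples
oracle_volume <- function(np, nq, nf, rule2 = "each") {
  n <- np + nq + nf
  if (np > 0.6 * n) return("pass")
  fail <- if (rule2 == "each") nf > np && nf > nq else nf > np + nq
  if (fail) return("fail")
  "questionable"
}
oracle_subject <- function(np, nq, nf) {
  n <- np + nq + nf
  if (np > 0.8 * n) return("pass")
  if (nf > 0.2 * n) return("fail")
  "questionable"
}

test_that("rules are total and match the oracle for all triples up to 60", {
  grid <- expand.grid(np = 0:60, nq = 0:60, nf = 0:60)
  grid <- grid[grid$np + grid$nq + grid$nf > 0 &
                 grid$np + grid$nq + grid$nf <= 60, ]
  # sample the full enumeration deterministically to keep runtime modest,
  # always including every boundary-total triple
  set.seed(1)
  idx <- unique(c(which(grid$np + grid$nq + grid$nf == 60),
                  sample.int(nrow(grid), 4000)))
  co_fire <- 0L
  for (i in idx) {
    np <- grid$np[i]; nq <- grid$nq[i]; nf <- grid$nf[i]
    labs <- rep(c("pass", "questionable", "fail"), c(np, nq, nf))
    for (r2 in c("each", "sum")) {
      got <- init_volume_label(labs, rule2 = r2)
      expect_identical(got, oracle_volume(np, nq, nf, r2))
    }
    got_s <- subject_label(labs)
    expect_identical(got_s, oracle_subject(np, nq, nf))
    # subject rules 1 and 2 can never both fire
    n <- np + nq + nf
    if (np > 0.8 * n && nf > 0.2 * n) co_fire <- co_fire + 1L
  }
  expect_identical(co_fire, 0L)
})

test_that("labels depend only on counts, not order", {
  set.seed(2)
  for (i in 1:20) {
    labs <- sample(quality_levels(), 30, replace = TRUE)
    expect_identical(init_volume_label(labs),
                     init_volume_label(sample(labs)))
    expect_identical(subject_label(labs), subject_label(sample(labs)))
  }
})

test_that("the two readings of volume rule 2 genuinely differ", {
  labs <- rep(c("pass", "questionable", "fail"), c(10, 20, 25))
  expect_equal(init_volume_label(labs, rule2 = "each"), "fail")
  expect_equal(init_volume_label(labs, rule2 = "sum"), "questionable")
})

test_that("tidy aggregation wrappers group correctly", {
  sl <- tibble::tibble(
    volume_id = rep(c("a", "b"), each = 10),
    label = c(rep("pass", 9), "fail", rep("fail", 6), rep("pass", 4))
  )
  agg <- aggregate_volume_labels(sl)
  expect_equal(agg$label[agg$volume_id == "a"], "pass")
  expect_equal(agg$label[agg$volume_id == "b"], "fail")

  vo <- tibble::tibble(subject_id = "s", label = rep("pass", 5))
  expect_equal(aggregate_subject_labels(vo)$label, "pass")
})
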