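# Shared fixtures. Expensive objects are built once per test run and
# cached; everything is generated in code, nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a small but non-trivial split: 2 subjects x 3 volumes x 4 slices of 32x32
small_split <- function() {
  fixture("small_split", function() {
    generate_split(sim_config(n_subjects = 2, n_volumes_per_subject = 3,
                              n_slices_per_volume = 4, size = 32,
                              flip_rate = 0, seed = 42))
  })
}

# minimal slice net for rule-logic tests (32x32, very thin channels)
tiny_spec <- function(n_slices = 4L) {
  net_spec(32, channels = c(2L, 3L, 4L, 5L), n_slices = n_slices,
           reduce_channels = 2L)
}

# a model whose CLF bias forces an (almost) fixed output distribution,
# independent of the input: handy for exercising threshold rules exactly
stub_model <- function(logits = c(20, 0, 0), spec = tiny_spec()) {
  m <- sqa_net(spec, seed = 7)
  m$params$clf$W[] <- 0
  m$params$clf$b <- logits
  m
}

# labeled slice table of n rows with given labels, images 32x32
labeled_slices <- function(labels, size = 32) {
  n <- length(labels)
  ph <- make_phantom(size, seed = 5)
  tibble::tibble(
    slice_id = sprintf("s%03d", seq_len(n)),
    volume_id = "v1", subject_id = "s1",
    slice_index = seq_len(n),
    label = labels, provenance = "inherited",
    p_pass = NA_real_, p_ques = NA_real_, p_fail = NA_real_,
    severity = NA_real_, true_label = labels,
    image = replicate(n, ph, simplify = FALSE)
  )
}

expect_prob_rows <- function(p) {
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(as.matrix(p)), rep(1, nrow(p)), tolerance = 1e-6)
}
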