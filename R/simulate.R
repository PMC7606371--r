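#' Artifact parameters at a given severity
#'
#' Maps a scalar severity in `[0, 1]` to the magnitudes of the four simulated
#' artifact processes, all non-decreasing in severity:
#' * `ghost_weight` — weight of a half-FOV cyclically shifted replica,
#'   mimicking EPI motion ghosts along the phase-encode axis;
#' * `dropout_band_count` — number of zeroed horizontal bands (slice-wise
#'   signal dropout);
#' * `blur_sigma` — Gaussian blur width in pixels (motion smearing);
#' * `noise_sigma` — scale of Rician-style magnitude noise, with a small
#'   floor so even pristine slices carry scanner noise.
#'
#' @param severity Real in `[0, 1]`; 0 means artifact-free up to the noise
#'   floor.
#' @param seed Integer seed used when the slice is corrupted.
#' @param ghost_weight,dropout_band_count,blur_sigma,noise_sigma Optional
#'   overrides of the severity-derived magnitudes.
#' @return A list of class `artifact_params`.
#' @export
artifact_params <- function(severity, seed = 1L,
                            ghost_weight = NULL, dropout_band_count = NULL,
                            blur_sigma = NULL, noise_sigma = NULL) {
  stopifnot(length(severity) == 1, is.finite(severity))
  if (severity < 0 || severity > 1) abort("severity must be in [0, 1]")
  p <- list(
    severity = severity,
    ghost_weight = ghost_weight %||% (0.35 * severity),
    dropout_band_count = dropout_band_count %||% floor(3 * severity + 1e-9),
    blur_sigma = blur_sigma %||% (2 * severity),
    noise_sigma = noise_sigma %||% (0.01 + 0.08 * severity),
    seed = as.integer(seed)
  )
  structure(p, class = "artifact_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic brain-like phantom slice
#'
#' An elliptical head support containing smoothed random "tissue" blobs and a
#' brighter rim, intensities in `[0, 1]` with exactly zero background. The
#' phantom is fully determined by `size` and `seed`.
#'
#' @param size Side length in pixels (`>= 32`).
#' @param seed Integer seed.
#' @return A `size x size` numeric matrix.
#' @export
#' @examples
#' ph <- make_phantom(64, seed = 1)
#' range(ph)
make_phantom <- function(size, seed = 1L) {
  stopifnot(length(size) == 1)
  if (size < 32) abort("phantom size must be >= 32")
  withr::with_seed(as.integer(seed), {
    cx <- size / 2 + runif(1, -1, 1)
    cy <- size / 2 + runif(1, -1, 1)
    rx <- size * runif(1, 0.36, 0.42)
    ry <- size * runif(1, 0.30, 0.36)
    xs <- matrix(seq_len(size), size, size)
    ys <- matrix(seq_len(size), size, size, byrow = TRUE)
    r2 <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2
    mask <- r2 <= 1

    tex <- matrix(rnorm(size * size), size, size)
    tex <- EBImage::gblur(tex, sigma = size / 16)
    tex <- (tex - min(tex)) / (max(tex) - min(tex))

    rim <- exp(-((sqrt(r2) - 0.92) / 0.06)^2)  # bright skull-like rim
    img <- (0.25 + 0.6 * tex + 0.4 * rim) * mask
    img <- img / max(img)
    img[!mask] <- 0
    img
  })
}

#' Corrupt a slice with severity-graded artifacts
#'
#' Applies, in order: phase-ghosting (a half-FOV cyclically shifted replica
#' added with weight `ghost_weight`), zeroed horizontal dropout bands,
#' Gaussian blur, and bounded Rician-style magnitude noise
#' (`sqrt((x + n1)^2 + n2^2)` with `n1, n2` truncated at two standard
#' deviations so the severity-zero deviation stays below three times the
#' noise floor). The result is clipped to `[0, 1]`.
#'
#' @param phantom Numeric matrix with finite values.
#' @param params An [artifact_params()] object.
#' @return Corrupted matrix, same dimensions, values in `[0, 1]`.
#' @export
corrupt_slice <- function(phantom, params) {
  stopifnot(is.matrix(phantom), all(is.finite(phantom)),
            inherits(params, "artifact_params"))
  h <- nrow(phantom); w <- ncol(phantom)
  withr::with_seed(params$seed, {
    img <- phantom
    if (params$ghost_weight > 0) {
      shift <- floor(h / 2)
      ghost <- img[c((shift + 1):h, 1:shift), , drop = FALSE]
      img <- (img + params$ghost_weight * ghost) / (1 + params$ghost_weight)
    }
    nb <- params$dropout_band_count
    if (nb > 0) {
      # one band inside each of nb equal row segments => disjoint by design
      seg <- floor(h / nb)
      for (k in seq_len(nb)) {
        bh <- sample(2:3, 1)
        lo <- (k - 1) * seg + sample.int(max(seg - bh, 1), 1)
        img[lo:min(lo + bh - 1, h), ] <- 0
      }
    }
    if (params$blur_sigma > 0) {
      img <- EBImage::gblur(img, sigma = params$blur_sigma)
    }
    s <- params$noise_sigma
    n1 <- pmin(pmax(matrix(rnorm(h * w, sd = s), h, w), -2 * s), 2 * s)
    n2 <- pmin(pmax(matrix(rnorm(h * w, sd = s), h, w), -2 * s), 2 * s)
    img <- sqrt((img + n1)^2 + n2^2)
    pmin(pmax(img, 0), 1)
  })
}

#' Ground-truth slice label from severity
#'
#' @param severity Real in `[0, 1]`.
#' @param thresholds Increasing pair `(s1, s2)`: severities below `s1` pass,
#'   below `s2` are questionable, the rest fail.
#' @return A quality label string.
#' @export
#' @examples
#' true_slice_label(0.3, c(0.3, 0.6))  # boundary goes to questionable
true_slice_label <- function(severity, thresholds = c(0.3, 0.6)) {
  if (any(severity < 0 | severity > 1)) abort("severity must be in [0, 1]")
  stopifnot(length(thresholds) == 2, thresholds[1] > 0,
            thresholds[1] < thresholds[2], thresholds[2] < 1)
  out <- ifelse(severity < thresholds[1], "pass",
                ifelse(severity < thresholds[2], "questionable", "fail"))
  out
}

#' Simulation configuration
#'
#' Describes the synthetic cohort: geometry, per-class slice-severity
#' mixtures (Beta distributions), the severity-to-label thresholds, the
#' volume class balance, weak labeling, and the volume label-flip rate.
#' Defaults give the desk-scale fixture (4 subjects x 12 volumes x 16
#' slices of 64 x 64) with the training class balance of the clinical
#' cohort the simulator stands in for (85/25/40 pass/questionable/fail
#' volumes out of 150).
#'
#' @param n_subjects,n_volumes_per_subject,n_slices_per_volume Geometry.
#' @param size Slice side length in pixels.
#' @param severity_mixture Named list of `c(shape1, shape2)` Beta parameters
#'   per volume class; slice severities inside a volume of that class are
#'   drawn from the corresponding Beta.
#' @param class_mix Probabilities that a volume belongs to each severity
#'   class, in `(pass, questionable, fail)` order.
#' @param label_thresholds Pair `(s1, s2)` passed to [true_slice_label()].
#' @param weak_labeling If `TRUE` every slice's stored label is copied from
#'   its volume's (possibly flipped) label, with provenance `inherited`.
#' @param flip_rate Fraction of volumes (exactly `round(flip_rate * n)`)
#'   whose stored label is reassigned uniformly to one of the two other
#'   classes; must be `< 0.5`.
#' @param seed Integer seed; the whole split is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 4, n_volumes_per_subject = 12,
                       n_slices_per_volume = 16, size = 64,
                       severity_mixture = list(
                         pass = c(2, 10),
                         questionable = c(8, 8),
                         fail = c(10, 2.5)
                       ),
                       class_mix = c(85, 25, 40) / 150,
                       label_thresholds = c(0.3, 0.6),
                       weak_labeling = TRUE, flip_rate = 0,
                       seed = 1L) {
  stopifnot(flip_rate >= 0, flip_rate < 0.5,
            length(class_mix) == 3, abs(sum(class_mix) - 1) < 1e-8,
            setequal(names(severity_mixture), quality_levels()))
  structure(
    list(n_subjects = n_subjects,
         n_volumes_per_subject = n_volumes_per_subject,
         n_slices_per_volume = n_slices_per_volume,
         size = size, severity_mixture = severity_mixture,
         class_mix = class_mix, label_thresholds = label_thresholds,
         weak_labeling = weak_labeling, flip_rate = flip_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a synthetic dataset split
#'
#' Draws a severity class per volume, slice severities from the class
#' mixture, renders each slice as a corrupted phantom, computes true slice
#' labels from severities and true volume labels by the volume decision rule
#' ([init_volume_label()]), then stores weak (inherited) slice labels and
#' applies exact-count volume label flips. For `name = "unlabeled"` stored
#' labels are blanked (truth is retained in `true_label` columns); for
#' `name = "test"` stored labels equal the truth.
#'
#' @param cfg A [sim_config()].
#' @param name Split role: `"labeled_train"` (default), `"unlabeled"`, or
#'   `"test"`.
#' @param prefix Subject ID prefix (default: the first three letters of
#'   `name`), so IDs stay unique when several splits are combined.
#' @return A [qa_split()] with a `config` attribute recording `cfg`.
#' @export
generate_split <- function(cfg, name = "labeled_train",
                           prefix = substr(name, 1, 3)) {
  stopifnot(inherits(cfg, "sim_config"))
  name <- match.arg(name, c("labeled_train", "unlabeled", "test"))
  lv <- quality_levels()

  withr::with_seed(cfg$seed, {
    slices <- list(); volumes <- list()
    for (s in seq_len(cfg$n_subjects)) {
      subj <- sprintf("%s%02d", prefix, s)
      for (v in seq_len(cfg$n_volumes_per_subject)) {
        vol <- sprintf("%s/vol%03d", subj, v)
        cls <- sample(lv, 1, prob = cfg$class_mix)
        sh <- cfg$severity_mixture[[cls]]
        sev <- rbeta(cfg$n_slices_per_volume, sh[1], sh[2])
        true_sl <- true_slice_label(sev, cfg$label_thresholds)
        imgs <- vector("list", cfg$n_slices_per_volume)
        for (i in seq_len(cfg$n_slices_per_volume)) {
          # anatomy varies with sagittal position: a fresh phantom per slice
          ph <- make_phantom(cfg$size,
                             seed = sample.int(.Machine$integer.max, 1))
          ap <- artifact_params(sev[i],
                                seed = sample.int(.Machine$integer.max, 1))
          imgs[[i]] <- corrupt_slice(ph, ap)
        }
        volumes[[vol]] <- tibble(
          volume_id = vol, subject_id = subj,
          true_label = init_volume_label(true_sl)
        )
        slices[[vol]] <- tibble(
          slice_id = sprintf("%s/s%03d", vol,
                             seq_len(cfg$n_slices_per_volume)),
          volume_id = vol, subject_id = subj,
          slice_index = seq_len(cfg$n_slices_per_volume),
          severity = sev, true_label = true_sl, image = imgs
        )
      }
    }
    volumes <- dplyr::bind_rows(volumes)
    slices <- dplyr::bind_rows(slices)

    # stored volume labels = truth, then exact-count random flips
    volumes$label <- volumes$true_label
    n_flip <- round(cfg$flip_rate * nrow(volumes))
    if (n_flip > 0) {
      idx <- sample.int(nrow(volumes), n_flip)
      volumes$label[idx] <- vapply(volumes$label[idx], function(l) {
        sample(setdiff(lv, l), 1)
      }, character(1))
    }
    volumes$provenance <- "given"
    volumes$p_pass <- NA_real_; volumes$p_ques <- NA_real_
    volumes$p_fail <- NA_real_

    if (cfg$weak_labeling) {
      slices$label <- volumes$label[match(slices$volume_id,
                                          volumes$volume_id)]
      slices$provenance <- "inherited"
    } else {
      slices$label <- slices$true_label
      slices$provenance <- "given"
    }
    slices$p_pass <- NA_real_; slices$p_ques <- NA_real_
    slices$p_fail <- NA_real_

    subjects <- volumes |>
      dplyr::summarise(
        label = subject_label(.data$label),
        true_label = subject_label(.data$true_label),
        .by = "subject_id"
      )

    if (name == "unlabeled") {
      volumes$label <- NA_character_; volumes$provenance <- NA_character_
      slices$label <- NA_character_; slices$provenance <- NA_character_
      subjects$label <- NA_character_
    }
    if (name == "test") {
      volumes$label <- volumes$true_label
      slices$label <- slices$true_label
      subjects$label <- subjects$true_label
    }

    cols_v <- c("volume_id", "subject_id", "label", "provenance",
                "p_pass", "p_ques", "p_fail", "true_label")
    cols_s <- c("slice_id", "volume_id", "subject_id", "slice_index",
                "label", "provenance", "p_pass", "p_ques", "p_fail",
                "severity", "true_label", "image")
    out <- qa_split(name, subjects, volumes[cols_v], slices[cols_s])
    attr(out, "config") <- cfg
    out
  })
}
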