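#' Define a time-varying representational geometry
#'
#' A geometry schedule is the ground truth behind a simulated EEG epoch set:
#' a list of latency windows, each carrying a latent pattern matrix (one row
#' per stimulus) and a gain. Within its window a pattern is active at full
#' gain (with a short linear cross-fade at the edges to avoid
#' discontinuities); after the window the gain falls to
#' `persistence * gain` and stays there until the end of the epoch. With
#' `persistence = 0` (the control regime) representations are transient;
#' `persistence > 0` makes early representational geometry linger into late
#' latencies — the single-case abnormality this package is built to detect.
#'
#' @param windows Tibble with columns `t_start`, `t_end` (ms), `gain`
#'   (>= 0) and a list-column `pattern` of numeric matrices
#'   (stimuli x latent dimensions).
#' @param persistence Non-negative scalar: fraction of each window's gain
#'   that survives after the window closes. An optional `persistence` column
#'   in `windows` overrides this default per window (use it to let only the
#'   early representation persist, the canonical patient abnormality).
#' @param noise_sd Positive scalar, standard deviation of the additive
#'   sensor noise.
#' @param noise_ar AR(1) coefficient in \[0, 1) for temporally correlated
#'   noise; 0 (default) gives i.i.d. Gaussian noise.
#' @param fade_ms Cross-fade duration at window edges (ms).
#' @return A list of class `geometry_schedule`.
#' @seealso [random_geometry()] for a seeded random schedule,
#'   [sim_epochs()] to realize it as data.
#' @export
geometry_schedule <- function(windows, persistence = 0, noise_sd = 1,
                              noise_ar = 0, fade_ms = 20) {
  stopifnot(
    is.data.frame(windows),
    all(c("t_start", "t_end", "gain", "pattern") %in% names(windows))
  )
  if (any(windows$gain < 0)) stop("window gains must be >= 0")
  if (any(windows$t_end <= windows$t_start)) stop("each window needs t_end > t_start")
  if (persistence < 0) stop("persistence must be >= 0")
  if (!"persistence" %in% names(windows)) windows$persistence <- NA_real_
  if (any(windows$persistence < 0, na.rm = TRUE)) stop("persistence must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (noise_ar < 0 || noise_ar >= 1) stop("noise_ar must be in [0, 1)")
  n_stim <- vapply(windows$pattern, nrow, integer(1))
  if (length(unique(n_stim)) > 1) stop("all window patterns must have the same number of rows")
  structure(
    list(
      windows = tibble::as_tibble(windows), persistence = persistence,
      noise_sd = noise_sd, noise_ar = noise_ar, fade_ms = fade_ms
    ),
    class = "geometry_schedule"
  )
}

#' Random geometry schedule for a catalog
#'
#' Convenience constructor: each window gets an independent standard-normal
#' latent pattern (one row per catalog stimulus).
#'
#' @param catalog A [sim_catalog()] tibble.
#' @param windows Tibble with `t_start`, `t_end`, `gain` (no `pattern`
#'   column; patterns are drawn here).
#' @param latent_dim Latent dimensionality of each window's pattern.
#' @param seed Integer seed for the pattern draws.
#' @inheritParams geometry_schedule
#' @export
random_geometry <- function(catalog, windows, latent_dim = 5, seed = 1,
                            persistence = 0, noise_sd = 1, noise_ar = 0) {
  assert_catalog(catalog)
  n <- nrow(catalog)
  patterns <- withr::with_seed(seed, {
    purrr::map(seq_len(nrow(windows)), function(i) {
      matrix(stats::rnorm(n * latent_dim), n, latent_dim)
    })
  })
  geometry_schedule(
    dplyr::mutate(tibble::as_tibble(windows), pattern = patterns),
    persistence = persistence, noise_sd = noise_sd, noise_ar = noise_ar
  )
}

#' Simulation configuration
#'
#' Bundles everything [sim_epochs()] needs. Defaults mirror the study design
#' this package emulates: a one-back stream with repetition probability 0.1,
#' 128-channel recordings downsampled to 256 Hz, epochs from -200 to
#' 1100 ms, and roughly 60 trials per stimulus (~3,200 trials over 49
#' stimuli across two sessions).
#'
#' @param catalog Stimulus catalog ([sim_catalog()]).
#' @param schedule Geometry schedule ([geometry_schedule()]).
#' @param n_trials_per_stimulus Non-repeat trials per stimulus.
#' @param n_channels Number of sensor channels.
#' @param sampling_rate Hz.
#' @param epoch_window `c(tmin_ms, tmax_ms)` relative to stimulus onset;
#'   samples are taken on the half-open interval `[tmin, tmax)`.
#' @param repeat_probability Probability that a one-back repetition trial is
#'   inserted after any trial; repeats are flagged, not counted against
#'   `n_trials_per_stimulus`.
#' @param seed Integer master seed; identical config + seed reproduces the
#'   simulated arrays bit for bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(catalog, schedule, n_trials_per_stimulus = 60,
                       n_channels = 128, sampling_rate = 256,
                       epoch_window = c(-200, 1100),
                       repeat_probability = 0.1, seed = 1L) {
  assert_catalog(catalog)
  if (!inherits(schedule, "geometry_schedule")) stop("schedule must be a geometry_schedule")
  if (n_trials_per_stimulus < 1 || n_channels < 1 || sampling_rate <= 0) {
    stop("counts and sampling rate must be positive")
  }
  if (repeat_probability < 0 || repeat_probability >= 1) {
    stop("repeat_probability must be in [0, 1)")
  }
  if (epoch_window[2] <= epoch_window[1]) stop("epoch_window must be increasing")
  w <- schedule$windows
  if (any(w$t_start < epoch_window[1]) || any(w$t_end > epoch_window[2])) {
    stop("schedule windows must lie within the epoch window")
  }
  if (nrow(w$pattern[[1]]) != nrow(catalog)) {
    stop("schedule patterns have ", nrow(w$pattern[[1]]), " rows but catalog has ",
         nrow(catalog), " stimuli")
  }
  latent_total <- sum(vapply(w$pattern, ncol, integer(1)))
  if (latent_total > n_channels) {
    stop("total latent dimensionality (", latent_total,
         ") exceeds n_channels (", n_channels, ")")
  }
  structure(
    list(
      catalog = catalog, schedule = schedule,
      n_trials_per_stimulus = as.integer(n_trials_per_stimulus),
      n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
      epoch_window = epoch_window, repeat_probability = repeat_probability,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

epoch_time_axis <- function(epoch_window, sampling_rate) {
  # half-open [tmin, tmax): onset sample included at t = 0
  k0 <- ceiling(epoch_window[1] * sampling_rate / 1000)
  k1 <- ceiling(epoch_window[2] * sampling_rate / 1000) - 1
  (k0:k1) * 1000 / sampling_rate
}

# gain profile of one window over the time axis: linear ramps of fade_ms at
# both edges, sustained persistence*gain tail after the window
window_gain <- function(time_ms, t_start, t_end, gain, persistence, fade_ms) {
  g <- numeric(length(time_ms))
  rise <- time_ms >= t_start & time_ms < t_start + fade_ms
  on <- time_ms >= t_start + fade_ms & time_ms <= t_end
  fall <- time_ms > t_end & time_ms < t_end + fade_ms
  tail <- time_ms >= t_end + fade_ms
  g[rise] <- (time_ms[rise] - t_start) / fade_ms
  g[on] <- 1
  frac <- (time_ms[fall] - t_end) / fade_ms
  g[fall] <- 1 + frac * (persistence - 1)
  g[tail] <- persistence
  g * gain
}

# seeded random orthonormal mixing (rows orthonormal), latent_total x channels
mixing_matrix <- function(latent_total, n_channels, seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(n_channels * latent_total), n_channels, latent_total)))
    t(q)
  })
}

#' Noise-free expected sensor topographies
#'
#' Returns the deterministic part of the simulated signal: for each stimulus
#' and timepoint, the sensor pattern that [sim_epochs()] adds noise to.
#' Useful for ground-truth checks: because the latent-to-sensor mixing is
#' orthonormal, pairwise distances between stimuli in sensor space equal the
#' gain-weighted distances between latent pattern rows.
#'
#' @param config A [sim_config()].
#' @return Array `stimuli x channels x timepoints` with attribute `time_ms`.
#' @export
sim_expected_topographies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  time_ms <- epoch_time_axis(config$epoch_window, config$sampling_rate)
  n_stim <- nrow(config$catalog)
  n_ch <- config$n_channels
  w <- config$schedule$windows
  dims <- vapply(w$pattern, ncol, integer(1))
  mix <- mixing_matrix(sum(dims), n_ch, config$seed)
  offsets <- cumsum(c(0, dims))
  e <- array(0, c(n_stim, n_ch, length(time_ms)))
  for (i in seq_len(nrow(w))) {
    pers <- if (is.na(w$persistence[i])) config$schedule$persistence else w$persistence[i]
    g <- window_gain(
      time_ms, w$t_start[i], w$t_end[i], w$gain[i],
      pers, config$schedule$fade_ms
    )
    if (all(g == 0)) next
    sensor <- w$pattern[[i]] %*% mix[(offsets[i] + 1):offsets[i + 1], , drop = FALSE]
    active <- which(g != 0)
    for (t in active) e[, , t] <- e[, , t] + g[t] * sensor
  }
  attr(e, "time_ms") <- time_ms
  e
}

#' Simulate an epoched EEG data set
#'
#' Realizes a [sim_config()] as a one-back trial stream: a balanced,
#' shuffled sequence of non-repeat trials with repetition trials inserted at
#' the configured probability (flagged in `repeat_flag`). Each trial is the
#' stimulus's expected topography plus Gaussian sensor noise (optionally
#' AR(1)-correlated over time).
#'
#' @param config A [sim_config()].
#' @return An object of class `epoch_set`: list with `data`
#'   (trials x channels x timepoints), `time_ms`, `labels` (stimulus ids),
#'   `repeat_flag`, `sampling_rate`, `catalog`, `seed`.
#' @export
sim_epochs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  e <- sim_expected_topographies(config)
  time_ms <- attr(e, "time_ms")
  n_stim <- nrow(config$catalog)
  n_ch <- config$n_channels
  n_t <- length(time_ms)
  sch <- config$schedule

  withr::with_seed(config$seed + 1L, {
    base <- sample(rep(config$catalog$stimulus_id, config$n_trials_per_stimulus))
    is_rep <- stats::runif(length(base)) < config$repeat_probability
    labels <- integer(0)
    repeat_flag <- logical(0)
    for (i in seq_along(base)) {
      labels <- c(labels, base[i])
      repeat_flag <- c(repeat_flag, FALSE)
      if (is_rep[i]) {
        labels <- c(labels, base[i])
        repeat_flag <- c(repeat_flag, TRUE)
      }
    }
    n_trials <- length(labels)
    noise <- array(stats::rnorm(n_trials * n_ch * n_t, sd = sch$noise_sd),
                   c(n_trials, n_ch, n_t))
    if (sch$noise_ar > 0) {
      phi <- sch$noise_ar
      scale_innov <- sqrt(1 - phi^2)
      noise[, , 1] <- noise[, , 1]
      for (t in 2:n_t) noise[, , t] <- phi * noise[, , t - 1] + scale_innov * noise[, , t]
    }
    data <- e[labels + 1L, , , drop = FALSE] + noise
    new_epoch_set(data, time_ms, labels, repeat_flag, config$sampling_rate,
                  config$catalog, config$seed)
  })
}

new_epoch_set <- function(data, time_ms, labels, repeat_flag, sampling_rate,
                          catalog = NULL, seed = NA_integer_) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(labels),
            dim(data)[3] == length(time_ms), length(repeat_flag) == length(labels))
  if (is.unsorted(time_ms, strictly = TRUE)) stop("time axis must be strictly increasing")
  structure(
    list(data = data, time_ms = time_ms, labels = as.integer(labels),
         repeat_flag = repeat_flag, sampling_rate = sampling_rate,
         catalog = catalog, seed = seed),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d timepoints (%.4g..%.4g ms @ %g Hz)\n  %d stimuli, %d repetition trials\n",
    d[1], d[2], d[3], min(x$time_ms), max(x$time_ms), x$sampling_rate,
    length(unique(x$labels)), sum(x$repeat_flag)
  ))
  invisible(x)
}

#' Simulate model feature matrices
#'
#' Generates a stimuli x features matrix whose representational structure
#' interpolates between exemplar-unique (`abstraction = 0`: i.i.d. features,
#' no categorical structure) and fully category-clustered (`abstraction = 1`:
#' every stimulus collapses onto its category prototype). These matrices
#' stand in for layer activations of vision networks (low layers ~ low
#' abstraction, top layers ~ high) and for caption-level semantic
#' embeddings.
#'
#' @param catalog Stimulus catalog.
#' @param abstraction Scalar in \[0, 1\].
#' @param n_features Feature dimensionality (e.g. 512 for sentence
#'   embeddings).
#' @param seed Integer seed.
#' @return Numeric matrix `nrow(catalog) x n_features`, rownames =
#'   stimulus ids.
#' @export
sim_model_features <- function(catalog, abstraction, n_features = 128, seed = 1L) {
  assert_catalog(catalog)
  if (abstraction < 0 || abstraction > 1) stop("abstraction must be in [0, 1]")
  if (n_features < 1) stop("n_features must be positive")
  n <- nrow(catalog)
  withr::with_seed(seed, {
    cats <- as.character(catalog$category)
    protos <- matrix(stats::rnorm(length(unique(cats)) * n_features),
                     length(unique(cats)), n_features,
                     dimnames = list(unique(cats), NULL))
    exemplar <- matrix(stats::rnorm(n * n_features), n, n_features)
    out <- abstraction * protos[cats, , drop = FALSE] + (1 - abstraction) * exemplar
    rownames(out) <- catalog$stimulus_id
    out
  })
}

#' Simulate a behavioral table
#'
#' One row per participant: one-back accuracy and median RT for face and
#' non-face trials plus a global face-recognition score (CFMT+-like, out of
#' 102). Controls are split into a young and an age-matched subgroup (15 + 3
#' at the default n of 18). The patient's face-specific measures (face
#' accuracy, face RT, recognition score) are shifted by
#' `patient_face_deficit` control standard deviations; negative values mean
#' a deficit.
#'
#' @param n_controls Number of controls (>= 2).
#' @param patient_face_deficit Effect size in control-sd units applied to
#'   the patient's face-specific measures.
#' @param seed Integer seed.
#' @return Tibble with columns `participant_id`, `group` (patient /
#'   control_young / control_matched), `face_acc`, `nonface_acc`, `face_rt`,
#'   `nonface_rt`, `cfmt_score`.
#' @export
sim_behavior <- function(n_controls = 18, patient_face_deficit = 0, seed = 1L) {
  if (n_controls < 2) stop("need at least 2 controls")
  sd_acc <- 0.04; sd_rt <- 40; sd_cfmt <- 7
  n_matched <- max(1L, round(n_controls / 6))
  withr::with_seed(seed, {
    n <- n_controls + 1L
    tb <- tibble::tibble(
      participant_id = c("patient", sprintf("control%02d", seq_len(n_controls))),
      group = c("patient",
                rep("control_young", n_controls - n_matched),
                rep("control_matched", n_matched)),
      face_acc = pmin(1, pmax(0, stats::rnorm(n, 0.90, sd_acc))),
      nonface_acc = pmin(1, pmax(0, stats::rnorm(n, 0.92, sd_acc))),
      face_rt = stats::rnorm(n, 520, sd_rt),
      nonface_rt = stats::rnorm(n, 510, sd_rt),
      cfmt_score = pmin(102, pmax(0, stats::rnorm(n, 88, sd_cfmt)))
    )
    d <- patient_face_deficit
    tb$face_acc[1] <- min(1, max(0, tb$face_acc[1] + d * sd_acc))
    tb$face_rt[1] <- tb$face_rt[1] - d * sd_rt
    tb$cfmt_score[1] <- min(102, max(0, tb$cfmt_score[1] + d * sd_cfmt))
    tb
  })
}
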