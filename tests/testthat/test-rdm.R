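test_that("pair counting and the pair index are consistent", {
  expect_equal(pair_count(49), 1176)
  expect_equal(pair_count(2), 1)
  expect_equal(pair_count(10), 45)
  expect_error(pair_count(1), ">= 2")

  pi5 <- pair_index(5)
  expect_equal(nrow(pi5), 10)
  expect_true(all(pi5$i < pi5$j))
  # row-major upper triangle order
  expect_equal(pi5$i[1:4], rep(0L, 4))
  expect_equal(pi5$j[1:4], 1:4)
  expect_equal(nrow(dplyr::distinct(pi5)), 10)
})

test_that("compiled decoding matches the brute-force oracle on tiny toys", {
  # fixed 2-feature toy, 4 trials per class, plus random toys
  toys <- list(
    list(
      xa = array(c(0.1, 0.3, -0.2, 0.4, 1.0, 1.2, 0.8, 1.1), c(4, 2, 1)),
      xb = array(c(0.9, 1.1, 0.7, 1.3, -0.1, 0.2, 0.05, -0.3), c(4, 2, 1))
    )
  )
  toys <- c(toys, withr::with_seed(99, lapply(1:5, function(i) {
    list(xa = array(rnorm(8 * 3 * 2), c(8, 3, 2)),
         xb = array(rnorm(8 * 3 * 2), c(8, 3, 2)))
  })))
  for (toy in toys) {
    n <- dim(toy$xa)[1]
    folds <- 2; reps <- 2
    fa <- withr::with_seed(1, casersa:::fold_assignments(n, folds, reps))
    fb <- withr::with_seed(2, casersa:::fold_assignments(n, folds, reps))
    got <- casersa:::decode_pair_cpp(toy$xa, toy$xb, fa, fb, folds)
    for (t in seq_len(dim(toy$xa)[3])) {
      want <- oracle_decode_timepoint(
        toy$xa[, , t, drop = FALSE][, , 1], toy$xb[, , t, drop = FALSE][, , 1],
        fa, fb, folds
      )
      expect_equal(got[t], want, tolerance = 1e-12)
    }
  }
})

test_that("decoding is perfect for separated noiseless patterns and chance-level under the null", {
  # noiseless: expected AUC saturates at 1 inside the window
  cat2 <- sim_catalog(n_faces = 0, n_nonfaces = c(animal = 2))
  pat <- matrix(c(1, 0, 0, 1), 2, 2)
  geo <- geometry_schedule(
    tibble::tibble(t_start = 100, t_end = 400, gain = 5, pattern = list(pat)),
    noise_sd = 1e-6
  )
  cfg <- sim_config(cat2, geo, n_trials_per_stimulus = 10, n_channels = 4,
                    sampling_rate = 64, repeat_probability = 0, seed = 2)
  tc <- decode_pair_timecourse(sim_epochs(cfg), 0, 1, seed = 3)
  expect_true(all(tc$auc[tc$time_ms > 130 & tc$time_ms < 380] == 1))

  # pure noise: mean AUC within 3 SE of 0.5. Noise is independent across
  # timepoints, so per-timepoint grand means are the natural units for the
  # standard error (pairs within a timepoint share trials and correlate).
  nf <- null_fixture()
  per_time <- rowMeans(nf$rdm$values)
  se <- sd(per_time) / sqrt(length(per_time))
  expect_lt(abs(mean(per_time) - 0.5), 3 * se)
})

test_that("decoding is symmetric in the pair and invariant to trial order", {
  f <- signal_fixture()
  a <- decode_pair_timecourse(f$epochs, 2, 4, seed = 9)
  b <- decode_pair_timecourse(f$epochs, 4, 2, seed = 9)
  expect_identical(a$auc, b$auc)

  # permuting stored trial order leaves the RDM series unchanged
  perm <- withr::with_seed(13, sample(dim(f$epochs$data)[1]))
  ep_perm <- f$epochs
  ep_perm$data <- f$epochs$data[perm, , , drop = FALSE]
  ep_perm$labels <- f$epochs$labels[perm]
  ep_perm$repeat_flag <- f$epochs$repeat_flag[perm]
  rdm_perm <- compute_rdm_series(ep_perm, time_range = c(-200, 800), seed = 31)
  expect_identical(f$rdm$values, rdm_perm$values)
})

test_that("shuffling labels within a pair drives AUC to chance", {
  f <- signal_fixture()
  ep <- f$epochs
  sel <- ep$labels %in% c(0, 1) & !ep$repeat_flag
  ep$labels[sel] <- withr::with_seed(8, sample(ep$labels[sel]))
  tc <- decode_pair_timecourse(ep, 0, 1, seed = 12)
  se <- sd(tc$auc) / sqrt(nrow(tc))
  expect_lt(abs(mean(tc$auc) - 0.5), max(3 * se, 0.03))
})

test_that("stronger pattern separation never lowers in-window decodability", {
  cat2 <- sim_catalog(n_faces = 0, n_nonfaces = c(animal = 2))
  pat <- matrix(c(1, 0, 0, 1), 2, 2)
  mean_auc <- function(gain) {
    geo <- geometry_schedule(
      tibble::tibble(t_start = 100, t_end = 400, gain = gain, pattern = list(pat)),
      noise_sd = 1
    )
    cfg <- sim_config(cat2, geo, n_trials_per_stimulus = 30, n_channels = 4,
                      sampling_rate = 64, repeat_probability = 0, seed = 6)
    tc <- decode_pair_timecourse(sim_epochs(cfg), 0, 1, seed = 7)
    mean(tc$auc[tc$time_ms > 130 & tc$time_ms < 380])
  }
  aucs <- vapply(c(0.3, 1, 3), mean_auc, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("RDM series enforces trial and stimulus availability", {
  f <- signal_fixture()
  missing_cat <- sim_catalog(n_faces = 0, n_nonfaces = c(animal = 3, object = 3, scene = 1))
  expect_error(compute_rdm_series(f$epochs, catalog = missing_cat), "absent")
  expect_error(decode_pair_timecourse(f$epochs, 0, 0), "must differ")
})

test_that("pair subsets partition the full pair set with the documented counts", {
  cat49 <- sim_catalog()
  pairs <- pair_index(49)
  values <- matrix(runif(3 * 1176, 0.4, 0.6), 3, 1176)
  rdm <- casersa:::new_rdm_series(values, c(0, 4, 8), pairs, 5, 5, cat49)

  ff <- subset_pairs(rdm, "face_face")
  fn <- subset_pairs(rdm, "face_nonface")
  nn <- subset_pairs(rdm, "nonface_nonface")
  expect_equal(ncol(ff$values), 276)
  expect_equal(ncol(fn$values), 600)
  expect_equal(ncol(nn$values), 300)
  expect_equal(ncol(ff$values) + ncol(fn$values) + ncol(nn$values), 1176)
  expect_identical(subset_pairs(rdm, "all"), rdm)
  # subsets are disjoint: each pair lands in exactly one
  all_pairs <- dplyr::bind_rows(ff$pairs, fn$pairs, nn$pairs)
  expect_equal(nrow(dplyr::distinct(all_pairs)), 1176)
})

test_that("repetition trials are excluded from decoding by default", {
  f <- signal_fixture()
  with_reps <- decode_pair_timecourse(f$epochs, 0, 1, seed = 5, exclude_repeats = FALSE)
  without <- decode_pair_timecourse(f$epochs, 0, 1, seed = 5, exclude_repeats = TRUE)
  # both are valid AUC series but computed on different trial sets
  expect_false(identical(with_reps$auc, without$auc))
  expect_true(all(without$auc >= 0 & without$auc <= 1))
})
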