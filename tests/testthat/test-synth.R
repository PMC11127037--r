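test_that("default catalog reproduces the 49-stimulus structure", {
  cat49 <- sim_catalog()
  expect_equal(nrow(cat49), 49)
  expect_equal(sum(cat49$category == "face"), 24)
  expect_equal(length(unique(cat49$face_identity[cat49$category == "face"])), 8)
  expect_equal(sum(cat49$face_gender == "female", na.rm = TRUE), 12) # 4 female identities x 3 expressions
  expect_identical(cat49$stimulus_id, 0:48)
  # face attributes present iff face
  is_face <- cat49$category == "face"
  expect_true(all(!is.na(cat49$face_identity[is_face])))
  expect_true(all(is.na(cat49$face_identity[!is_face])))
  expect_true(all(is.na(cat49$face_expression[!is_face])))
})

test_that("catalog handles degenerate and small configurations", {
  tiny <- sim_catalog(n_faces = 0, n_nonfaces = c(scene = 2))
  expect_equal(nrow(tiny), 2)
  expect_equal(sum(tiny$category == "face"), 0)

  small <- sim_catalog(n_faces = 6, n_nonfaces = c(scene = 2))
  expect_equal(nrow(small), 8)
  expect_equal(sum(!is.na(small$face_expression)), 6)
  expect_equal(length(unique(small$face_identity[small$category == "face"])), 2)

  expect_error(sim_catalog(n_faces = 5), "divisible")
  expect_error(sim_catalog(n_faces = 0, n_nonfaces = c(tree = 3)), "unknown")
})

test_that("identical config and seed reproduce epochs bit for bit", {
  f <- signal_fixture()
  ep2 <- sim_epochs(f$config)
  expect_identical(f$epochs$data, ep2$data)
  expect_identical(f$epochs$labels, ep2$labels)
  # different seed changes the data
  cfg2 <- f$config; cfg2$seed <- f$config$seed + 1L
  expect_false(identical(sim_epochs(cfg2)$data, f$epochs$data))
})

test_that("noiseless expected topographies preserve the latent pattern geometry", {
  f <- signal_fixture()
  e <- sim_expected_topographies(f$config)
  time_ms <- attr(e, "time_ms")
  t_mid <- which.min(abs(time_ms - 200)) # inside window 1, full gain
  sensor_d <- as.numeric(dist(e[, , t_mid]))
  latent_d <- as.numeric(dist(f$geometry$windows$pattern[[1]]))
  expect_gt(cor(sensor_d, latent_d, method = "spearman"), 0.99)
  # orthonormal mixing preserves Euclidean distances exactly
  expect_equal(sensor_d, latent_d * f$geometry$windows$gain[1], tolerance = 1e-9)
})

test_that("persistence raises early-by-late TGM correlation at matched seeds", {
  cat6 <- tiny_catalog()
  win <- tibble::tibble(t_start = c(80, 400), t_end = c(200, 700), gain = c(1, 1))
  mean_early_late <- function(persistence) {
    geo <- random_geometry(cat6, win, latent_dim = 4, seed = 5,
                           persistence = persistence, noise_sd = 0.7)
    cfg <- sim_config(cat6, geo, n_trials_per_stimulus = 24, n_channels = 10,
                      sampling_rate = 64, seed = 77)
    rdm <- compute_rdm_series(sim_epochs(cfg), time_range = c(0, 800), seed = 7)
    g <- compute_tgm(rdm, time_range = c(0, 800))
    early <- g$time_ms >= 80 & g$time_ms <= 200
    late <- g$time_ms >= 400 & g$time_ms <= 700
    mean(g$values[early, late])
  }
  expect_gt(mean_early_late(0.6), mean_early_late(0))
})

test_that("window validation rejects schedules outside the epoch", {
  cat6 <- tiny_catalog()
  geo <- random_geometry(cat6, tibble::tibble(t_start = 900, t_end = 1200, gain = 1),
                         latent_dim = 3, seed = 1)
  expect_error(sim_config(cat6, geo, epoch_window = c(-200, 1100)), "within the epoch")
  geo2 <- random_geometry(cat6, tibble::tibble(t_start = 100, t_end = 300, gain = 1),
                          latent_dim = 20, seed = 1)
  expect_error(sim_config(cat6, geo2, n_channels = 10), "latent dimensionality")
})

test_that("model features interpolate between exemplar-unique and category-clustered", {
  cat49 <- sim_catalog()
  # abstraction = 1: clustered by category
  f1 <- sim_model_features(cat49, abstraction = 1, n_features = 64, seed = 3)
  r1 <- rdm_from_features(f1, "one_minus_pearson")
  is_face <- cat49$category == "face"
  same_cat <- as.character(cat49$category)[r1$pairs$i + 1] ==
    as.character(cat49$category)[r1$pairs$j + 1]
  expect_lt(mean(r1$values[same_cat]), mean(r1$values[!same_cat]))

  # abstraction = 0: no categorical structure (Monte-Carlo over seeds)
  multihot <- categorical_rdm(cat49, c("category", "face_gender", "face_expression"))
  rhos <- vapply(1:50, function(s) {
    f0 <- sim_model_features(cat49, abstraction = 0, n_features = 64, seed = s)
    spearman_rdm(rdm_from_features(f0)$values, multihot$values)
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)

  expect_equal(dim(sim_model_features(cat49, 0.5, n_features = 512, seed = 1)), c(49, 512))
  expect_error(sim_model_features(cat49, abstraction = 2), "abstraction")
})

test_that("behavioral generator calibrates the Crawford-Howell test on the face score", {
  # deficit of -8 control SDs with 18 controls: essentially always detected
  hits <- vapply(1:40, function(s) {
    tb <- sim_behavior(18, patient_face_deficit = -8, seed = s)
    fs <- face_specific_score(tb)
    pat <- tb$group == "patient"
    ch <- crawford_howell(fs$scores$pc_score[pat], fs$scores$pc_score[!pat])
    (ch$p < 0.05) && (ch$t < 0)
  }, logical(1))
  expect_gt(mean(hits), 0.99)

  # a single draw reports df = 17 with 18 controls
  tb <- sim_behavior(18, 0, seed = 1)
  pat <- tb$group == "patient"
  expect_identical(crawford_howell(tb$cfmt_score[pat], tb$cfmt_score[!pat])$df, 17L)
  # default subgrouping gives the 15 + 3 control split
  expect_equal(sum(tb$group == "control_young"), 15)
  expect_equal(sum(tb$group == "control_matched"), 3)
})

test_that("null behavioral generator keeps the type-I error near nominal", {
  # patient drawn from the control distribution: ~5% false positives
  pvals <- vapply(1:1000, function(s) {
    tb <- sim_behavior(18, patient_face_deficit = 0, seed = s)
    fs <- face_specific_score(tb)
    pat <- tb$group == "patient"
    crawford_howell(fs$scores$pc_score[pat], fs$scores$pc_score[!pat])$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  # binomial 3*SE band around 0.05 at 1000 replicates, plus slack for the
  # patient entering the PCA basis
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
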