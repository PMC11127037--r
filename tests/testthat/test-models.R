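test_that("feature-space RDMs match hand-computed dissimilarities", {
  # identical rows: dissimilarity 0
  f <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 1, 2))
  r <- rdm_from_features(f, "one_minus_pearson")
  expect_equal(r$values[1], 0, tolerance = 1e-12)

  # perfectly anticorrelated rows: 1 - (-1) = 2
  f2 <- rbind(c(1, -1, 2), -c(1, -1, 2))
  expect_equal(rdm_from_features(f2, "one_minus_pearson")$values, 2, tolerance = 1e-12)

  # cosine toy: [[1,0],[0,1],[1,1]] -> (1, 1 - 1/sqrt(2), 1 - 1/sqrt(2))
  f3 <- rbind(c(1, 0), c(0, 1), c(1, 1))
  r3 <- rdm_from_features(f3, "cosine_distance")
  expect_equal(r3$values, c(1, 1 - 1 / sqrt(2), 1 - 1 / sqrt(2)), tolerance = 1e-12)

  f4 <- rbind(c(2, 2, 2), c(1, 2, 3))
  expect_error(rdm_from_features(f4, "one_minus_pearson"), "constant feature row")
  expect_error(rdm_from_features(rbind(c(0, 0), c(1, 1)), "cosine_distance"), "zero-norm")
})

test_that("categorical RDMs encode catalog dimensions as binary codes", {
  cat49 <- sim_catalog()
  one <- categorical_rdm(cat49, "category", encoding = "onehot")
  # exactly 2 distinct values: same category vs different category
  expect_equal(length(unique(one$values)), 2)
  same_cat <- as.character(cat49$category)[one$pairs$i + 1] ==
    as.character(cat49$category)[one$pairs$j + 1]
  expect_true(all(one$values[same_cat] == 0))
  expect_true(all(one$values[!same_cat] > 0))
  expect_equal(unique(one$values[!same_cat]), sqrt(2))

  # multihot over category + gender: different-gender faces farther apart
  multi <- categorical_rdm(cat49, c("category", "face_gender"))
  faces <- which(cat49$category == "face") - 1
  same_gender <- multi$pairs$i %in% faces & multi$pairs$j %in% faces &
    cat49$face_gender[multi$pairs$i + 1] == cat49$face_gender[multi$pairs$j + 1]
  diff_gender <- multi$pairs$i %in% faces & multi$pairs$j %in% faces & !same_gender
  expect_gt(min(multi$values[diff_gender]), max(multi$values[same_gender]))

  ham <- categorical_rdm(cat49, "category", encoding = "onehot", distance = "hamming")
  expect_equal(sort(unique(ham$values)), c(0, 2))
  expect_error(categorical_rdm(cat49, "colour"), "unknown catalog dimension")
  expect_error(categorical_rdm(cat49, c("category", "animacy"), encoding = "onehot"),
               "exactly one")
})

test_that("spearman_rdm follows rank-correlation arithmetic", {
  a <- c(0.2, 0.5, 0.9, 1.4)
  expect_equal(spearman_rdm(a, a), 1)
  expect_equal(spearman_rdm(a, rev(a)), -1)
  expect_equal(spearman_rdm(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8, tolerance = 1e-12)
  expect_warning(out <- spearman_rdm(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(out))
  expect_error(spearman_rdm(1:4, 1:5), "length")
})

test_that("partial Spearman matches the rank-residualization oracle", {
  # fixed 6-element vectors
  a <- c(3.2, 1.1, 4.8, 2.2, 5.9, 0.4)
  b <- c(2.0, 1.5, 3.9, 2.8, 5.1, 1.0)
  ctl <- c(1.0, 2.5, 3.1, 0.7, 4.4, 2.2)
  expect_equal(partial_spearman_rdm(a, b, ctl),
               oracle_partial_spearman(a, b, ctl), tolerance = 1e-12)

  # random instances, including ties from rounding
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- round(rnorm(12), 1); y <- round(rnorm(12), 1); z <- round(rnorm(12), 1)
      if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) next
      expect_equal(partial_spearman_rdm(x, y, z),
                   oracle_partial_spearman(x, y, z), tolerance = 1e-12)
    }
  })

  # constant control: reduces to plain Spearman
  expect_equal(partial_spearman_rdm(a, b, rep(1, 6)), spearman_rdm(a, b))
  # b identical to control: nothing left to explain
  expect_warning(out <- partial_spearman_rdm(a, b, b), "collinear")
  expect_true(is.na(out))
  # control rank-uncorrelated with both inputs ~ plain Spearman
  a2 <- c(1, 2, 3, 4); b2 <- c(1, 3, 2, 4); c2 <- c(2, 4, 1, 3)
  if (abs(cor(rank(a2), rank(c2))) < 1e-12 && abs(cor(rank(b2), rank(c2))) < 1e-12) {
    expect_equal(partial_spearman_rdm(a2, b2, c2), spearman_rdm(a2, b2), tolerance = 1e-12)
  }
})

test_that("model timecourses recover injected structure and enforce pair alignment", {
  withr::with_seed(17, {
    n_pairs <- 15
    pairs <- pair_index(6)
    v <- matrix(runif(4 * n_pairs), 4, n_pairs)
    rdm <- casersa:::new_rdm_series(v, c(0, 10, 20, 30), pairs, 5, 5, NULL)
    model <- casersa:::new_model_rdm(v[3, ], pairs, "one_minus_pearson", "probe")
    tc <- model_timecourse(rdm, model)
    expect_s3_class(tc, "model_timecourse")
    expect_equal(tc$rho[3], 1, tolerance = 1e-12)
    expect_equal(which.max(tc$rho), 3)

    # misaligned pair index is refused
    bad <- casersa:::new_model_rdm(runif(10), pair_index(5), "one_minus_pearson", "bad")
    expect_error(model_timecourse(rdm, bad), "misalignment")

    # pure-noise brain RDMs: mean rho within 3 SE of 0
    vn <- matrix(runif(60 * n_pairs), 60, n_pairs)
    rdm_n <- casersa:::new_rdm_series(vn, seq(0, 590, 10), pairs, 5, 5, NULL)
    tcn <- model_timecourse(rdm_n, model)
    se <- sd(tcn$rho) / sqrt(nrow(tcn))
    expect_lt(abs(mean(tcn$rho)), 3 * se)
  })
})

test_that("timecourse case contrast is null at the control mean and carries df metadata", {
  withr::with_seed(23, {
    pairs <- pair_index(6)
    mk <- function(seed) {
      v <- withr::with_seed(seed, matrix(runif(5 * 15), 5, 15))
      rdm <- casersa:::new_rdm_series(v, seq(0, 40, 10), pairs, 5, 5, NULL)
      model <- casersa:::new_model_rdm(withr::with_seed(1000, runif(15)), pairs,
                                       "one_minus_pearson", "m")
      model_timecourse(rdm, model, subject = paste0("s", seed))
    }
    controls <- lapply(1:19, mk)
    ct <- timecourse_case_contrast(controls[[1]], controls[-1])
    expect_identical(unique(ct$df), 17L)

    patient <- controls[[1]]
    patient$rho <- rowMeans(vapply(controls[-1], `[[`, numeric(5), "rho"))
    ct0 <- timecourse_case_contrast(patient, controls[-1])
    expect_lt(max(abs(ct0$t)), 1e-8)
    expect_equal(sum(ct0$significant), 0)

    bad <- controls[[2]]
    bad$time_ms <- bad$time_ms + 1
    expect_error(timecourse_case_contrast(controls[[1]], list(bad, controls[[3]])),
                 "time axis")
  })
})
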