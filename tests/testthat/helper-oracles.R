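# Independent oracles and shared fixtures. Oracles re-derive results from
# first principles (explicit sums, residualization, enumeration) and never
# call the implementation they check.

fixture_env <- new.env(parent = emptyenv())
get_fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) assign(name, build(), envir = fixture_env)
  get(name, envir = fixture_env)
}

# Mann-Whitney AUC by direct pair counting
oracle_auc <- function(scores_a, scores_b) {
  s <- 0
  for (x in scores_a) for (y in scores_b) {
    s <- s + (y > x) + 0.5 * (y == x)
  }
  s / (length(scores_a) * length(scores_b))
}

# Fisher direction with Ledoit-Wolf shrinkage toward nu*I, written as
# explicit elementwise sums
oracle_fisher_w <- function(train_a, train_b) {
  ma <- colMeans(train_a); mb <- colMeans(train_b)
  z <- rbind(sweep(train_a, 2, ma), sweep(train_b, 2, mb))
  n <- nrow(z); c <- ncol(z)
  s <- matrix(0, c, c)
  for (i in seq_len(n)) s <- s + tcrossprod(z[i, ])
  s <- s / n
  nu <- sum(diag(s)) / c
  if (nu < 1e-300) {
    sh <- diag(c)
  } else {
    sum4 <- sum(vapply(seq_len(n), function(i) sum(z[i, ]^2)^2, numeric(1)))
    b2 <- sum4 / n^2 - sum(s^2) / n
    dev <- s; diag(dev) <- diag(dev) - nu
    d2 <- sum(dev^2)
    lambda <- if (d2 > 0) min(1, max(0, b2) / d2) else 1
    sh <- (1 - lambda) * s
    diag(sh) <- diag(sh) + lambda * nu + 1e-12 * nu
  }
  solve(sh, mb - ma)
}

# full decode oracle for one timepoint, replaying the package's fold plan
# (fold assignments are plumbing; the decoding math is computed here from
# scratch and compared against the compiled kernel)
oracle_decode_timepoint <- function(xa, xb, folds_a, folds_b, n_folds) {
  reps <- nrow(folds_a)
  rep_aucs <- vapply(seq_len(reps), function(r) {
    fold_aucs <- vapply(seq_len(n_folds), function(f) {
      tr_a <- xa[folds_a[r, ] != f, , drop = FALSE]
      tr_b <- xb[folds_b[r, ] != f, , drop = FALSE]
      te_a <- xa[folds_a[r, ] == f, , drop = FALSE]
      te_b <- xb[folds_b[r, ] == f, , drop = FALSE]
      w <- oracle_fisher_w(tr_a, tr_b)
      oracle_auc(te_a %*% w, te_b %*% w)
    }, numeric(1))
    mean(fold_aucs)
  }, numeric(1))
  mean(rep_aucs)
}

# partial Spearman by rank residualization: rank, OLS-residualize the ranks
# on the control ranks, Pearson on the residuals
oracle_partial_spearman <- function(a, b, control) {
  ra <- rank(a); rb <- rank(b); rc <- rank(control)
  res_a <- stats::residuals(stats::lm(ra ~ rc))
  res_b <- stats::residuals(stats::lm(rb ~ rc))
  stats::cor(res_a, res_b)
}

# exhaustive sign-flip permutation p for the mean
oracle_signflip_p <- function(values) {
  n <- length(values)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stats <- as.numeric(signs %*% values) / n
  mean(stats >= mean(values))
}

# small two-category catalog used across decoding tests
tiny_catalog <- function() {
  sim_catalog(n_faces = 0, n_nonfaces = c(animal = 3, object = 3))
}

# shared simulated data: one 6-stimulus subject with two disjoint windows
signal_fixture <- function() {
  get_fixture("signal_fixture", function() {
    cat6 <- tiny_catalog()
    geo <- random_geometry(
      cat6,
      tibble::tibble(t_start = c(100, 500), t_end = c(300, 700), gain = c(1, 1)),
      latent_dim = 4, seed = 11, noise_sd = 0.8
    )
    cfg <- sim_config(cat6, geo, n_trials_per_stimulus = 26, n_channels = 10,
                      sampling_rate = 64, seed = 21)
    ep <- sim_epochs(cfg)
    rdm <- compute_rdm_series(ep, time_range = c(-200, 800), seed = 31)
    list(catalog = cat6, geometry = geo, config = cfg, epochs = ep, rdm = rdm)
  })
}

# pure-noise counterpart (all gains zero)
null_fixture <- function() {
  get_fixture("null_fixture", function() {
    cat6 <- tiny_catalog()
    geo <- random_geometry(
      cat6, tibble::tibble(t_start = 100, t_end = 300, gain = 0),
      latent_dim = 4, seed = 12, noise_sd = 1
    )
    cfg <- sim_config(cat6, geo, n_trials_per_stimulus = 26, n_channels = 10,
                      sampling_rate = 64, seed = 22)
    ep <- sim_epochs(cfg)
    rdm <- compute_rdm_series(ep, time_range = c(-200, 800), seed = 32)
    list(catalog = cat6, config = cfg, epochs = ep, rdm = rdm)
  })
}
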