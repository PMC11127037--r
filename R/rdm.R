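#' Number of stimulus pairs
#'
#' @param n_stimuli Number of stimuli, >= 2.
#' @return `n * (n - 1) / 2`, e.g. 1176 for 49 stimuli.
#' @export
pair_count <- function(n_stimuli) {
  if (any(n_stimuli < 2)) stop("pair_count() needs n_stimuli >= 2")
  n_stimuli * (n_stimuli - 1) / 2
}

#' Upper-triangle pair index over a stimulus set
#'
#' The canonical ordering of stimulus pairs used by every RDM in the
#' package: row-major upper triangle, `(i, j)` with `i < j` over 0-based
#' stimulus ids. Brain RDMs and model RDMs are aligned by comparing these
#' tables, never by positional trust.
#'
#' @param n_stimuli Number of stimuli.
#' @return Tibble with columns `i`, `j` and `n_stimuli * (n_stimuli - 1) / 2`
#'   rows.
#' @export
pair_index <- function(n_stimuli) {
  if (n_stimuli < 2) stop("need at least 2 stimuli")
  ij <- which(upper.tri(matrix(0, n_stimuli, n_stimuli)), arr.ind = TRUE)
  ord <- order(ij[, "row"], ij[, "col"])
  tibble::tibble(i = as.integer(ij[ord, "row"] - 1L), j = as.integer(ij[ord, "col"] - 1L))
}

# deterministic per-pair seed, symmetric in (a, b); kept below 2^31
pair_seed <- function(seed, a, b) {
  i <- min(a, b); j <- max(a, b)
  as.integer(((seed %% 100000) * 20011 + (i + 1) * 1299709 + (j + 1) * 15485863) %% 2147483629)
}

# canonical trial ordering keyed to trial content, so results do not depend
# on the storage order of the input trials
order_trials_canonically <- function(x) {
  s1 <- apply(x, 1, sum)
  s2 <- apply(x, 1, function(v) sum(v * v))
  order(s1, s2)
}

# stratified fold assignments: repetitions x n matrix of ids in 1..folds
fold_assignments <- function(n, folds, repetitions) {
  t(vapply(seq_len(repetitions), function(r) {
    f <- integer(n)
    f[sample.int(n)] <- rep_len(seq_len(folds), n)
    f
  }, integer(n)))
}

select_pair_trials <- function(epochs, stim, exclude_repeats) {
  keep <- epochs$labels == stim
  if (exclude_repeats) keep <- keep & !epochs$repeat_flag
  which(keep)
}

#' Time-resolved pairwise decoding (cross-validated AUC)
#'
#' Trains, independently at every timepoint, a Fisher linear discriminant
#' distinguishing two stimuli from their single-trial sensor patterns (all
#' channels as features), with stratified k-fold cross-validation repeated
#' several times. The pooled within-class covariance is shrunk toward a
#' scaled identity with analytically chosen (Ledoit-Wolf) intensity, so the
#' discriminant is defined even with more channels than trials. Held-out
#' decision values yield an AUC per fold; AUCs are averaged over folds, then
#' over repetitions.
#'
#' Fold assignments are seeded canonically by the unordered stimulus pair,
#' so `decode_pair_timecourse(e, a, b, ...)` and `(e, b, a, ...)` are
#' exactly equal, and trials are ordered internally by content so the
#' result is invariant to trial storage order. When one stimulus has more
#' usable trials than the other, the larger class is subsampled (seeded) to
#' match.
#'
#' @param epochs An `epoch_set`.
#' @param stim_a,stim_b Stimulus ids to discriminate.
#' @param folds,repetitions Cross-validation plan (defaults 5 and 5).
#' @param seed Master integer seed.
#' @param exclude_repeats Drop one-back repetition trials (default TRUE;
#'   they involve adaptation and key presses).
#' @param time_range Optional `c(tmin, tmax)` ms to restrict the decoded
#'   window.
#' @return Tibble with columns `time_ms` and `auc` (in \[0, 1\]; 0.5 =
#'   indiscriminable).
#' @export
decode_pair_timecourse <- function(epochs, stim_a, stim_b, folds = 5,
                                   repetitions = 5, seed = 1L,
                                   exclude_repeats = TRUE, time_range = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (stim_a == stim_b) stop("stim_a and stim_b must differ")
  tsel <- seq_along(epochs$time_ms)
  if (!is.null(time_range)) {
    tsel <- which(epochs$time_ms >= time_range[1] & epochs$time_ms <= time_range[2])
    if (!length(tsel)) stop("time_range contains no timepoints")
  }
  auc <- decode_pair_raw(epochs, min(stim_a, stim_b), max(stim_a, stim_b),
                         folds, repetitions, seed, exclude_repeats, tsel)
  tibble::tibble(time_ms = epochs$time_ms[tsel], auc = auc)
}

decode_pair_raw <- function(epochs, a, b, folds, repetitions, seed,
                            exclude_repeats, tsel) {
  ia <- select_pair_trials(epochs, a, exclude_repeats)
  ib <- select_pair_trials(epochs, b, exclude_repeats)
  for (s in c(a, b)) {
    nn <- if (s == a) length(ia) else length(ib)
    if (nn < folds) {
      stop("stimulus ", s, " has only ", nn, " usable trials (need >= ", folds, ")")
    }
  }
  xa <- epochs$data[ia, , , drop = FALSE]
  xb <- epochs$data[ib, , , drop = FALSE]
  xa <- xa[order_trials_canonically(xa), , , drop = FALSE]
  xb <- xb[order_trials_canonically(xb), , , drop = FALSE]
  n <- min(dim(xa)[1], dim(xb)[1])
  withr::with_seed(pair_seed(seed, a, b), {
    if (dim(xa)[1] > n) xa <- xa[sort(sample.int(dim(xa)[1], n)), , , drop = FALSE]
    if (dim(xb)[1] > n) xb <- xb[sort(sample.int(dim(xb)[1], n)), , , drop = FALSE]
    fa <- fold_assignments(n, folds, repetitions)
    fb <- fold_assignments(n, folds, repetitions)
    as.numeric(decode_pair_cpp(
      xa[, , tsel, drop = FALSE], xb[, , tsel, drop = FALSE], fa, fb, folds
    ))
  })
}

#' Time-resolved brain representational dissimilarity matrices
#'
#' Runs [decode_pair_timecourse()] for every stimulus pair in the catalog
#' and stacks the AUC timecourses into a timepoints x pairs array: one
#' decoding-based RDM per timepoint, vectorized along the canonical
#' [pair_index()]. Results are deterministic given `seed` and independent of
#' both trial storage order and pair evaluation order.
#'
#' @inheritParams decode_pair_timecourse
#' @param catalog Stimulus catalog; defaults to the one attached to
#'   `epochs`. Every catalog stimulus must be present in the epochs.
#' @param time_range Decoded window in ms (default `c(-200, 800)`).
#' @return Object of class `rdm_series`: list with `values`
#'   (timepoints x pairs AUC matrix), `time_ms`, `pairs` (the pair index
#'   tibble), `n_folds`, `n_repetitions`, `catalog`, `subset`.
#' @export
compute_rdm_series <- function(epochs, catalog = epochs$catalog,
                               time_range = c(-200, 800), folds = 5,
                               repetitions = 5, seed = 1L,
                               exclude_repeats = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(catalog)) stop("no catalog attached to epochs and none supplied")
  assert_catalog(catalog)
  absent <- setdiff(catalog$stimulus_id, unique(epochs$labels))
  if (length(absent)) {
    stop("catalog stimuli absent from epochs: ", paste(absent, collapse = ", "))
  }
  tsel <- which(epochs$time_ms >= time_range[1] & epochs$time_ms <= time_range[2])
  if (!length(tsel)) stop("time_range contains no timepoints")
  pairs <- pair_index(nrow(catalog))
  ids <- sort(catalog$stimulus_id)
  values <- matrix(NA_real_, length(tsel), nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    values[, p] <- decode_pair_raw(
      epochs, ids[pairs$i[p] + 1L], ids[pairs$j[p] + 1L],
      folds, repetitions, seed, exclude_repeats, tsel
    )
  }
  new_rdm_series(values, epochs$time_ms[tsel], pairs, folds, repetitions,
                 catalog, subset = "all")
}

new_rdm_series <- function(values, time_ms, pairs, n_folds, n_repetitions,
                           catalog, subset = "all") {
  stopifnot(nrow(values) == length(time_ms), ncol(values) == nrow(pairs))
  structure(
    list(values = values, time_ms = time_ms, pairs = pairs,
         n_folds = n_folds, n_repetitions = n_repetitions,
         catalog = catalog, subset = subset),
    class = "rdm_series"
  )
}

#' @export
print.rdm_series <- function(x, ...) {
  cat(sprintf(
    "<rdm_series> %d timepoints x %d pairs (subset: %s), %.4g..%.4g ms, %d-fold x %d reps\n",
    nrow(x$values), ncol(x$values), x$subset, min(x$time_ms), max(x$time_ms),
    x$n_folds, x$n_repetitions
  ))
  invisible(x)
}

#' Restrict an RDM series to a category subset of pairs
#'
#' Keeps only pairs where both stimuli are faces (`face_face`), exactly one
#' is (`face_nonface`), or neither is (`nonface_nonface`). For the default
#' 49-stimulus catalog (24 faces, 25 non-faces) the three subsets partition
#' the 1176 pairs into 276 + 600 + 300.
#'
#' @param rdm An `rdm_series`.
#' @param subset One of "all", "face_face", "face_nonface",
#'   "nonface_nonface".
#' @param catalog Catalog used to classify pairs; defaults to the one
#'   attached to `rdm`.
#' @return An `rdm_series` with the restricted pair columns.
#' @export
subset_pairs <- function(rdm, subset = c("all", "face_face", "face_nonface", "nonface_nonface"),
                         catalog = rdm$catalog) {
  stopifnot(inherits(rdm, "rdm_series"))
  subset <- match.arg(subset)
  if (subset == "all") return(rdm)
  assert_catalog(catalog)
  if (nrow(catalog) != max(rdm$pairs$j) + 1L) {
    stop("catalog size inconsistent with the RDM pair index")
  }
  is_face <- catalog$category[order(catalog$stimulus_id)] == "face"
  fi <- is_face[rdm$pairs$i + 1L]
  fj <- is_face[rdm$pairs$j + 1L]
  keep <- switch(subset,
    face_face = fi & fj,
    face_nonface = xor(fi, fj),
    nonface_nonface = !fi & !fj
  )
  if (!any(keep)) stop("subset '", subset, "' contains no pairs for this catalog")
  new_rdm_series(rdm$values[, keep, drop = FALSE], rdm$time_ms,
                 rdm$pairs[keep, ], rdm$n_folds, rdm$n_repetitions,
                 catalog, subset = subset)
}
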