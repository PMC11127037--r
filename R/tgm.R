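#' Temporal generalization matrix of an RDM series
#'
#' Cross-correlates the time-resolved RDMs across all timepoints: entry
#' `[s, t]` is the correlation between the pair-vector of dissimilarities at
#' time `s` and at time `t`. High off-diagonal values mean the
#' representational geometry at one latency recurs at another. The matrix is
#' symmetric with unit diagonal. Timepoints whose dissimilarity vector is
#' constant (correlation undefined) get `NA` rows/columns and are recorded
#' in the `undefined_times` attribute — never silently zeroed.
#'
#' @param rdm An `rdm_series`.
#' @param metric "pearson" (default, the minimal reading of RDM
#'   cross-correlation) or "spearman" (invariant to monotone transforms of
#'   the dissimilarities).
#' @param time_range Window in ms over which to correlate (default
#'   `c(0, 800)`, i.e. post-onset).
#' @return Object of class `tgm`: list with `values` (time x time), `time_ms`,
#'   `metric`, `subset`.
#' @export
compute_tgm <- function(rdm, metric = c("pearson", "spearman"),
                        time_range = c(0, 800)) {
  stopifnot(inherits(rdm, "rdm_series"))
  metric <- match.arg(metric)
  if (ncol(rdm$values) < 3) stop("need at least 3 pairs to correlate RDMs")
  tsel <- which(rdm$time_ms >= time_range[1] & rdm$time_ms <= time_range[2])
  if (length(tsel) < 2) stop("time_range contains fewer than 2 timepoints")
  v <- rdm$values[tsel, , drop = FALSE]
  sds <- apply(v, 1, stats::sd)
  defined <- sds > 0
  vals <- matrix(NA_real_, nrow(v), nrow(v))
  if (sum(defined) >= 2) {
    vals[defined, defined] <- suppressWarnings(
      stats::cor(t(v[defined, , drop = FALSE]), method = metric)
    )
  } else if (sum(defined) == 1) {
    vals[defined, defined] <- 1
  }
  structure(
    list(values = vals, time_ms = rdm$time_ms[tsel], metric = metric,
         subset = rdm$subset),
    class = "tgm",
    undefined_times = rdm$time_ms[tsel][!defined]
  )
}

#' @export
print.tgm <- function(x, ...) {
  cat(sprintf(
    "<tgm> %d x %d (%s, pairs: %s), %.4g..%.4g ms\n",
    nrow(x$values), ncol(x$values), x$metric, x$subset,
    min(x$time_ms), max(x$time_ms)
  ))
  invisible(x)
}

assert_tgm_aligned <- function(tgms) {
  ref <- tgms[[1]]
  for (x in tgms[-1]) {
    if (!isTRUE(all.equal(x$time_ms, ref$time_ms)) ||
        !identical(x$metric, ref$metric) || !identical(x$subset, ref$subset)) {
      stop("TGMs differ in time axis, metric or pair subset")
    }
  }
  invisible(tgms)
}

#' Average TGMs across subjects
#'
#' Correlations are averaged after Fisher z-transform by default (then
#' transformed back), or as a raw mean.
#'
#' @param tgms List of `tgm` objects sharing axis, metric and subset.
#' @param average "fisher_z" (default) or "raw".
#' @return A `tgm`.
#' @export
group_mean_tgm <- function(tgms, average = c("fisher_z", "raw")) {
  average <- match.arg(average)
  assert_tgm_aligned(tgms)
  arr <- simplify2array(lapply(tgms, `[[`, "values"))
  m <- if (average == "fisher_z") {
    tanh(apply(atanh(pmin(pmax(arr, -1 + 1e-15), 1 - 1e-15)), c(1, 2), mean))
  } else {
    apply(arr, c(1, 2), mean)
  }
  structure(
    list(values = m, time_ms = tgms[[1]]$time_ms, metric = tgms[[1]]$metric,
         subset = tgms[[1]]$subset),
    class = "tgm", averaged = average, n_subjects = length(tgms)
  )
}

#' Case-versus-controls contrast of temporal generalization matrices
#'
#' Applies the Crawford-Howell modified t-test cell by cell: the patient's
#' TGM value against the control distribution, `df = n_controls - 1`. The
#' significance mask thresholds the two-tailed p values uncorrected by
#' default (optionally FDR-adjusted). Cells undefined in any subject are
#' `NA` in all maps and excluded from the mask.
#'
#' @param patient A `tgm`.
#' @param controls List of `tgm` objects (>= 2), same axis/metric/subset.
#' @param alpha Mask threshold on p (default 0.05).
#' @param correction "none" (default, mirroring uncorrected reporting) or
#'   "fdr" (Benjamini-Hochberg over defined cells).
#' @return Object of class `tgm_contrast`: list with `t_map`, `p_map`,
#'   `mask`, `df`, `alpha`, `time_ms`, plus contrast metadata.
#' @export
tgm_case_contrast <- function(patient, controls, alpha = 0.05,
                              correction = c("none", "fdr")) {
  correction <- match.arg(correction)
  if (length(controls) < 2) stop("need at least 2 control TGMs")
  assert_tgm_aligned(c(list(patient), controls))
  n <- length(controls)
  arr <- simplify2array(lapply(controls, `[[`, "values"))
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd)
  t_map <- (patient$values - m) / (s * sqrt((n + 1) / n))
  t_map[s == 0] <- NA_real_
  df <- n - 1L
  p_map <- 2 * stats::pt(-abs(t_map), df)
  if (correction == "fdr") {
    ok <- !is.na(p_map)
    p_map[ok] <- stats::p.adjust(p_map[ok], method = "BH")
  }
  mask <- !is.na(p_map) & p_map < alpha
  structure(
    list(t_map = t_map, p_map = p_map, mask = mask, df = df, alpha = alpha,
         time_ms = patient$time_ms, metric = patient$metric,
         subset = patient$subset, n_controls = n, correction = correction,
         n_undefined = sum(is.na(t_map))),
    class = "tgm_contrast"
  )
}

#' @export
print.tgm_contrast <- function(x, ...) {
  cat(sprintf(
    "<tgm_contrast> %d x %d, df = %d, %d/%d cells significant at p < %g (%s)\n",
    nrow(x$t_map), ncol(x$t_map), x$df, sum(x$mask), length(x$mask), x$alpha,
    x$correction
  ))
  invisible(x)
}
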