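#' Crawford-Howell modified t-test for a single case against controls
#'
#' Tests whether a single patient's score is abnormally different from a small
#' control sample, treating the case as a sample of one rather than a fixed
#' population value:
#' \deqn{t = \frac{x^* - \bar{x}}{s \sqrt{(n+1)/n}}, \qquad df = n - 1,}
#' where \eqn{x^*} is the case score and \eqn{\bar{x}}, \eqn{s}, \eqn{n}
#' describe the controls. The inflation factor \eqn{\sqrt{(n+1)/n}} accounts
#' for the sampling error of the case itself, which an ordinary z-score
#' ignores; as \eqn{n \to \infty} the statistic converges to the z value.
#'
#' @param case_value Numeric scalar, the patient's score.
#' @param control_values Numeric vector of control scores (length >= 2,
#'   non-zero variance).
#' @param tails 2 (default) for a two-tailed p value, 1 for one-tailed in the
#'   direction of the observed deviation.
#' @return An object of class `case_control`: a list with `t`, `df`, `p`,
#'   `case_value`, `control_mean`, `control_sd`, `n_controls`, `tails`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' ch <- crawford_howell(10, c(1, 2, 3))
#' ch$t   # 6.9282
#' @export
crawford_howell <- function(case_value, control_values, tails = 2) {
  stopifnot(is.numeric(case_value), length(case_value) == 1L, is.finite(case_value))
  control_values <- as.numeric(control_values)
  n <- length(control_values)
  if (n < 2L) stop("crawford_howell() needs at least 2 control values, got ", n)
  if (anyNA(control_values)) stop("control_values contain NA")
  m <- mean(control_values)
  s <- stats::sd(control_values)
  if (s <= 0) stop("degenerate controls: control standard deviation is zero")
  tt <- (case_value - m) / (s * sqrt((n + 1) / n))
  df <- n - 1L
  structure(
    list(
      t = tt, df = df, p = p_from_t(tt, df, tails = tails),
      case_value = case_value, control_mean = m, control_sd = s,
      n_controls = n, tails = tails
    ),
    class = "case_control"
  )
}

#' @export
print.case_control <- function(x, ...) {
  cat(sprintf(
    "Crawford-Howell case-control test\n  t(%d) = %.4f, p = %.4g (%d-tailed)\n  case = %.4g, controls: mean = %.4g, sd = %.4g, n = %d\n",
    x$df, x$t, x$p, x$tails, x$case_value, x$control_mean, x$control_sd,
    x$n_controls
  ))
  invisible(x)
}

#' Tail probability of a Student t statistic
#'
#' Reporting helper behind every printed `t(df) = ..., P = ...` pair.
#'
#' @param t Test statistic (vectorized).
#' @param df Degrees of freedom, >= 1.
#' @param tails 2 (default) or 1.
#' @return p value(s) in (0, 1]; symmetric in the sign of `t`.
#' @examples
#' p_from_t(-2.7623, 17)  # 0.0133
#' @export
p_from_t <- function(t, df, tails = 2) {
  if (any(df < 1)) stop("df must be >= 1")
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  tails * stats::pt(-abs(t), df = df)
}

#' Face-specific behavioral performance score
#'
#' Combines one-back accuracy and response time into a single per-participant
#' face-specificity score. For each participant a contrast
#' `(face - nonface) / (face + nonface)` is computed separately for accuracy
#' and RT; the RT contrast is negated (lower face RT = better face
#' performance), both contrasts are standardized, and the first principal
#' component across participants is extracted. The component sign is fixed so
#' that a higher score means better face-specific accuracy.
#'
#' @param behavior A data frame with one row per participant and columns
#'   `participant_id`, `face_acc`, `nonface_acc`, `face_rt`, `nonface_rt`
#'   (as produced by [sim_behavior()]).
#' @return An object of class `face_score`: list with `scores` (tibble of
#'   per-participant contrasts and `pc_score`) and `variance_explained`
#'   (percent of variance captured by the first component).
#' @export
face_specific_score <- function(behavior) {
  req <- c("participant_id", "face_acc", "nonface_acc", "face_rt", "nonface_rt")
  missing_cols <- setdiff(req, names(behavior))
  if (length(missing_cols)) {
    stop("behavior table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(behavior) < 3L) stop("need at least 3 participants for the PCA")
  denom_acc <- behavior$face_acc + behavior$nonface_acc
  denom_rt <- behavior$face_rt + behavior$nonface_rt
  bad <- which(denom_acc <= 0 | denom_rt <= 0)
  if (length(bad)) {
    stop(
      "zero contrast denominator for participant(s): ",
      paste(behavior$participant_id[bad], collapse = ", ")
    )
  }
  acc_contrast <- (behavior$face_acc - behavior$nonface_acc) / denom_acc
  rt_contrast <- (behavior$face_rt - behavior$nonface_rt) / denom_rt
  # lower face RT = better, so flip the RT contrast before combining
  x <- cbind(acc = acc_contrast, rt = -rt_contrast)
  pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ve <- 100 * pca$sdev[1]^2 / sum(pca$sdev^2)
  pc <- pca$x[, 1]
  if (pca$rotation["acc", 1] < 0) pc <- -pc  # higher score = better face accuracy
  structure(
    list(
      scores = tibble::tibble(
        participant_id = behavior$participant_id,
        acc_contrast = acc_contrast,
        rt_contrast = rt_contrast,
        pc_score = as.numeric(pc)
      ),
      variance_explained = ve
    ),
    class = "face_score"
  )
}

#' @export
print.face_score <- function(x, ...) {
  cat(sprintf(
    "Face-specific performance score (PC1, %.2f%% of variance), %d participants\n",
    x$variance_explained, nrow(x$scores)
  ))
  print(x$scores, ...)
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Student's two-sample t with pooled variance and `df = n_a + n_b - 2`,
#' used for control-subgroup comparisons (e.g. young vs age-matched).
#'
#' @param group_a,group_b Numeric vectors of scores, each length >= 2.
#' @return Tibble with one row: `t`, `df`, `p`, group means.
#' @export
two_sample_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    stop("degenerate variance in both groups")
  }
  fit <- stats::t.test(group_a, group_b, var.equal = TRUE)
  tibble::tibble(
    t = unname(fit$statistic),
    df = as.integer(unname(fit$parameter)),
    p = fit$p.value,
    mean_a = mean(group_a),
    mean_b = mean(group_b)
  )
}

#' Nonparametric permutation test on per-subject statistics
#'
#' One-sided test of a positive mean by default. Under `scheme = "sign_flip"`
#' the null distribution is generated by randomly flipping the sign of each
#' subject's value (exchangeability under a symmetric null); when the full
#' enumeration `2^n` does not exceed `n_perm` the test is exact and
#' enumerates all sign patterns. Under `scheme = "label_shuffle"` a `groups`
#' factor with two levels is required and group labels are permuted, testing
#' the difference of group means.
#'
#' The Monte-Carlo p value uses the add-one convention
#' `p = (1 + #{perm >= observed}) / (1 + n_perm)`, so the smallest attainable
#' value is `1 / (1 + n_perm)`. Exhaustive enumeration returns the exact
#' proportion (the identity permutation counts itself).
#'
#' @param values Numeric vector of per-subject statistics.
#' @param n_perm Number of permutations (>= 100 recommended; fewer draws a
#'   warning but still computes).
#' @param scheme "sign_flip" (default) or "label_shuffle".
#' @param seed Integer seed for the permutation draws.
#' @param groups Two-level grouping vector, required for "label_shuffle".
#' @return Tibble with `p`, `observed`, `n_perm` (actual count used) and
#'   `exact` (TRUE when fully enumerated).
#' @export
permutation_test <- function(values, n_perm = 1000, scheme = c("sign_flip", "label_shuffle"),
                             seed = 1L, groups = NULL) {
  scheme <- match.arg(scheme)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 subjects")
  exhaustive <- scheme == "sign_flip" && 2^n <= n_perm
  if (n_perm < 100 && !exhaustive) {
    warning("n_perm < 100 gives a coarse p value; computing anyway")
  }

  if (scheme == "sign_flip") {
    observed <- mean(values)
    if (exhaustive) {
      # exact: all 2^n sign assignments
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      perm_stats <- as.numeric(signs %*% values) / n
      p <- mean(perm_stats >= observed)
      return(tibble::tibble(p = p, observed = observed, n_perm = 2L^n, exact = TRUE))
    }
    perm_stats <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        mean(sample(c(-1, 1), n, replace = TRUE) * values)
      }, numeric(1))
    })
  } else {
    if (is.null(groups)) stop("scheme = 'label_shuffle' requires `groups`")
    g <- as.factor(groups)
    if (nlevels(g) != 2L) stop("`groups` must have exactly two levels")
    stat <- function(gg) mean(values[gg == levels(g)[1]]) - mean(values[gg == levels(g)[2]])
    observed <- stat(g)
    perm_stats <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat(sample(g)), numeric(1))
    })
  }
  p <- (1 + sum(perm_stats >= observed)) / (1 + n_perm)
  tibble::tibble(p = p, observed = observed, n_perm = as.integer(n_perm), exact = FALSE)
}
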