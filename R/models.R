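#' Model RDM from a feature matrix
#'
#' Computes pairwise dissimilarities between stimulus feature vectors (e.g.
#' network-layer activations or sentence embeddings), vectorized along the
#' canonical [pair_index()] ordering.
#'
#' @param features Numeric matrix, stimuli x features (rows in stimulus-id
#'   order, as from [sim_model_features()] or [read_feature_matrix()]).
#' @param metric "one_minus_pearson" (1 - Pearson correlation between
#'   feature vectors, range \[0, 2\]) or "cosine_distance" (1 - cosine
#'   similarity, range \[0, 2\]).
#' @param name Label carried into downstream results (e.g. "layer7",
#'   "semantic").
#' @return Object of class `model_rdm`: list with `values` (pair vector),
#'   `pairs`, `metric`, `name`.
#' @export
rdm_from_features <- function(features, metric = c("one_minus_pearson", "cosine_distance"),
                              name = "model") {
  metric <- match.arg(metric)
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2) stop("need at least 2 stimuli")
  rid <- if (is.null(rownames(features))) as.character(seq_len(n) - 1L) else rownames(features)
  if (metric == "one_minus_pearson") {
    const <- apply(features, 1, stats::sd) == 0
    if (any(const)) {
      stop("constant feature row(s) under the correlation metric for stimulus: ",
           paste(rid[const], collapse = ", "))
    }
    d <- 1 - stats::cor(t(features))
  } else {
    nrm <- sqrt(rowSums(features^2))
    if (any(nrm == 0)) {
      stop("zero-norm feature row(s) under the cosine metric for stimulus: ",
           paste(rid[nrm == 0], collapse = ", "))
    }
    d <- 1 - tcrossprod(features / nrm)
  }
  pairs <- pair_index(n)
  new_model_rdm(d[cbind(pairs$i + 1L, pairs$j + 1L)], pairs, metric, name)
}

new_model_rdm <- function(values, pairs, metric, name) {
  stopifnot(length(values) == nrow(pairs), all(is.finite(values)))
  structure(list(values = values, pairs = pairs, metric = metric, name = name),
            class = "model_rdm")
}

#' @export
print.model_rdm <- function(x, ...) {
  cat(sprintf("<model_rdm> '%s': %d pairs (%s)\n", x$name, length(x$values), x$metric))
  invisible(x)
}

# binary code matrix for one catalog dimension; rows with NA attribute
# (e.g. face_gender of a non-face) get an all-zero code
dimension_code <- function(catalog, dimension) {
  supported <- c("category", "animacy", "face_gender", "face_expression", "face_identity")
  if (!dimension %in% supported) {
    stop("unknown catalog dimension '", dimension, "'; available: ",
         paste(supported, collapse = ", "))
  }
  v <- switch(dimension,
    category = as.character(catalog$category),
    animacy = ifelse(catalog$category %in% c("face", "animal"), "animate", "inanimate"),
    face_gender = as.character(catalog$face_gender),
    face_expression = as.character(catalog$face_expression),
    face_identity = ifelse(is.na(catalog$face_identity), NA_character_,
                           paste0("id", catalog$face_identity))
  )
  lev <- sort(unique(v[!is.na(v)]))
  if (!length(lev)) stop("dimension '", dimension, "' has no defined levels in this catalog")
  code <- matrix(0, nrow(catalog), length(lev), dimnames = list(NULL, paste0(dimension, ":", lev)))
  ok <- !is.na(v)
  code[cbind(which(ok), match(v[ok], lev))] <- 1
  code
}

#' Categorical model RDM from binary encodings
#'
#' Encodes catalog dimensions (category, animacy, face gender, face
#' expression, face identity) as binary indicator vectors and measures the
#' distance between the per-stimulus codes. `encoding = "onehot"` uses a
#' single dimension; `"multihot"` concatenates the codes of several
#' dimensions. Attributes undefined for a stimulus (face attributes of
#' non-faces) contribute an all-zero block.
#'
#' @param catalog Stimulus catalog.
#' @param dimensions Character vector of dimension names.
#' @param encoding "multihot" (default) or "onehot".
#' @param distance "euclidean" (default) or "hamming" between code vectors.
#' @param name Label for the resulting model RDM.
#' @return A `model_rdm` with metric `"binary_vector_distance"`.
#' @export
categorical_rdm <- function(catalog, dimensions, encoding = c("multihot", "onehot"),
                            distance = c("euclidean", "hamming"),
                            name = paste(dimensions, collapse = "+")) {
  assert_catalog(catalog)
  encoding <- match.arg(encoding)
  distance <- match.arg(distance)
  if (encoding == "onehot" && length(dimensions) != 1) {
    stop("onehot encoding takes exactly one dimension")
  }
  catalog <- catalog[order(catalog$stimulus_id), ]
  code <- do.call(cbind, lapply(dimensions, dimension_code, catalog = catalog))
  pairs <- pair_index(nrow(catalog))
  a <- code[pairs$i + 1L, , drop = FALSE]
  b <- code[pairs$j + 1L, , drop = FALSE]
  values <- if (distance == "euclidean") {
    sqrt(rowSums((a - b)^2))
  } else {
    rowSums(a != b)
  }
  new_model_rdm(values, pairs, "binary_vector_distance", name)
}

#' Spearman correlation between two dissimilarity vectors
#'
#' Rank correlation with average ranks for ties. Constant input is flagged
#' with a warning and returns `NA` rather than an arbitrary value.
#'
#' @param a,b Numeric vectors of equal length >= 3 (pair-vectors of two
#'   RDMs).
#' @return Spearman's rho, or `NA` if undefined.
#' @export
spearman_rdm <- function(a, b) {
  if (length(a) != length(b)) stop("inputs differ in length")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' First-order partial Spearman correlation
#'
#' Rank-transforms all three vectors (average ranks) and computes
#' \deqn{\rho_{ab \cdot c} = \frac{r_{ab} - r_{ac} r_{bc}}
#'   {\sqrt{(1 - r_{ac}^2)(1 - r_{bc}^2)}}}
#' on the ranks: the rank correlation between `a` and `b` after removing the
#' (linear-in-ranks) contribution of `control`. A constant control reduces
#' to the plain Spearman correlation; a control collinear (in ranks) with
#' `a` or `b` leaves nothing to correlate and returns `NA` with a warning.
#'
#' @param a,b Pair-vectors to correlate.
#' @param control Pair-vector whose rank variance is partialled out.
#' @return Partial Spearman rho, or `NA` if undefined.
#' @export
partial_spearman_rdm <- function(a, b, control) {
  if (length(a) != length(b) || length(a) != length(control)) {
    stop("inputs differ in length")
  }
  if (length(a) < 4) stop("need at least 4 pairs for a partial correlation")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant input: partial Spearman correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(control) == 0) return(spearman_rdm(a, b))
  ra <- rank(a); rb <- rank(b); rc <- rank(control)
  r_ab <- stats::cor(ra, rb)
  r_ac <- stats::cor(ra, rc)
  r_bc <- stats::cor(rb, rc)
  if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12) {
    warning("control is rank-collinear with an input: partial correlation undefined")
    return(NA_real_)
  }
  (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
}

assert_pairs_aligned <- function(pairs_a, pairs_b, what = "model RDM") {
  if (!identical(as.data.frame(pairs_a), as.data.frame(pairs_b))) {
    stop("pair index misalignment between brain RDM and ", what,
         ": refusing to correlate")
  }
  invisible(TRUE)
}

#' Timecourse of brain-model RDM correlation
#'
#' Correlates a model RDM with the brain RDM at every timepoint using
#' Spearman correlation, optionally partialling out a second model RDM
#' (e.g. layer RDMs partialling out the semantic RDM, and vice versa).
#' Alignment is enforced through the shared pair index, never assumed from
#' position. Timepoints where the correlation is undefined are `NA` and
#' flagged in the `undefined` column.
#'
#' @param rdm An `rdm_series` (brain RDMs).
#' @param model A `model_rdm`.
#' @param partial_out Optional `model_rdm` to partial out.
#' @param subject Optional subject label carried into the result.
#' @return Tibble of class `model_timecourse` with columns `time_ms`, `rho`,
#'   `model`, `partialled_out`, `subject`, `undefined`.
#' @export
model_timecourse <- function(rdm, model, partial_out = NULL, subject = NA_character_) {
  stopifnot(inherits(rdm, "rdm_series"), inherits(model, "model_rdm"))
  assert_pairs_aligned(rdm$pairs, model$pairs)
  if (!is.null(partial_out)) {
    stopifnot(inherits(partial_out, "model_rdm"))
    assert_pairs_aligned(rdm$pairs, partial_out$pairs, "control model RDM")
  }
  rho <- vapply(seq_along(rdm$time_ms), function(t) {
    v <- rdm$values[t, ]
    suppressWarnings(
      if (is.null(partial_out)) spearman_rdm(v, model$values)
      else partial_spearman_rdm(v, model$values, partial_out$values)
    )
  }, numeric(1))
  out <- tibble::tibble(
    time_ms = rdm$time_ms, rho = rho, model = model$name,
    partialled_out = if (is.null(partial_out)) NA_character_ else partial_out$name,
    subject = subject, undefined = is.na(rho)
  )
  class(out) <- c("model_timecourse", class(out))
  out
}

#' Case-versus-controls contrast of correlation timecourses
#'
#' Crawford-Howell test at every timepoint: the patient's brain-model
#' correlation against the control distribution, `df = n_controls - 1`,
#' two-tailed p, uncorrected significance at `alpha` with the direction of
#' the deviation recorded.
#'
#' @param patient A `model_timecourse`.
#' @param controls List of `model_timecourse` objects (>= 2) on the same
#'   time axis.
#' @param alpha Significance threshold (default 0.05, uncorrected).
#' @return Tibble of class `timecourse_contrast` with columns `time_ms`,
#'   `t`, `df`, `p`, `direction`, `significant`, plus attribute `df`.
#' @export
timecourse_case_contrast <- function(patient, controls, alpha = 0.05) {
  if (length(controls) < 2) stop("need at least 2 control timecourses")
  for (x in controls) {
    if (!isTRUE(all.equal(x$time_ms, patient$time_ms))) {
      stop("timecourses differ in time axis")
    }
  }
  n <- length(controls)
  cmat <- vapply(controls, `[[`, numeric(nrow(patient)), "rho")
  m <- rowMeans(cmat)
  s <- apply(cmat, 1, stats::sd)
  tt <- (patient$rho - m) / (s * sqrt((n + 1) / n))
  tt[s == 0] <- NA_real_
  df <- n - 1L
  p <- 2 * stats::pt(-abs(tt), df)
  out <- tibble::tibble(
    time_ms = patient$time_ms, t = tt, df = df, p = p,
    direction = dplyr::case_when(
      is.na(tt) ~ NA_character_,
      tt >= 0 ~ "patient>controls",
      TRUE ~ "controls>patient"
    ),
    significant = !is.na(p) & p < alpha
  )
  class(out) <- c("timecourse_contrast", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n_controls") <- n
  out
}
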