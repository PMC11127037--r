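#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname crawford_howell
#' @param x A `case_control` object.
#' @param ... Unused.
tidy.case_control <- function(x, ...) {
  tibble::tibble(t = x$t, df = x$df, p = x$p,
                 case_value = x$case_value, control_mean = x$control_mean,
                 control_sd = x$control_sd)
}

#' @export
#' @rdname crawford_howell
glance.case_control <- function(x, ...) {
  tibble::tibble(n_controls = x$n_controls, df = x$df, tails = x$tails)
}

#' @export
#' @rdname face_specific_score
#' @param x A `face_score` object.
#' @param ... Unused.
tidy.face_score <- function(x, ...) x$scores

#' @export
#' @rdname face_specific_score
glance.face_score <- function(x, ...) {
  tibble::tibble(variance_explained = x$variance_explained,
                 n_participants = nrow(x$scores))
}

#' Long-format view of an RDM series
#'
#' @param x An `rdm_series`.
#' @param ... Unused.
#' @return Tibble with `time_ms`, `i`, `j`, `dissimilarity`.
#' @export
tidy.rdm_series <- function(x, ...) {
  tidyr::expand_grid(
    time_ms = x$time_ms,
    pair = seq_len(nrow(x$pairs))
  ) |>
    dplyr::mutate(
      i = x$pairs$i[.data$pair], j = x$pairs$j[.data$pair],
      dissimilarity = as.vector(t(x$values))
    ) |>
    dplyr::select(!"pair")
}

#' Long-format view of a TGM
#'
#' @param x A `tgm`.
#' @param ... Unused.
#' @return Tibble with `time_train_ms`, `time_test_ms`, `correlation`.
#' @export
tidy.tgm <- function(x, ...) {
  tidyr::expand_grid(time_train_ms = x$time_ms, time_test_ms = x$time_ms) |>
    dplyr::mutate(correlation = as.vector(t(x$values)))
}

#' Long-format view of a TGM case contrast
#'
#' @param x A `tgm_contrast`.
#' @param ... Unused.
#' @return Tibble with `time_train_ms`, `time_test_ms`, `t`, `p`,
#'   `significant`.
#' @export
tidy.tgm_contrast <- function(x, ...) {
  tidyr::expand_grid(time_train_ms = x$time_ms, time_test_ms = x$time_ms) |>
    dplyr::mutate(
      t = as.vector(t(x$t_map)), p = as.vector(t(x$p_map)),
      significant = as.vector(t(x$mask))
    )
}

#' @export
#' @rdname tidy.tgm_contrast
glance.tgm_contrast <- function(x, ...) {
  tibble::tibble(
    df = x$df, alpha = x$alpha, n_controls = x$n_controls,
    n_cells = length(x$mask), n_significant = sum(x$mask),
    n_undefined = x$n_undefined, correction = x$correction
  )
}
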