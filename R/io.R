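#' Write / read an epoch set as a plain-text container
#'
#' Serializes an `epoch_set` into a directory holding `meta.json` (time
#' axis, labels, repetition flags, sampling rate, seed, catalog) and
#' `data.csv` (the trial x channel x timepoint array flattened to
#' `trials * channels` rows by `timepoints` columns). The round trip is
#' lossless to full double precision.
#'
#' @param epochs An `epoch_set`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  meta <- list(
    dim = d, time_ms = epochs$time_ms, labels = epochs$labels,
    repeat_flag = epochs$repeat_flag, sampling_rate = epochs$sampling_rate,
    seed = epochs$seed,
    catalog = if (!is.null(epochs$catalog)) as.data.frame(epochs$catalog)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  flat <- tibble::as_tibble(matrix(epochs$data, d[1] * d[2], d[3]),
                            .name_repair = ~ sprintf("t%d", seq_along(.x)))
  readr::write_csv(flat, file.path(path, "data.csv"))
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  flat <- as.matrix(readr::read_csv(file.path(path, "data.csv"),
                                    show_col_types = FALSE))
  d <- meta$dim
  catalog <- if (!is.null(meta$catalog)) {
    cc <- tibble::as_tibble(meta$catalog)
    cc$category <- factor(cc$category, levels = c("face", "animal", "object", "plant", "scene"))
    class(cc) <- c("stimulus_catalog", class(cc))
    cc
  }
  new_epoch_set(array(flat, d), meta$time_ms, meta$labels,
                meta$repeat_flag, meta$sampling_rate, catalog,
                if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

#' Write an RDM series to CSV + JSON
#'
#' `values.csv` holds timepoints as rows (first column `time_ms`, one column
#' per pair named `p<i>_<j>`); `meta.json` records the pair index, CV plan
#' and subset.
#'
#' @param rdm An `rdm_series`.
#' @param path Directory to write into.
#' @export
write_rdm_series <- function(rdm, path) {
  stopifnot(inherits(rdm, "rdm_series"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tab <- tibble::as_tibble(rdm$values, .name_repair = "minimal")
  names(tab) <- sprintf("p%d_%d", rdm$pairs$i, rdm$pairs$j)
  readr::write_csv(dplyr::bind_cols(tibble::tibble(time_ms = rdm$time_ms), tab),
                   file.path(path, "values.csv"))
  jsonlite::write_json(
    list(pairs = as.data.frame(rdm$pairs), n_folds = rdm$n_folds,
         n_repetitions = rdm$n_repetitions, subset = rdm$subset,
         catalog = if (!is.null(rdm$catalog)) as.data.frame(rdm$catalog)),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Square RDM at one timepoint
#'
#' Expands the vectorized RDM nearest to `time_ms` into a symmetric square
#' matrix (zero diagonal), e.g. for export or heatmap display.
#'
#' @param rdm An `rdm_series` with the full pair set.
#' @param time_ms Requested timepoint (nearest sample used).
#' @return Square numeric matrix with stimulus ids as dimnames.
#' @export
rdm_at <- function(rdm, time_ms) {
  stopifnot(inherits(rdm, "rdm_series"))
  ti <- which.min(abs(rdm$time_ms - time_ms))
  n <- max(rdm$pairs$j) + 1L
  m <- matrix(0, n, n, dimnames = list(0:(n - 1), 0:(n - 1)))
  idx <- cbind(rdm$pairs$i + 1L, rdm$pairs$j + 1L)
  m[idx] <- rdm$values[ti, ]
  m[idx[, 2:1]] <- rdm$values[ti, ]
  m
}

#' Write a TGM (or TGM contrast map) as square CSV
#'
#' First column and header carry the time axis in ms.
#'
#' @param x A `tgm`, or any square matrix with a matching `time_ms`.
#' @param path File to write.
#' @param time_ms Time axis (taken from `x` when it is a `tgm`).
#' @export
write_tgm_csv <- function(x, path, time_ms = NULL) {
  if (inherits(x, "tgm")) {
    time_ms <- x$time_ms
    x <- x$values
  }
  stopifnot(is.matrix(x), !is.null(time_ms), length(time_ms) == nrow(x))
  tab <- tibble::as_tibble(x, .name_repair = "minimal")
  names(tab) <- sprintf("t%.4f", time_ms)
  readr::write_csv(dplyr::bind_cols(tibble::tibble(time_ms = time_ms), tab), path)
  invisible(path)
}

#' Read a stimulus x feature matrix from CSV
#'
#' Expected layout: header row of feature names, first column `stimulus_id`,
#' one row per stimulus. Rows are ordered by stimulus id on read.
#'
#' @param path CSV file.
#' @return Numeric matrix with stimulus ids as rownames.
#' @export
read_feature_matrix <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (names(tab)[1] != "stimulus_id") stop("first column must be `stimulus_id`")
  tab <- dplyr::arrange(tab, .data$stimulus_id)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$stimulus_id
  m
}

#' Read a behavioral table from CSV
#'
#' Validates the column contract used by [face_specific_score()] and the
#' case-control tests: `participant_id`, `group` (patient / control_young /
#' control_matched), `face_acc`, `nonface_acc`, `face_rt`, `nonface_rt`,
#' `cfmt_score`.
#'
#' @param path CSV file.
#' @return Tibble.
#' @export
read_behavior <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("participant_id", "group", "face_acc", "nonface_acc",
           "face_rt", "nonface_rt", "cfmt_score")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("behavior CSV lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$group), c("patient", "control_young", "control_matched"))
  if (length(bad)) stop("unknown group value(s): ", paste(bad, collapse = ", "))
  tab
}
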