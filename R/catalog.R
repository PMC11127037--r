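#' Generate a stimulus catalog
#'
#' Builds the stimulus set used throughout the package: a tibble with one row
#' per stimulus. Faces carry identity, gender and expression attributes
#' (identities cycle through the three expressions neutral/happy/fearful);
#' non-face stimuli have those fields `NA`. The default call reproduces the
#' 49-stimulus structure used in single-case face-processing work: 24 faces
#' (8 identities, 4 of them female, x 3 expressions) plus 8 animals, 8
#' objects and 9 scenes.
#'
#' @param n_faces Number of face stimuli; must be divisible by the number of
#'   expressions (3) when positive.
#' @param n_nonfaces Named integer vector of non-face counts per category;
#'   names drawn from `c("animal", "object", "plant", "scene")`.
#' @param seed Unused at present (the catalog is deterministic) but accepted
#'   so configuration code can pass one uniformly.
#' @return Tibble of class `stimulus_catalog` with columns `stimulus_id`
#'   (0-based, contiguous), `category` (factor), `face_identity`,
#'   `face_gender`, `face_expression`.
#' @examples
#' cat49 <- sim_catalog()
#' nrow(cat49)                      # 49
#' sum(cat49$category == "face")    # 24
#' @export
sim_catalog <- function(n_faces = 24,
                        n_nonfaces = c(animal = 8, object = 8, scene = 9),
                        seed = NULL) {
  expressions <- c("neutral", "happy", "fearful")
  categories <- c("face", "animal", "object", "plant", "scene")
  if (n_faces < 0 || any(n_nonfaces < 0)) stop("stimulus counts must be non-negative")
  if (length(n_nonfaces) && is.null(names(n_nonfaces))) {
    stop("n_nonfaces must be a named vector (animal/object/plant/scene)")
  }
  unknown <- setdiff(names(n_nonfaces), categories[-1])
  if (length(unknown)) stop("unknown non-face categories: ", paste(unknown, collapse = ", "))
  if (n_faces > 0 && n_faces %% length(expressions) != 0) {
    stop("n_faces must be divisible by ", length(expressions), " (one stimulus per expression)")
  }
  if (n_faces + sum(n_nonfaces) < 1) stop("catalog must contain at least one stimulus")

  n_id <- n_faces %/% length(expressions)
  faces <- if (n_faces > 0) {
    tibble::tibble(
      category = "face",
      face_identity = rep(seq_len(n_id), each = length(expressions)),
      # first half of the identities female (default: 4 of 8)
      face_gender = ifelse(rep(seq_len(n_id), each = length(expressions)) <= ceiling(n_id / 2),
        "female", "male"
      ),
      face_expression = rep(expressions, times = n_id)
    )
  } else {
    tibble::tibble(
      category = character(), face_identity = integer(),
      face_gender = character(), face_expression = character()
    )
  }
  nonfaces <- tibble::tibble(
    category = rep(names(n_nonfaces), times = n_nonfaces),
    face_identity = NA_integer_, face_gender = NA_character_,
    face_expression = NA_character_
  )
  out <- dplyr::bind_rows(faces, nonfaces)
  out <- dplyr::mutate(out,
    stimulus_id = dplyr::row_number() - 1L,
    category = factor(.data$category, levels = categories),
    face_expression = factor(.data$face_expression, levels = expressions)
  )
  out <- dplyr::relocate(out, "stimulus_id")
  class(out) <- c("stimulus_catalog", class(out))
  out
}

assert_catalog <- function(catalog) {
  if (!all(c("stimulus_id", "category") %in% names(catalog))) {
    stop("not a stimulus catalog: needs stimulus_id and category columns")
  }
  ids <- sort(catalog$stimulus_id)
  if (!identical(as.integer(ids), seq_len(nrow(catalog)) - 1L)) {
    stop("catalog stimulus_id values must be unique and contiguous from 0")
  }
  invisible(catalog)
}
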