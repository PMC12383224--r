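#' Aggregate responses into per-participant category profiles
#'
#' Collapses item-level responses to one row per participant holding the four
#' per-category values every estimator consumes: in `binary` mode the
#' acceptance proportion (ratings recoded via [recode_rating()] unless an
#' `accept` column is already present), in `continuous` mode the mean raw
#' rating.
#'
#' @param responses Long tibble with columns `participant_id`, `item_id`, and
#'   either `rating` (1-6) or `accept` (0/1); a `category` column is used if
#'   present, otherwise supplied by joining `battery` on `item_id`.
#' @param battery Optional battery definition (needed when `responses` lacks
#'   a `category` column).
#' @param mode `"binary"` or `"continuous"`.
#' @return A tibble with columns `participant_id`, `mode`, the four category
#'   values `PB`, `PC`, `AB`, `AC`, and trial counts `n_PB` .. `n_AC`.
#' @export
aggregate_profiles <- function(responses, battery = NULL,
                               mode = c("binary", "continuous")) {
  mode <- match.arg(mode)
  require_columns(responses, c("participant_id", "item_id"), "responses")
  if (!"category" %in% names(responses)) {
    if (is.null(battery)) {
      abort("responses lack a `category` column; supply `battery` to join on item_id.")
    }
    require_columns(battery, c("item_id", "category"), "battery")
    responses <- dplyr::left_join(
      responses, dplyr::select(battery, "item_id", "category"), by = "item_id")
    if (anyNA(responses$category)) {
      abort("some response item_id values are not in the battery definition.")
    }
  }
  bad <- setdiff(unique(responses$category), DILEMMA_CATEGORIES)
  if (length(bad) > 0) {
    abort(sprintf("unknown response category code(s): %s.", paste(bad, collapse = ", ")))
  }

  if (mode == "binary") {
    if ("accept" %in% names(responses)) {
      assert_numeric_in(responses$accept, 0, 1, "accept", integer = TRUE)
      responses$value <- as.integer(responses$accept)
    } else if ("rating" %in% names(responses)) {
      responses$value <- recode_rating(responses$rating)
    } else {
      abort("binary mode needs an `accept` or `rating` column.")
    }
  } else {
    if (!"rating" %in% names(responses)) {
      abort("continuous mode needs a `rating` column.")
    }
    assert_numeric_in(responses$rating, 1, 6, "rating", integer = TRUE)
    responses$value <- as.numeric(responses$rating)
  }

  if (anyDuplicated(responses[, c("participant_id", "item_id")])) {
    abort("each (participant_id, item_id) pair may appear at most once.")
  }

  agg <- dplyr::summarise(
    dplyr::group_by(responses, .data$participant_id, .data$category),
    value = mean(.data$value),
    n = dplyr::n(),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    agg,
    id_cols = "participant_id",
    names_from = "category",
    values_from = c("value", "n"),
    names_glue = "{ifelse(.value == 'value', '', 'n_')}{category}",
    values_fill = list(n = 0L)
  )
  for (cat in DILEMMA_CATEGORIES) {
    vcol <- cat
    if (!vcol %in% names(wide) || anyNA(wide[[vcol]])) {
      offenders <- if (!vcol %in% names(wide)) wide$participant_id else
        wide$participant_id[is.na(wide[[vcol]])]
      abort(sprintf(
        "category %s has no responses for participant(s): %s.",
        cat, paste(utils::head(offenders, 5), collapse = ", ")))
    }
    ncol_ <- paste0("n_", cat)
    if (!ncol_ %in% names(wide)) wide[[ncol_]] <- 0L
  }
  out <- dplyr::select(wide, "participant_id",
                       dplyr::all_of(DILEMMA_CATEGORIES),
                       dplyr::all_of(paste0("n_", DILEMMA_CATEGORIES)))
  dplyr::mutate(out, mode = mode, .after = "participant_id")
}
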