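#' Construct a 2x2 moral-dilemma battery definition
#'
#' The standard battery crosses two norm kinds (proscriptive: the norm
#' prohibits action; prescriptive: the norm favours action) with two
#' consequence kinds (benefits outweigh costs; costs outweigh benefits),
#' giving four categories coded `PB`, `PC`, `AB`, `AC`. Each of
#' `items_per_category` stories contributes one scenario to every category,
#' and the deterministic presentation order guarantees that no two adjacent
#' scenarios come from the same story.
#'
#' @param items_per_category Number of scenarios per category (default 6,
#'   i.e. the 24-item battery).
#' @return A tibble with columns `item_id`, `story_id`, `category`,
#'   `norm_kind`, `consequence_kind`, `presentation_order`.
#' @export
#' @examples
#' dilemma_battery()
dilemma_battery <- function(items_per_category = 6) {
  stopifnot(is.numeric(items_per_category), length(items_per_category) == 1,
            items_per_category >= 1, items_per_category == round(items_per_category))
  ipc <- as.integer(items_per_category)
  grid <- tidyr::expand_grid(
    category = DILEMMA_CATEGORIES,
    story = seq_len(ipc)
  )
  grid <- dplyr::mutate(
    grid,
    item_id = sprintf("item_%s_%02d", .data$category, .data$story),
    story_id = sprintf("story_%02d", .data$story),
    norm_kind = ifelse(substr(.data$category, 1, 1) == "P", "prohibited", "allowed"),
    consequence_kind = ifelse(substr(.data$category, 2, 2) == "B",
                              "benefits_gt_costs", "costs_gt_benefits")
  )
  # round-robin over stories with a rotating category offset: adjacent
  # presentation slots always move to the next story
  order_key <- purrr::map_dfr(0:3, function(r) {
    tibble::tibble(
      story = seq_len(ipc),
      category = DILEMMA_CATEGORIES[((seq_len(ipc) + r) %% 4) + 1L]
    )
  })
  order_key$presentation_order <- seq_len(nrow(order_key))
  out <- dplyr::left_join(grid, order_key, by = c("story", "category"))
  out <- dplyr::arrange(out, .data$presentation_order)
  tibble::as_tibble(out[, c("item_id", "story_id", "category", "norm_kind",
                            "consequence_kind", "presentation_order")])
}

#' Validate a battery definition
#'
#' Checks the 2x2 structure (equal item counts in all four categories), the
#' uniqueness of item identifiers, and that no two adjacent items in
#' presentation order share a story.
#'
#' @param battery A battery tibble as produced by [dilemma_battery()] or read
#'   from a battery CSV.
#' @return The battery, invisibly; errors describe the first violation found.
#' @export
validate_battery <- function(battery) {
  require_columns(battery, c("item_id", "story_id", "category"), "battery")
  if (anyDuplicated(battery$item_id)) {
    abort("battery item_id values must be unique.")
  }
  bad <- setdiff(unique(battery$category), DILEMMA_CATEGORIES)
  if (length(bad) > 0) {
    abort(sprintf("battery contains unknown category code(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  counts <- table(factor(battery$category, levels = DILEMMA_CATEGORIES))
  if (length(unique(as.integer(counts))) != 1 || any(counts == 0)) {
    abort(sprintf(
      "battery must have the same number of items in all four categories; got %s.",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  }
  if ("presentation_order" %in% names(battery)) {
    ord <- battery[order(battery$presentation_order), ]
    adjacent_same <- ord$story_id[-1] == ord$story_id[-nrow(ord)]
    if (any(adjacent_same)) {
      abort("battery presentation order places two items from the same story adjacently.")
    }
  }
  invisible(battery)
}
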