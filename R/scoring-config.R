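#' S-GUS scoring configuration
#'
#' The short-form Global Usability Score (S-GUS) is a 12-item questionnaire
#' yielding a usability score between 0 and 50 points per inhaler, higher
#' meaning more usable. Items 1--9 each contribute a single subscore, items
#' 10 and 11 are graded by the degree of difficulty observed by the nurse
#' (strictly decreasing subscores with increasing difficulty), and item 12
#' awards a fixed agreement constant when the patient's self-assessment
#' matches the nurse's judgment ("Yes") and 0 otherwise.
#'
#' A configuration is a tibble of class `sgus_config` with one row per
#' (item, response level): columns `item_id` (integer 1--12), `kind`
#' (`"single-subscore"`, `"difficulty-graded"` or `"agreement"`),
#' `level` (character response code) and `points` (numeric subscore).
#' The `agreement_value` attribute holds the item-12 "Yes" constant.
#'
#' @param items A data frame with columns `item_id`, `kind`, `level`,
#'   `points`.
#' @param agreement_value Points awarded by item 12 on agreement.
#' @return A tibble of class `sgus_config`.
#' @seealso [default_sgus_config()], [validate_sgus_config()]
#' @export
sgus_config <- function(items, agreement_value = 3.2) {
  items <- tibble::as_tibble(items)
  req <- c("item_id", "kind", "level", "points")
  missing_cols <- setdiff(req, names(items))
  if (length(missing_cols) > 0) {
    stop("scoring config is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  items$item_id <- as.integer(items$item_id)
  items$level <- as.character(items$level)
  items$points <- as.numeric(items$points)
  structure(items,
            agreement_value = agreement_value,
            class = c("sgus_config", class(tibble::tibble())))
}

#' Default S-GUS scoring configuration
#'
#' The exact per-item subscore table of the short-form instrument is not in
#' the public domain, so this default is a documented stand-in that honours
#' every published constraint: twelve items, item maxima summing to 50
#' points, strictly decreasing difficulty grades on items 10 and 11, and an
#' item-12 agreement constant of 3.2 points. Items 1--3 (previous device
#' experience) are worth 2 points each, items 4--9 ("at a glance"
#' preference) 3 points each, item 10 grades handling difficulty over
#' \{10, 6.6, 3.3, 0\} and item 11 actuation difficulty over
#' \{12.8, 8.5, 4.3, 0\}. Studies holding the licensed subscore table can
#' supply it via [read_sgus_config()].
#'
#' @return A tibble of class `sgus_config`.
#' @examples
#' cfg <- default_sgus_config()
#' sum(dplyr::summarise(dplyr::group_by(cfg, item_id),
#'                      mx = max(points))$mx) # 50
#' @export
default_sgus_config <- function() {
  binary <- function(id, kind, pts) {
    tibble::tibble(item_id = id, kind = kind,
                   level = c("yes", "no"), points = c(pts, 0))
  }
  graded <- function(id, pts) {
    tibble::tibble(item_id = id, kind = "difficulty-graded",
                   level = c("none", "mild", "moderate", "severe"),
                   points = pts)
  }
  items <- dplyr::bind_rows(
    purrr::map(1:3, binary, kind = "single-subscore", pts = 2),
    purrr::map(4:9, binary, kind = "single-subscore", pts = 3),
    graded(10L, c(10, 6.6, 3.3, 0)),
    graded(11L, c(12.8, 8.5, 4.3, 0)),
    binary(12L, "agreement", 3.2)
  )
  sgus_config(items, agreement_value = 3.2)
}

#' Validate a scoring configuration
#'
#' Checks the structural invariants of an S-GUS configuration and returns
#' the violations instead of raising: exactly 12 items with ids 1..12, item
#' maxima summing to 50 points, item 12 scoring exactly
#' \{agreement_value, 0\}, and strictly decreasing subscores across the
#' difficulty grades of items 10 and 11.
#'
#' @param config An [sgus_config()] object.
#' @return A character vector of violation messages; empty when the
#'   configuration is valid.
#' @export
validate_sgus_config <- function(config) {
  violations <- character()
  ids <- sort(unique(config$item_id))
  if (!identical(ids, 1:12)) {
    violations <- c(violations,
                    "config must contain items 1..12 exactly once each")
  }
  maxima <- config |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(mx = max(.data$points), .groups = "drop")
  total_max <- sum(maxima$mx)
  if (abs(total_max - 50) > 1e-9) {
    violations <- c(violations, sprintf(
      "item maxima must sum to 50 points (got %.6g)", total_max))
  }
  av <- attr(config, "agreement_value") %||% 3.2
  item12 <- sort(config$points[config$item_id == 12L])
  if (length(item12) != 2 || any(abs(item12 - sort(c(0, av))) > 1e-9)) {
    violations <- c(violations, sprintf(
      "item 12 must score agreement_value (%.6g) or 0", av))
  }
  for (id in intersect(c(10L, 11L), ids)) {
    pts <- config$points[config$item_id == id]
    if (any(diff(pts) >= 0)) {
      violations <- c(violations, sprintf(
        "item %d must have strictly decreasing subscores across difficulty levels",
        id))
    }
  }
  violations
}

#' Read / write a scoring configuration as YAML
#'
#' The on-disk schema is a list with `agreement_value` and an `items` list,
#' each item holding `item_id`, `kind`, and a `levels` mapping of response
#' code to points.
#'
#' @param path File path.
#' @param config An [sgus_config()] object.
#' @return `read_sgus_config()` returns an `sgus_config`;
#'   `write_sgus_config()` returns `path` invisibly.
#' @export
read_sgus_config <- function(path) {
  raw <- yaml::read_yaml(path)
  items <- purrr::map_dfr(raw$items, function(it) {
    tibble::tibble(item_id = as.integer(it$item_id),
                   kind = it$kind,
                   level = names(it$levels),
                   points = as.numeric(unlist(it$levels)))
  })
  sgus_config(items, agreement_value = raw$agreement_value %||% 3.2)
}

#' @rdname read_sgus_config
#' @export
write_sgus_config <- function(config, path) {
  items <- config |>
    dplyr::group_by(.data$item_id, .data$kind) |>
    dplyr::group_map(function(grp, key) {
      list(item_id = key$item_id, kind = key$kind,
           levels = stats::setNames(as.list(grp$points), grp$level))
    })
  yaml::write_yaml(list(agreement_value = attr(config, "agreement_value"),
                        items = items), path)
  invisible(path)
}

#' Maximum attainable S-GUS total under a configuration
#'
#' @param config An [sgus_config()] object.
#' @return Numeric: the sum of all item maxima (50 for a valid config).
#' @export
max_sgus_total <- function(config) {
  config |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(mx = max(.data$points), .groups = "drop") |>
    dplyr::pull(.data$mx) |>
    sum()
}
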