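#' Score one patient-device questionnaire
#'
#' Sums the item subscores of a complete 12-item response set for a single
#' patient and device. The total lands on the 0--50 point S-GUS scale.
#'
#' @param responses A data frame with columns `item_id` and `level`
#'   containing exactly one response per item 1..12 (extra columns such as
#'   `patient_id`/`device_id` are ignored here).
#' @param config An [sgus_config()]; defaults to the shipped configuration.
#' @return Numeric S-GUS total in \[0, 50\].
#' @examples
#' best <- tibble::tibble(item_id = 1:12,
#'                        level = c(rep("yes", 9), "none", "none", "yes"))
#' score_device(best) # 50
#' @export
score_device <- function(responses, config = default_sgus_config()) {
  responses <- tibble::as_tibble(responses)
  ids <- responses$item_id
  if (anyDuplicated(ids)) {
    stop("duplicate response for item(s) ",
         paste(sort(unique(ids[duplicated(ids)])), collapse = ", "),
         call. = FALSE)
  }
  missing_items <- setdiff(1:12, ids)
  if (length(missing_items) > 0) {
    stop("missing response for item(s) ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  scored <- dplyr::left_join(
    responses, config,
    by = c("item_id", "level")
  )
  if (anyNA(scored$points)) {
    bad <- scored[is.na(scored$points), ]
    stop(sprintf("unknown level '%s' for item %d",
                 bad$level[1], bad$item_id[1]), call. = FALSE)
  }
  sum(scored$points)
}

#' Score a cohort of item responses
#'
#' Converts long-format item responses (one row per patient, device and
#' item) into one S-GUS total per patient-device pair. Scoring is
#' deterministic: the same input always yields the same output.
#'
#' @param responses A data frame with columns `patient_id`, `device_id`,
#'   `item_id`, `level`.
#' @param config An [sgus_config()].
#' @return A tibble with columns `patient_id`, `device_id`, `sgus_total`,
#'   one row per (patient, device) pair present in the input, ordered by
#'   patient then device.
#' @export
score_cohort <- function(responses, config = default_sgus_config()) {
  responses <- tibble::as_tibble(responses)
  req <- c("patient_id", "device_id", "item_id", "level")
  missing_cols <- setdiff(req, names(responses))
  if (length(missing_cols) > 0) {
    stop("responses are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(responses) == 0) {
    return(tibble::tibble(patient_id = character(),
                          device_id = character(),
                          sgus_total = numeric()))
  }
  responses |>
    dplyr::group_by(.data$patient_id, .data$device_id) |>
    dplyr::group_modify(function(grp, key) {
      total <- tryCatch(
        score_device(grp, config),
        error = function(e) {
          stop(sprintf("patient '%s', device '%s': %s",
                       key$patient_id, key$device_id, conditionMessage(e)),
               call. = FALSE)
        })
      tibble::tibble(sgus_total = total)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$patient_id, .data$device_id)
}

#' Read / write S-GUS tables as CSV
#'
#' Thin readr wrappers fixing the schemas used throughout the package:
#' responses (`patient_id`, `device_id`, `item_id`, `level`) and scores
#' (`patient_id`, `device_id`, `sgus_total`). UTF-8, comma-separated,
#' header row mandatory, `.` decimal; device ids are canonical names read
#' case-insensitively.
#'
#' @param path File path.
#' @param scores A scores data frame.
#' @name sgus_io
#' @export
read_responses <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    device_id = readr::col_character(),
    item_id = readr::col_integer(),
    level = readr::col_character()
  )) |>
    dplyr::mutate(device_id = canonical_device(.data$device_id))
}

#' @rdname sgus_io
#' @export
read_scores <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    device_id = readr::col_character(),
    sgus_total = readr::col_double()
  )) |>
    dplyr::mutate(device_id = canonical_device(.data$device_id))
}

#' @rdname sgus_io
#' @export
write_scores <- function(scores, path) {
  scores |>
    dplyr::mutate(sgus_total = round(.data$sgus_total, 1)) |>
    readr::write_csv(path)
  invisible(path)
}

# Canonical device spelling, case-insensitive on read; unknown names pass
# through unchanged (the model does not restrict the device universe).
canonical_device <- function(x) {
  canon <- dpi_devices()
  idx <- match(tolower(x), tolower(canon))
  ifelse(is.na(idx), x, canon[idx])
}

#' The six dry powder inhalers of the reference study design
#'
#' @return Character vector of canonical device names, alphabetical.
#' @export
dpi_devices <- function() {
  c("Breezhaler", "Diskus", "Ellipta", "Nexthaler", "Spiromax", "Turbohaler")
}
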