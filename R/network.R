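#' Build the evidence network of within-patient device comparisons
#'
#' In an incomplete-block usability study every patient who tested both
#' devices of a pair contributes a direct within-patient comparison. The
#' evidence network has devices as nodes and, on each unordered pair, an
#' edge weighted by the number of such patients. Under the reference design
#' Breezhaler--Spiromax is observed in all 33 patients, pairs within
#' Group 1 in 18 and pairs within Group 2 in 15.
#'
#' @param scores A data frame with columns `patient_id` and `device_id`
#'   (one row per observed score).
#' @return A tibble of class `evidence_network` with columns `device_a`,
#'   `device_b` (with `device_a < device_b` alphabetically) and `weight`;
#'   zero-weight pairs are omitted.
#' @export
build_network <- function(scores) {
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0) stop("scores must be nonempty", call. = FALSE)
  pairs <- scores |>
    dplyr::distinct(.data$patient_id, .data$device_id) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(grp, key) {
      d <- sort(grp$device_id)
      if (length(d) < 2) return(tibble::tibble(device_a = character(),
                                               device_b = character()))
      cmb <- utils::combn(d, 2)
      tibble::tibble(device_a = cmb[1, ], device_b = cmb[2, ])
    }) |>
    dplyr::ungroup() |>
    dplyr::count(.data$device_a, .data$device_b, name = "weight") |>
    dplyr::arrange(.data$device_a, .data$device_b)
  structure(pairs, class = c("evidence_network", class(pairs)))
}

#' Check that every device is reachable from the reference
#'
#' The indirect-comparison model is identified only if the evidence network
#' is connected: each device must be linked to the reference through
#' shared-patient edges.
#'
#' @param network An [build_network()] result.
#' @param reference Reference device name.
#' @return Invisibly `TRUE`; errors naming the unreachable devices
#'   otherwise.
#' @export
assert_connected <- function(network, reference) {
  nodes <- union(network$device_a, network$device_b)
  if (!reference %in% nodes) {
    stop("reference device '", reference, "' has no observations",
         call. = FALSE)
  }
  reached <- reference
  repeat {
    nxt <- union(network$device_b[network$device_a %in% reached],
                 network$device_a[network$device_b %in% reached])
    new_reached <- union(reached, nxt)
    if (length(new_reached) == length(reached)) break
    reached <- new_reached
  }
  unreachable <- setdiff(nodes, reached)
  if (length(unreachable) > 0) {
    stop("evidence network is disconnected; unreachable device(s): ",
         paste(sort(unreachable), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Plot an evidence network
#'
#' Devices on a circle, edges drawn with width proportional to the number
#' of patients providing the direct comparison.
#'
#' @param object An `evidence_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot evidence_network
#' @export
autoplot.evidence_network <- function(object, ...) {
  nodes <- sort(union(object$device_a, object$device_b))
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  layout <- tibble::tibble(device = nodes,
                           x = cos(theta), y = sin(theta))
  edges <- object |>
    dplyr::left_join(dplyr::rename(layout, device_a = "device",
                                   xa = "x", ya = "y"), by = "device_a") |>
    dplyr::left_join(dplyr::rename(layout, device_b = "device",
                                   xb = "x", yb = "y"), by = "device_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$weight),
      colour = "grey40") +
    ggplot2::geom_label(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$device)) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5), name = "patients") +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.2, 1.2)) +
    ggplot2::theme_void()
}
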