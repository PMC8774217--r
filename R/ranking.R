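#' Rank probabilities of the devices
#'
#' In each posterior draw the devices are ranked by their absolute mean
#' S-GUS, `mu + delta_d`, in descending order — rank 1 is the most usable
#' device. Exact ties within a draw (a measure-zero event for continuous
#' draws) are broken deterministically by device order, keeping reruns
#' reproducible. The empirical frequency of each (device, rank) pair over
#' the draws is the rank-probability matrix: each device's probabilities
#' sum to 1, and so do each rank's across devices.
#'
#' @param fit An [fit_ic_model()] object, or a numeric matrix of draws
#'   (rows) by devices (named columns).
#' @return A tibble of class `ic_ranking` with columns `device`, `rank`,
#'   `probability`, covering all device-rank combinations.
#' @export
rank_probabilities <- function(fit) {
  dd <- if (inherits(fit, "ic_fit")) device_draws(fit) else as.matrix(fit)
  D <- ncol(dd)
  if (D < 2) stop("ranking needs at least 2 devices", call. = FALSE)
  if (nrow(dd) == 0) stop("no posterior draws", call. = FALSE)
  # rank 1 = largest; ties.method = "first" breaks ties by column order
  counts <- matrix(0L, D, D, dimnames = list(colnames(dd), NULL))
  rk <- t(apply(-dd, 1, rank, ties.method = "first"))
  for (r in seq_len(D)) {
    counts[, r] <- colSums(rk == r)
  }
  probs <- counts / nrow(dd)
  out <- tibble::tibble(
    device = rep(rownames(probs), times = D),
    rank = rep(seq_len(D), each = D),
    probability = as.vector(probs)
  )
  structure(out, class = c("ic_ranking", class(out)))
}

#' Cumulative ranking curves
#'
#' For each device, `F_d(r) = P(rank <= r)`: the probability of being
#' among the top `r` devices. These are the curves whose area defines
#' SUCRA.
#'
#' @param ranking An [rank_probabilities()] tibble.
#' @return A tibble `device`, `rank`, `cumulative_probability`.
#' @export
cumulative_ranking <- function(ranking) {
  ranking |>
    dplyr::group_by(.data$device) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::mutate(cumulative_probability = cumsum(.data$probability)) |>
    dplyr::ungroup() |>
    dplyr::select("device", "rank", "cumulative_probability")
}

#' Surface under the cumulative ranking curve (SUCRA)
#'
#' \deqn{\mathrm{SUCRA}_d = \frac{1}{D-1} \sum_{r=1}^{D-1} F_d(r),}
#' where `F_d` is the cumulative rank distribution. SUCRA is 1 for a
#' device certain to rank first, 0 for one certain to rank last, and 0.5
#' under complete ranking uncertainty; the SUCRAs of all devices always
#' average to 0.5.
#'
#' @param ranking An [rank_probabilities()] tibble (or an `ic_fit`, which
#'   is ranked first).
#' @return A tibble `device`, `sucra`, sorted best (highest SUCRA) first.
#' @export
sucra <- function(ranking) {
  if (inherits(ranking, "ic_fit")) ranking <- rank_probabilities(ranking)
  D <- max(ranking$rank)
  if (D < 2) stop("SUCRA needs at least 2 devices", call. = FALSE)
  cumulative_ranking(ranking) |>
    dplyr::filter(.data$rank < D) |>
    dplyr::group_by(.data$device) |>
    dplyr::summarise(sucra = sum(.data$cumulative_probability) / (D - 1),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$sucra))
}

#' Classify device usability against the S-GUS threshold
#'
#' Devices whose posterior mean S-GUS exceeds the threshold (15 points by
#' default) are classed "good to pretty good"; the rest — including a mean
#' exactly at the threshold — are "insufficient".
#'
#' @param summary An [summarize_posterior()] object, or any data frame
#'   with columns `device` and `mean`.
#' @param threshold Classification cut point (points).
#' @return A tibble `device`, `mean`, (`lower`, `upper` when available,)
#'   `usability`.
#' @export
classify_usability <- function(summary, threshold = 15) {
  tbl <- if (inherits(summary, "ic_summary")) summary$devices
         else tibble::as_tibble(summary)
  tbl |>
    dplyr::mutate(usability = ifelse(.data$mean > threshold,
                                     "good to pretty good",
                                     "insufficient"))
}

#' Heterogeneity decomposition
#'
#' Per posterior draw, total variance is `tau^2 + sigma^2` and
#' \deqn{I^2 = \tau^2 / (\tau^2 + \sigma^2)} is the proportion of total
#' variability attributable to between-patient heterogeneity (the Higgins
#' & Thompson decomposition applied at the patient level). Variances are
#' summarized by their posterior means (so `total_var` equals
#' `tau2 + sigma2` identically); `I^2` by its posterior mean and credible
#' interval.
#'
#' @param fit An [fit_ic_model()] object, or a data frame of draws with
#'   columns `tau` and `sigma`.
#' @param level Credible level for the `I^2` interval.
#' @return A one-row tibble: `tau2`, `sigma2`, `total_var`, `i2`,
#'   `i2_lower`, `i2_upper`.
#' @export
heterogeneity <- function(fit, level = 0.90) {
  draws <- if (inherits(fit, "ic_fit")) fit$draws else tibble::as_tibble(fit)
  if (!all(c("tau", "sigma") %in% names(draws))) {
    stop("draws must contain tau and sigma", call. = FALSE)
  }
  tau2_draws <- draws$tau^2
  sigma2_draws <- draws$sigma^2
  i2_draws <- tau2_draws / (tau2_draws + sigma2_draws)
  i2_draws[tau2_draws + sigma2_draws == 0] <- 0
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  tibble::tibble(
    tau2 = mean(tau2_draws),
    sigma2 = mean(sigma2_draws),
    total_var = mean(tau2_draws) + mean(sigma2_draws),
    i2 = mean(i2_draws),
    i2_lower = stats::quantile(i2_draws, probs[1], names = FALSE),
    i2_upper = stats::quantile(i2_draws, probs[2], names = FALSE)
  )
}

#' Plot cumulative ranking curves
#'
#' One curve per device: the probability of being among the top `r`
#' devices as a function of `r`. Devices whose curve rises early rank
#' well.
#'
#' @param object An [rank_probabilities()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ic_ranking
#' @export
autoplot.ic_ranking <- function(object, ...) {
  cr <- cumulative_ranking(object)
  ggplot2::ggplot(cr, ggplot2::aes(x = .data$rank,
                                   y = .data$cumulative_probability,
                                   colour = .data$device)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq_len(max(cr$rank))) +
    ggplot2::labs(x = "Rank", y = "P(rank ≤ r)", colour = "Device") +
    ggplot2::theme_minimal()
}

#' Plot device usability estimates against the classification threshold
#'
#' Posterior mean S-GUS per device with its credible interval, ordered
#' best first, with the usability threshold drawn as a dashed line.
#'
#' @param summary An [summarize_posterior()] object.
#' @param threshold Classification cut point (points).
#' @return A ggplot.
#' @export
plot_usability <- function(summary, threshold = 15) {
  tbl <- classify_usability(summary, threshold)
  tbl$device <- stats::reorder(tbl$device, tbl$mean)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$mean, y = .data$device,
                                    colour = .data$usability)) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper), height = 0.2) +
    ggplot2::geom_point(size = 3, shape = 21, fill = "white") +
    ggplot2::labs(x = "S-GUS (points)", y = NULL, colour = "Usability") +
    ggplot2::theme_minimal()
}
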