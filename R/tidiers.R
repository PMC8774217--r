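#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted indirect-comparison model
#'
#' One row per model parameter (`mu`, each `delta_*`, `sigma`, `tau`) with
#' the posterior mean, SD and quantile credible interval.
#'
#' @param x An [fit_ic_model()] object.
#' @param level Credible level (defaults to the fit's, 0.90).
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @method tidy ic_fit
#' @export
tidy.ic_fit <- function(x, level = NULL, ...) {
  level <- level %||% x$level
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  pars <- setdiff(names(x$draws), "chain")
  pars <- pars[!startsWith(pars, "u_")]
  purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(term = p, estimate = mean(v), std.error = stats::sd(v),
                   conf.low = stats::quantile(v, probs[1], names = FALSE),
                   conf.high = stats::quantile(v, probs[2], names = FALSE))
  })
}

#' One-row fit summary
#'
#' Sampling settings, data dimensions, posterior means of the variance
#' components and the implied I-squared; with more than one chain the
#' worst split-Rhat across parameters is included.
#'
#' @param x An [fit_ic_model()] object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance ic_fit
#' @export
glance.ic_fit <- function(x, ...) {
  het <- heterogeneity(x)
  tibble::tibble(
    n_obs = x$n_obs,
    n_devices = length(x$devices),
    n_patients = length(x$patients),
    chains = x$chains,
    iterations = x$iterations,
    burnin = x$burnin,
    n_draws = nrow(x$draws),
    sigma = mean(x$draws$sigma),
    tau = mean(x$draws$tau),
    i_squared = het$i2,
    max_rhat = if (x$chains > 1) max_split_rhat(x) else NA_real_
  )
}

# Worst split-Rhat over the scalar model parameters.
max_split_rhat <- function(fit) {
  pars <- setdiff(names(fit$draws), "chain")
  pars <- pars[!startsWith(pars, "u_")]
  max(vapply(pars, function(p) {
    split_rhat(fit$draws[[p]], fit$draws$chain)
  }, numeric(1)))
}

# Split-Rhat: each chain halved, potential scale reduction across halves.
split_rhat <- function(x, chain) {
  halves <- lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[seq.int(h + 1, 2 * h)])
  })
  segs <- unlist(halves, recursive = FALSE)
  m <- length(segs)
  n <- length(segs[[1]])
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.ic_fit <- function(x, ...) {
  cat("Bayesian indirect-comparison fit\n")
  cat(sprintf("  devices: %s (reference: %s)\n",
              paste(x$devices, collapse = ", "), x$reference))
  cat(sprintf("  %d observations, %d patients\n",
              x$n_obs, length(x$patients)))
  cat(sprintf("  %d chain(s) x %d iterations (burn-in %d), %d draws kept\n",
              x$chains, x$iterations, x$burnin, nrow(x$draws)))
  invisible(x)
}

#' @export
print.ic_summary <- function(x, ...) {
  cat(sprintf("Posterior device estimates (%.0f%% CrI):\n", 100 * x$level))
  print(x$devices)
  cat("\nPairwise comparisons (first rows):\n")
  print(utils::head(x$comparisons, 6))
  invisible(x)
}
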