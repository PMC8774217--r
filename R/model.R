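#' Fit the Bayesian hierarchical indirect-comparison model
#'
#' Merges all pairwise device comparisons from an incomplete-block
#' usability study into a single hierarchical random-effects model. The
#' contrast-level formulation of the usability difference
#' \eqn{\delta_{ij}} with patient heterogeneity \eqn{u_s \sim N(0,\tau^2)}
#' is fitted in its arm-level equivalent
#' \deqn{Y_{sd} \sim N(\mu + \delta_d + u_s,\ \sigma^2), \qquad
#'       u_s \sim N(0, \tau^2), \qquad \delta_{\mathrm{ref}} \equiv 0,}
#' which carries the same estimands — absolute device means and every
#' pairwise absolute mean difference \eqn{\delta_i - \delta_j} — while
#' keeping the patient effect identified (one score per patient-device
#' rather than one contrast per patient-pair). Priors are vague:
#' \eqn{N(0, 10^4)} on \eqn{\mu} and each \eqn{\delta_d}, and
#' \eqn{\mathrm{Uniform}(0, 5)} on both standard deviations
#' \eqn{\sigma} and \eqn{\tau}.
#'
#' Sampling is by a Gibbs scheme: all location parameters have exact
#' normal conditional-conjugate updates, and each standard deviation is
#' drawn exactly from its truncated inverse-gamma full conditional by
#' inverse-CDF sampling on the precision scale (respecting the
#' Uniform(0, 5) support), so the sampler has no tuning parameters.
#'
#' @param scores Data frame with columns `patient_id`, `device_id`,
#'   `sgus_total`. May have zero rows, in which case the posterior equals
#'   the prior (useful for prior-predictive checks).
#' @param reference Reference device; defaults to `"Breezhaler"` when
#'   present (tested by every patient under the reference design, hence
#'   the most informative baseline) and otherwise to the first device
#'   alphabetically. The choice affects no between-device difference.
#' @param iterations Total MCMC iterations in the single chain.
#' @param burnin Iterations discarded before summarizing.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed RNG seed; fits are exactly reproducible given the seed.
#' @param chains Number of chains (1 reproduces the reference analysis;
#'   more enable split-Rhat diagnostics via [glance.ic_fit()]).
#' @param prior_effect_sd Prior SD of `mu` and each `delta` (default 100,
#'   i.e. variance 10^4).
#' @param sd_upper Upper bound of the uniform priors on `sigma` and `tau`.
#' @param sigma_fixed,tau_fixed Optionally fix a standard deviation at a
#'   known value instead of sampling it (used when validating against the
#'   closed-form Gaussian posterior).
#' @param level Default credible level carried to summaries (0.90: the
#'   5th and 95th posterior percentiles).
#' @param store_u Keep the patient-effect draws? (They are needed only for
#'   patient-level diagnostics.)
#' @return An object of class `ic_fit`: a list with `draws` (a tibble with
#'   one row per retained draw: `chain`, `mu`, one `delta_*` column per
#'   non-reference device, `sigma`, `tau`, and optionally `u_*` columns),
#'   `devices`, `reference`, and the sampling settings.
#' @examples
#' cohort <- simulate_cohort(default_study_spec(), seed = 7)
#' fit <- fit_ic_model(cohort$scores, iterations = 2000, burnin = 1000)
#' tidy(fit)
#' @export
fit_ic_model <- function(scores,
                         reference = NULL,
                         iterations = 100000L,
                         burnin = 50000L,
                         thin = 1L,
                         seed = 1L,
                         chains = 1L,
                         prior_effect_sd = 100,
                         sd_upper = 5,
                         sigma_fixed = NULL,
                         tau_fixed = NULL,
                         level = 0.90,
                         store_u = FALSE) {
  if (burnin >= iterations) {
    stop("burnin must be smaller than iterations", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  scores <- tibble::as_tibble(scores)

  if (nrow(scores) > 0) {
    devices <- sort(unique(scores$device_id))
    if (is.null(reference)) {
      reference <- if ("Breezhaler" %in% devices) "Breezhaler" else devices[1]
    }
    if (!reference %in% devices) {
      stop("reference device '", reference, "' not present in the scores",
           call. = FALSE)
    }
    if (length(devices) > 1) {
      assert_connected(build_network(scores), reference)
    }
    patients <- sort(unique(scores$patient_id))
    y <- scores$sgus_total
    dev <- match(scores$device_id, devices)
    pat <- match(scores$patient_id, patients)
  } else {
    devices <- character()
    reference <- reference %||% NA_character_
    patients <- character()
    y <- numeric()
    dev <- integer()
    pat <- integer()
  }

  ref_idx <- match(reference, devices)
  draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    draws[[ch]] <- gibbs_ic(
      y = y, dev = dev, pat = pat,
      n_dev = length(devices), n_pat = length(patients),
      ref_idx = ref_idx,
      iterations = as.integer(iterations), burnin = as.integer(burnin),
      thin = as.integer(thin),
      prior_var = prior_effect_sd^2, sd_upper = sd_upper,
      sigma_fixed = sigma_fixed, tau_fixed = tau_fixed,
      seed = seed + ch - 1L, chain = ch, store_u = store_u,
      devices = devices, patients = patients)
  }
  draws <- dplyr::bind_rows(draws)

  structure(list(
    draws = draws,
    devices = devices,
    reference = reference,
    patients = patients,
    n_obs = length(y),
    iterations = iterations, burnin = burnin, thin = thin,
    chains = chains, seed = seed, level = level,
    sigma_fixed = sigma_fixed, tau_fixed = tau_fixed
  ), class = "ic_fit")
}

# Gibbs kernel. Location parameters: exact normal conjugate updates.
# sigma/tau: full conditional p(s) propto s^-m exp(-b/s^2) on (0, upper),
# i.e. precision 1/s^2 ~ Gamma((m-1)/2, rate=b) truncated to > 1/upper^2;
# sampled exactly by inverse CDF. m <= 1 or b ~ 0 degenerates to the
# uniform prior (no information), which is then drawn directly.
gibbs_ic <- function(y, dev, pat, n_dev, n_pat, ref_idx,
                     iterations, burnin, thin, prior_var, sd_upper,
                     sigma_fixed, tau_fixed, seed, chain, store_u,
                     devices, patients) {
  set.seed(seed)
  n <- length(y)
  n_d <- if (n_dev > 0) tabulate(dev, n_dev) else integer()
  n_s <- if (n_pat > 0) tabulate(pat, n_pat) else integer()
  free_dev <- setdiff(seq_len(n_dev), ref_idx)

  mu <- if (n > 0) mean(y) else 0
  delta <- numeric(n_dev)
  u <- numeric(n_pat)
  sigma <- sigma_fixed %||% (sd_upper / 2)
  tau <- tau_fixed %||% (sd_upper / 2)

  keep <- seq.int(burnin + 1L, iterations, by = thin)
  n_keep <- length(keep)
  out <- matrix(NA_real_, nrow = n_keep,
                ncol = 1L + length(free_dev) + 2L +
                       if (store_u) n_pat else 0L)
  kk <- 0L

  for (it in seq_len(iterations)) {
    sig2 <- sigma^2

    # mu | rest
    resid <- if (n > 0) y - delta[dev] - u[pat] else numeric()
    prec <- n / sig2 + 1 / prior_var
    mu <- stats::rnorm(1, (sum(resid) / sig2) / prec, sqrt(1 / prec))

    # delta_d | rest, d != reference (conditionally independent)
    if (length(free_dev) > 0) {
      s_d <- rowsum(y - mu - u[pat], dev, reorder = TRUE)[, 1]
      prec_d <- n_d[free_dev] / sig2 + 1 / prior_var
      delta[free_dev] <- stats::rnorm(length(free_dev),
                                      (s_d[free_dev] / sig2) / prec_d,
                                      sqrt(1 / prec_d))
    }

    # u_s | rest (conditionally independent); tau = 0 pins them at 0
    if (n_pat > 0) {
      if (tau == 0) {
        u[] <- 0
      } else {
        s_s <- rowsum(y - mu - delta[dev], pat, reorder = TRUE)[, 1]
        prec_s <- n_s / sig2 + 1 / tau^2
        u <- stats::rnorm(n_pat, (s_s / sig2) / prec_s, sqrt(1 / prec_s))
      }
    }

    # sigma | rest
    if (is.null(sigma_fixed)) {
      rss <- if (n > 0) sum((y - mu - delta[dev] - u[pat])^2) else 0
      sigma <- draw_truncated_sd(m = n, b = rss / 2, upper = sd_upper)
    }
    # tau | rest
    if (is.null(tau_fixed)) {
      tau <- draw_truncated_sd(m = n_pat, b = sum(u^2) / 2, upper = sd_upper)
    }

    if (it > burnin && (it - burnin - 1L) %% thin == 0L) {
      kk <- kk + 1L
      out[kk, ] <- c(mu, delta[free_dev], sigma, tau,
                     if (store_u) u)
    }
  }

  cols <- c("mu",
            if (length(free_dev) > 0) paste0("delta_", devices[free_dev]),
            "sigma", "tau",
            if (store_u) paste0("u_", patients))
  res <- tibble::as_tibble(as.data.frame(out))
  names(res) <- cols
  res$chain <- chain
  dplyr::relocate(res, "chain")
}

# Exact draw from p(s) propto s^(-m) exp(-b / s^2) on (0, upper).
draw_truncated_sd <- function(m, b, upper) {
  shape <- (m - 1) / 2
  if (shape <= 0 || b <= .Machine$double.eps) {
    return(stats::runif(1, 0, upper))
  }
  p_lo <- stats::pgamma(1 / upper^2, shape, rate = b)
  uu <- stats::runif(1, p_lo, 1)
  uu <- min(uu, 1 - 1e-16)
  g <- stats::qgamma(uu, shape, rate = b)
  1 / sqrt(g)
}

#' Per-draw absolute device means
#'
#' Returns the matrix of posterior draws of `mu + delta_d` (the absolute
#' S-GUS level of each device), with the reference device's delta fixed at
#' zero. This is the quantity devices are ranked on.
#'
#' @param fit An [fit_ic_model()] object.
#' @return A numeric matrix, draws in rows, one column per device.
#' @export
device_draws <- function(fit) {
  stopifnot(inherits(fit, "ic_fit"))
  d <- fit$draws
  out <- sapply(fit$devices, function(dv) {
    col <- paste0("delta_", dv)
    if (col %in% names(d)) d$mu + d[[col]] else d$mu
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = length(fit$devices),
                                       dimnames = list(NULL, fit$devices))
  out
}

#' Exact Gaussian posterior with known variance components
#'
#' With the residual SD `sigma` and patient SD `tau` fixed and flat priors
#' on the location parameters, the model is linear-Gaussian and the
#' posterior of `(mu, delta)` is available in closed form by generalized
#' least squares: `y ~ N(X beta, V)` with
#' `V = sigma^2 I + tau^2 Z Z'` (Z the patient indicator matrix), so
#' `beta | y ~ N((X'V^-1 X)^-1 X'V^-1 y, (X'V^-1 X)^-1)`. Used as the
#' independent oracle the MCMC sampler is validated against.
#'
#' @param scores Data frame with `patient_id`, `device_id`, `sgus_total`.
#' @param sigma,tau Fixed standard deviations (points).
#' @param reference Reference device (default as in [fit_ic_model()]).
#' @return A list with `mean` (named vector: `mu`, then `delta_*` for each
#'   non-reference device) and `cov` (posterior covariance matrix).
#' @export
conjugate_posterior <- function(scores, sigma, tau, reference = NULL) {
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0) stop("scores must be nonempty", call. = FALSE)
  devices <- sort(unique(scores$device_id))
  if (is.null(reference)) {
    reference <- if ("Breezhaler" %in% devices) "Breezhaler" else devices[1]
  }
  patients <- sort(unique(scores$patient_id))
  n <- nrow(scores)
  free <- setdiff(devices, reference)
  X <- matrix(1, n, 1)
  if (length(free) > 0) {
    X <- cbind(X, sapply(free, function(dv) {
      as.numeric(scores$device_id == dv)
    }))
  }
  colnames(X) <- c("mu", if (length(free) > 0) paste0("delta_", free))
  Z <- sapply(patients, function(p) as.numeric(scores$patient_id == p))
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = length(patients))
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  V <- sigma^2 * diag(n) + tau^2 * (Z %*% t(Z))
  Vinv <- tryCatch(solve(V), error = function(e) {
    stop("marginal covariance is numerically singular for this cohort",
         call. = FALSE)
  })
  XtVX <- t(X) %*% Vinv %*% X
  if (rcond(XtVX) < 1e-12) {
    stop("design matrix is rank deficient for this cohort", call. = FALSE)
  }
  cov <- solve(XtVX)
  mean <- drop(cov %*% t(X) %*% Vinv %*% scores$sgus_total)
  list(mean = stats::setNames(mean, colnames(X)), cov = cov,
       reference = reference, devices = devices)
}

#' Summarize the posterior as device estimates and pairwise comparisons
#'
#' Device estimates are posterior means of `mu + delta_d` with
#' quantile-based credible intervals (5th/95th percentiles at the default
#' 90% level). Every ordered device pair gets its absolute mean difference
#' (AMD), credible interval, and posterior probability
#' `post_p = P(delta_i > delta_j | data)`; draws with an exact tie (a
#' measure-zero event for continuous draws) are split 50/50.
#'
#' @param fit An [fit_ic_model()] object.
#' @param level Credible level (defaults to the fit's).
#' @return An object of class `ic_summary`: list with `devices` (tibble
#'   `device`, `mean`, `lower`, `upper`) and `comparisons` (tibble
#'   `device_i`, `device_j`, `amd`, `lower`, `upper`, `post_p` for every
#'   ordered pair).
#' @export
summarize_posterior <- function(fit, level = NULL) {
  stopifnot(inherits(fit, "ic_fit"))
  level <- level %||% fit$level
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  dd <- device_draws(fit)
  if (nrow(dd) == 0) stop("fit contains no posterior draws", call. = FALSE)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  devices_tbl <- tibble::tibble(
    device = colnames(dd),
    mean = unname(colMeans(dd)),
    lower = unname(apply(dd, 2, stats::quantile, probs[1])),
    upper = unname(apply(dd, 2, stats::quantile, probs[2]))
  )

  pairs <- tidyr::expand_grid(device_i = colnames(dd),
                              device_j = colnames(dd)) |>
    dplyr::filter(.data$device_i != .data$device_j)
  comp <- purrr::pmap_dfr(pairs, function(device_i, device_j) {
    diff <- dd[, device_i] - dd[, device_j]
    tibble::tibble(
      device_i = device_i, device_j = device_j,
      amd = mean(diff),
      lower = stats::quantile(diff, probs[1], names = FALSE),
      upper = stats::quantile(diff, probs[2], names = FALSE),
      post_p = mean(diff > 0) + 0.5 * mean(diff == 0)
    )
  })

  structure(list(devices = devices_tbl, comparisons = comp,
                 level = level, reference = fit$reference),
            class = "ic_summary")
}

#' Lay out an `ic_summary` as the publication-style comparison matrix
#'
#' Devices on the diagonal (ordered by descending SUCRA when a ranking is
#' supplied, otherwise by descending posterior mean) showing the absolute
#' S-GUS estimate with its credible interval; the lower triangle holds the
#' AMD of the column device minus the row device with its interval; the
#' upper triangle holds the posterior probabilities.
#'
#' @param summary An [summarize_posterior()] result.
#' @param sucra Optional [sucra()] tibble used to order the diagonal.
#' @return A character data.frame, ready for `readr::write_csv`.
#' @export
format_comparison_table <- function(summary, sucra = NULL) {
  stopifnot(inherits(summary, "ic_summary"))
  dv <- summary$devices
  ord <- if (!is.null(sucra)) {
    sucra$device[order(-sucra$sucra)]
  } else {
    dv$device[order(-dv$mean)]
  }
  D <- length(ord)
  m <- matrix("", D, D, dimnames = list(ord, ord))
  for (i in seq_len(D)) {
    row <- dv[dv$device == ord[i], ]
    m[i, i] <- sprintf("%s S-GUS = %.1f (%.0f%% CrI %.1f to %.1f)",
                       ord[i], row$mean, 100 * summary$level,
                       row$lower, row$upper)
    for (j in seq_len(D)) {
      if (j >= i) next
      cmp <- summary$comparisons[
        summary$comparisons$device_i == ord[j] &
        summary$comparisons$device_j == ord[i], ]
      m[i, j] <- sprintf("AMD = %.2f (%.0f%% CrI %.1f to %.1f)",
                         cmp$amd, 100 * summary$level, cmp$lower, cmp$upper)
      m[j, i] <- sprintf("Post p = %.3f", cmp$post_p)
    }
  }
  as.data.frame(m)
}
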