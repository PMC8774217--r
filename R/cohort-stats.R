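#' Exact Fisher test for a 2x2 table
#'
#' Conditions on both margins, so the Group-1 "yes" count `a` follows a
#' hypergeometric distribution. The default one-sided lower tail
#' `p = P(X <= a)` is the convention that reproduces the baseline-table
#' p-values of the reference analysis; `"greater"` gives the upper tail,
#' `"observed"` the one-sided tail in the observed direction (the smaller
#' of the two), and `"two.sided"` sums the probabilities of all tables no
#' more probable than the observed one (the usual two-sided rule).
#'
#' @param a,b Group 1 yes / no counts.
#' @param c,d Group 2 yes / no counts.
#' @param alternative Tail convention; see Details.
#' @return The p-value.
#' @examples
#' fisher_exact(7, 11, 10, 5) # 0.107: males by group
#' @export
fisher_exact <- function(a, b, c, d,
                         alternative = c("less", "greater",
                                         "observed", "two.sided")) {
  alternative <- match.arg(alternative)
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  m <- a + b   # group 1 size
  n2 <- c + d  # group 2 size
  k <- a + c   # total yes
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) {
    stop("all table margins must be positive", call. = FALSE)
  }
  lower <- stats::phyper(a, m, n2, k)
  upper <- stats::phyper(a - 1, m, n2, k, lower.tail = FALSE)
  switch(alternative,
    less = lower,
    greater = upper,
    observed = min(lower, upper),
    two.sided = {
      support <- max(0, k - n2):min(k, m)
      dens <- stats::dhyper(support, m, n2, k)
      # tables no more probable than the observed (relative tolerance as
      # in the classical implementation)
      sum(dens[dens <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)])
    })
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test comparing two samples (used for the age
#' distribution between design groups). For combined sample size up to 20
#' the exact permutation null distribution of the rank sum is enumerated
#' in full (midranks, so ties are handled exactly); for larger samples a
#' normal approximation with tie correction and continuity correction is
#' used. The two-sided p doubles the smaller tail (the permutation
#' distribution of the rank sum is symmetric), capped at 1.
#'
#' @param x,y Numeric samples.
#' @param method `"auto"` (exact when `length(x) + length(y) <= 20`),
#'   `"exact"`, or `"approx"`.
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))  # midranks
  w <- sum(r[seq_len(n1)])
  if (method == "auto") method <- if (n <= 20) "exact" else "approx"

  if (method == "exact") {
    sums <- utils::combn(r, n1, sum)
    p_le <- mean(sums <= w + 1e-9)
    p_ge <- mean(sums >= w - 1e-9)
    min(1, 2 * min(p_le, p_ge))
  } else {
    mu_w <- n1 * (n + 1) / 2
    ties <- table(r)
    var_w <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu_w - sign(w - mu_w) * 0.5) / sqrt(var_w)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Power specification for the sample-size algorithm
#'
#' Encodes the three published usability classes with their mean S-GUS and
#' 95% intervals: good 26 (21--32), pretty good 20 (15--25), insufficient
#' 11 (8--13). Each class SD is derived from its interval as half-width
#' divided by 1.959964 unless overridden.
#'
#' @param alpha Two-sided type-I error.
#' @param power Target power.
#' @param classes A tibble with columns `class`, `mean`, `lower`, `upper`.
#' @return A list of class `power_spec`.
#' @export
power_spec <- function(alpha = 0.05, power = 0.80, classes = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)", call. = FALSE)
  if (is.null(classes)) {
    classes <- tibble::tibble(
      class = c("good", "pretty good", "insufficient"),
      mean = c(26, 20, 11),
      lower = c(21, 15, 8),
      upper = c(32, 25, 13))
  }
  if (any(classes$lower > classes$mean | classes$mean > classes$upper)) {
    stop("class interval bounds must bracket the mean", call. = FALSE)
  }
  structure(list(alpha = alpha, power = power,
                 classes = tibble::as_tibble(classes)),
            class = "power_spec")
}

#' Sample size for detecting between-class usability differences
#'
#' For each pair of usability classes the detectable difference is the
#' difference of class means and the dispersion is the pooled SD
#' `sqrt((sd_1^2 + sd_2^2)/2)` with each class SD taken as its 95%
#' interval half-width over 1.959964. The per-group sample size follows
#' the two-sample normal-approximation formula
#' \deqn{n = \lceil 2 (z_{1-\alpha/2} + z_{\mathrm{power}})^2
#'       \sigma_p^2 / \Delta^2 \rceil,}
#' and the recommended study size is the largest total (both groups) over
#' the three comparisons. Every rule here (SD derivation, formula,
#' ceiling) is explicit and configurable through the spec.
#'
#' @param spec A [power_spec()].
#' @return A list with `comparisons` (tibble: `class_1`, `class_2`,
#'   `delta`, `sd_pooled`, `n_per_group`, `n_total`) and `n_final` (the
#'   maximum total).
#' @export
sample_size <- function(spec = power_spec()) {
  stopifnot(inherits(spec, "power_spec"))
  cl <- spec$classes
  cl$sd <- (cl$upper - cl$lower) / (2 * 1.959964)
  z <- stats::qnorm(1 - spec$alpha / 2) + stats::qnorm(spec$power)
  pairs <- utils::combn(seq_len(nrow(cl)), 2)
  comparisons <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    delta <- abs(cl$mean[i] - cl$mean[j])
    if (delta == 0) {
      stop("no detectable difference between classes '", cl$class[i],
           "' and '", cl$class[j], "'", call. = FALSE)
    }
    sd_pooled <- sqrt((cl$sd[i]^2 + cl$sd[j]^2) / 2)
    n_grp <- ceiling(2 * z^2 * sd_pooled^2 / delta^2)
    tibble::tibble(class_1 = cl$class[i], class_2 = cl$class[j],
                   delta = delta, sd_pooled = sd_pooled,
                   n_per_group = n_grp, n_total = 2 * n_grp)
  })
  list(comparisons = comparisons, n_final = max(comparisons$n_total))
}

#' Baseline characteristics table with group-comparison p-values
#'
#' Summarizes a demographics table into the publication-style baseline
#' layout: counts and percentages per group for categorical variables
#' (with an exact Fisher test: one-sided in the observed direction for
#' binary variables, Freeman--Halton two-sided for variables with more
#' than two levels) and mean (SD) with a Wilcoxon rank-sum test for age.
#'
#' @param demographics Tibble with columns `patient_id`, `group` (two
#'   levels), `sex`, `age`, `instructed_dpi`, `instructed_mdi`,
#'   `instructed_smi`, `region`, `education` (missing columns are
#'   skipped).
#' @return A tibble: `variable`, `level`, `total`, `group_1`, `group_2`,
#'   `p_value`, `method`.
#' @export
baseline_table <- function(demographics) {
  demographics <- tibble::as_tibble(demographics)
  groups <- sort(unique(demographics$group))
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  g1 <- demographics[demographics$group == groups[1], ]
  g2 <- demographics[demographics$group == groups[2], ]
  fmt_n <- function(k, n) sprintf("%d (%.1f%%)", k, 100 * k / n)

  binary_row <- function(variable, x1, x2) {
    a <- sum(x1); b <- sum(!x1); c <- sum(x2); d <- sum(!x2)
    p <- tryCatch(fisher_exact(a, b, c, d, alternative = "observed"),
                  error = function(e) NA_real_)
    tibble::tibble(variable = variable, level = "yes",
                   total = fmt_n(a + c, length(x1) + length(x2)),
                   group_1 = fmt_n(a, length(x1)),
                   group_2 = fmt_n(c, length(x2)),
                   p_value = p, method = "Fisher exact (one-sided)")
  }
  rows <- list()
  if ("sex" %in% names(demographics)) {
    rows <- c(rows, list(binary_row("male",
                                    g1$sex == "male", g2$sex == "male")))
  }
  for (v in intersect(c("instructed_dpi", "instructed_mdi",
                        "instructed_smi"), names(demographics))) {
    rows <- c(rows, list(binary_row(v, as.logical(g1[[v]]),
                                    as.logical(g2[[v]]))))
  }
  if ("age" %in% names(demographics)) {
    p <- wilcoxon_rank_sum(g1$age, g2$age)
    rows <- c(rows, list(tibble::tibble(
      variable = "age", level = "mean (SD)",
      total = sprintf("%.1f (%.2f)", mean(demographics$age),
                      stats::sd(demographics$age)),
      group_1 = sprintf("%.1f (%.2f)", mean(g1$age), stats::sd(g1$age)),
      group_2 = sprintf("%.1f (%.2f)", mean(g2$age), stats::sd(g2$age)),
      p_value = p, method = "Wilcoxon rank-sum")))
  }
  for (v in intersect(c("region", "education"), names(demographics))) {
    levels_v <- sort(unique(demographics[[v]]))
    tab <- rbind(table(factor(g1[[v]], levels_v)),
                 table(factor(g2[[v]], levels_v)))
    if (length(levels_v) == 2) {
      p <- fisher_exact(tab[1, 2], tab[1, 1], tab[2, 2], tab[2, 1],
                        alternative = "observed")
      method <- "Fisher exact (one-sided)"
    } else {
      p <- stats::fisher.test(tab)$p.value
      method <- "Fisher exact (Freeman-Halton)"
    }
    rows <- c(rows, list(purrr::map_dfr(seq_along(levels_v), function(i) {
      tibble::tibble(
        variable = v, level = levels_v[i],
        total = fmt_n(sum(tab[, i]), nrow(demographics)),
        group_1 = fmt_n(tab[1, i], nrow(g1)),
        group_2 = fmt_n(tab[2, i], nrow(g2)),
        p_value = if (i == 1) p else NA_real_, method = method)
    })))
  }
  dplyr::bind_rows(rows)
}
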