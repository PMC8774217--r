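test_that("identical scores for every device give null differences", {
  scores <- tidyr::expand_grid(patient_id = sprintf("P%d", 1:10),
                               device_id = c("A", "B", "C"))
  scores$sgus_total <- 30
  fit <- fit_ic_model(scores, reference = "A",
                      iterations = 6000, burnin = 2000, seed = 4)
  s <- summarize_posterior(fit)
  expect_true(all(abs(s$comparisons$amd) < 0.5))
})

test_that("a pure location shift is recovered", {
  scores <- two_device_cohort(n_patients = 12, shift = 5, noise_sd = 0.5)
  fit <- fit_ic_model(scores, reference = "A",
                      iterations = 8000, burnin = 3000, seed = 4)
  amd <- summarize_posterior(fit)$comparisons
  ba <- amd[amd$device_i == "B" & amd$device_j == "A", ]
  expect_equal(ba$amd, 5, tolerance = 0.5)
  expect_gt(ba$post_p, 0.99)
})

test_that("sampler matches the closed-form posterior with fixed variances", {
  scores <- two_device_cohort(n_patients = 8, shift = 5, noise_sd = 1)
  oracle <- conjugate_posterior(scores, sigma = 1, tau = 0, reference = "A")
  fit <- fit_ic_model(scores, reference = "A", sigma_fixed = 1, tau_fixed = 0,
                      iterations = 30000, burnin = 5000, seed = 8)
  est <- tidy(fit)
  amd_mean <- est$estimate[est$term == "delta_B"]
  amd_sd <- est$std.error[est$term == "delta_B"]
  expect_equal(amd_mean, unname(oracle$mean["delta_B"]), tolerance = 0.05)
  expect_equal(amd_sd, sqrt(oracle$cov["delta_B", "delta_B"]),
               tolerance = 0.05)

  # and with a nonzero patient SD the GLS covariance is still matched
  oracle2 <- conjugate_posterior(scores, sigma = 1, tau = 2, reference = "A")
  fit2 <- fit_ic_model(scores, reference = "A", sigma_fixed = 1,
                       tau_fixed = 2, iterations = 30000, burnin = 5000,
                       seed = 8)
  est2 <- tidy(fit2)
  expect_equal(est2$estimate[est2$term == "mu"],
               unname(oracle2$mean["mu"]), tolerance = 0.1)
  expect_equal(est2$std.error[est2$term == "mu"],
               sqrt(oracle2$cov["mu", "mu"]), tolerance = 0.05)
})

test_that("conjugate oracle reduces to textbook limits", {
  one_dev <- tibble::tibble(patient_id = sprintf("P%d", 1:6),
                            device_id = "A",
                            sgus_total = c(18, 22, 20, 19, 21, 23))
  post <- conjugate_posterior(one_dev, sigma = 2, tau = 0)
  expect_equal(unname(post$mean["mu"]), mean(one_dev$sgus_total))
  expect_equal(post$cov["mu", "mu"], 4 / 6)

  crossed <- two_device_cohort(n_patients = 5, shift = 3, noise_sd = 1)
  post2 <- conjugate_posterior(crossed, sigma = 1, tau = 0, reference = "A")
  means <- tapply(crossed$sgus_total, crossed$device_id, mean)
  expect_equal(unname(post2$mean["delta_B"]),
               unname(means["B"] - means["A"]))

  degenerate <- tibble::tibble(patient_id = "P1", device_id = c("A", "B"),
                               sgus_total = c(1, 2))
  expect_error(conjugate_posterior(degenerate, sigma = 0, tau = 5),
               "sigma must be positive")
  expect_error(conjugate_posterior(degenerate, sigma = 1e-8, tau = 5),
               "singular|rank deficient")
})

test_that("draw-level consistency holds exactly: AMD(i,k) = AMD(i,j) + AMD(j,k)", {
  cohort <- simulate_cohort(default_study_spec(), seed = 12)
  fit <- fit_ic_model(cohort$scores, iterations = 3000, burnin = 1000,
                      seed = 2)
  dd <- device_draws(fit)
  lhs <- dd[, "Ellipta"] - dd[, "Diskus"]
  rhs <- (dd[, "Ellipta"] - dd[, "Spiromax"]) +
    (dd[, "Spiromax"] - dd[, "Diskus"])
  expect_equal(lhs, rhs, tolerance = 1e-12)
  s <- summarize_posterior(fit)
  cmp <- s$comparisons
  amd <- function(i, j) cmp$amd[cmp$device_i == i & cmp$device_j == j]
  expect_equal(amd("Ellipta", "Diskus"),
               amd("Ellipta", "Spiromax") + amd("Spiromax", "Diskus"),
               tolerance = 1e-12)
})

test_that("posterior summaries have the stated structure", {
  cohort <- simulate_cohort(default_study_spec(), seed = 12)
  fit <- fit_ic_model(cohort$scores, iterations = 3000, burnin = 1000,
                      seed = 2)
  s <- summarize_posterior(fit)
  expect_equal(nrow(s$devices), 6)
  expect_equal(nrow(s$comparisons), 30) # ordered pairs
  expect_true(all(s$devices$lower <= s$devices$mean &
                    s$devices$mean <= s$devices$upper))
  cmp <- s$comparisons
  rev_idx <- match(paste(cmp$device_j, cmp$device_i),
                   paste(cmp$device_i, cmp$device_j))
  expect_equal(cmp$amd, -cmp$amd[rev_idx], tolerance = 1e-12)
  expect_equal(cmp$post_p + cmp$post_p[rev_idx], rep(1, nrow(cmp)),
               tolerance = 1e-12)
  dv <- s$devices
  ed <- cmp[cmp$device_i == "Ellipta" & cmp$device_j == "Diskus", ]
  expect_equal(ed$amd, unname(dv$mean[dv$device == "Ellipta"] -
                                dv$mean[dv$device == "Diskus"]),
               tolerance = 1e-12)
})

test_that("summarize handles degenerate and constructed draws", {
  # constant draws: mean equals the constant, CrI collapses onto it
  fit <- structure(list(
    draws = tibble::tibble(chain = 1L, mu = rep(3.44, 100),
                           sigma = 1, tau = 1),
    devices = "A", reference = "A", patients = character(),
    n_obs = 0L, iterations = 100L, burnin = 0L, thin = 1L, chains = 1L,
    seed = 1L, level = 0.9, sigma_fixed = NULL, tau_fixed = NULL),
    class = "ic_fit")
  s <- summarize_posterior(fit)
  expect_equal(s$devices$mean, 3.44)
  expect_equal(s$devices$lower, 3.44)
  expect_equal(s$devices$upper, 3.44)

  # draws constructed so that delta_E - delta_D > 0 in exactly 97% of draws
  draws <- tibble::tibble(chain = 1L, mu = rep(0, 1000),
                          delta_E = c(rep(1, 970), rep(-1, 30)),
                          delta_D = 0, sigma = 1, tau = 1)
  fit2 <- structure(list(draws = draws, devices = c("B", "D", "E"),
                         reference = "B", patients = character(),
                         n_obs = 0L, iterations = 1000L, burnin = 0L,
                         thin = 1L, chains = 1L, seed = 1L, level = 0.9,
                         sigma_fixed = NULL, tau_fixed = NULL),
                    class = "ic_fit")
  names(fit2$draws) <- c("chain", "mu", "delta_E", "delta_D", "sigma", "tau")
  s2 <- summarize_posterior(fit2)
  cmp <- s2$comparisons
  expect_equal(cmp$post_p[cmp$device_i == "E" & cmp$device_j == "D"], 0.97)
  # exact ties split 50/50
  expect_equal(cmp$post_p[cmp$device_i == "B" & cmp$device_j == "D"], 0.5)
})

test_that("spec validation and reproducibility contracts hold", {
  scores <- two_device_cohort()
  expect_error(fit_ic_model(scores, iterations = 100, burnin = 100),
               "burnin")
  expect_error(fit_ic_model(scores, iterations = 100, burnin = 10,
                            level = 1.2), "level")
  f1 <- fit_ic_model(scores, iterations = 500, burnin = 100, seed = 77)
  f2 <- fit_ic_model(scores, iterations = 500, burnin = 100, seed = 77)
  expect_identical(f1$draws, f2$draws)
  expect_error(summarize_posterior(f1, level = 0), "level")
})

test_that("multi-chain mode converges with split-Rhat near 1", {
  scores <- two_device_cohort(n_patients = 10)
  fit <- fit_ic_model(scores, iterations = 4000, burnin = 2000,
                      chains = 2, seed = 5)
  g <- glance(fit)
  expect_equal(g$chains, 2)
  expect_lt(g$max_rhat, 1.05)
  expect_equal(nrow(fit$draws), 2 * 2000)
})
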