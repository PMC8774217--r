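test_that("one-sided Fisher p agrees with brute-force enumeration", {
  tables <- list(c(7, 11, 10, 5), c(8, 10, 9, 6), c(5, 13, 6, 9),
                 c(1, 17, 1, 14), c(3, 15, 4, 11), c(0, 5, 3, 2),
                 c(4, 4, 4, 4))
  for (tb in tables) {
    expect_equal(fisher_exact(tb[1], tb[2], tb[3], tb[4]),
                 oracle_fisher_lower(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
  # p = 1 when a is at its maximum given the margins
  expect_equal(fisher_exact(5, 0, 2, 5), 1)
  expect_lte(fisher_exact(2, 3, 3, 2), 1)
})

test_that("two-sided Fisher matches the classical implementation", {
  tables <- list(c(7, 11, 10, 5), c(1, 17, 1, 14), c(3, 15, 4, 11))
  for (tb in tables) {
    expect_equal(
      fisher_exact(tb[1], tb[2], tb[3], tb[4], alternative = "two.sided"),
      stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
      tolerance = 1e-9)
  }
})

test_that("Fisher test validates its table", {
  expect_error(fisher_exact(-1, 2, 3, 4), "nonnegative")
  expect_error(fisher_exact(0, 0, 3, 4), "margins")
  expect_error(fisher_exact(0, 2, 0, 4), "margins")
})

test_that("Wilcoxon exact enumeration matches theory and base R", {
  # identical samples sit at the center of the symmetric null
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  # extreme separation: 2 / choose(6, 3) = 0.1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)),
               oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)))
  # agreement with wilcox.test on tie-free samples
  set.seed(14)
  for (rep in 1:5) {
    x <- round(rnorm(6, 10, 3), 4)
    y <- round(rnorm(7, 12, 3), 4)
    expect_equal(wilcoxon_rank_sum(x, y, method = "exact"),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Wilcoxon p is invariant under monotone transforms", {
  set.seed(15)
  x <- rnorm(8, 16, 2); y <- rnorm(9, 17, 2)
  p0 <- wilcoxon_rank_sum(x, y)
  expect_equal(wilcoxon_rank_sum(exp(x / 4), exp(y / 4)), p0)
  expect_equal(wilcoxon_rank_sum(x^3, y^3), p0)
})

test_that("Wilcoxon exact and approximate forms agree at n = 10 vs 10", {
  set.seed(16)
  for (rep in 1:4) {
    x <- rnorm(10, 15, 3); y <- rnorm(10, 16, 3)
    expect_lt(abs(wilcoxon_rank_sum(x, y, method = "exact") -
                    wilcoxon_rank_sum(x, y, method = "approx")), 0.02)
  }
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "nonempty")
})

test_that("sample-size algorithm evaluates its formula and is monotone", {
  # sigma_pooled = 5, delta = 5: n = ceil(2 * (1.959964 + 0.841621)^2) = 16
  spec <- power_spec(classes = tibble::tibble(
    class = c("a", "b"), mean = c(10, 15),
    lower = c(10 - 5 * 1.959964, 15 - 5 * 1.959964),
    upper = c(10 + 5 * 1.959964, 15 + 5 * 1.959964)))
  res <- sample_size(spec)
  expect_equal(res$comparisons$n_per_group, 16)
  expect_equal(res$n_final, 32)

  # huge difference -> 1 per group after ceiling
  spec_big <- power_spec(classes = tibble::tibble(
    class = c("a", "b"), mean = c(0, 1000),
    lower = c(-1, 999), upper = c(1, 1001)))
  expect_equal(sample_size(spec_big)$comparisons$n_per_group, 1)

  # nonincreasing in delta, nondecreasing in sigma
  n_of <- function(delta, halfwidth) {
    sample_size(power_spec(classes = tibble::tibble(
      class = c("a", "b"), mean = c(0, delta),
      lower = c(-halfwidth, delta - halfwidth),
      upper = c(halfwidth, delta + halfwidth))))$comparisons$n_per_group
  }
  expect_true(n_of(2, 6) >= n_of(4, 6))
  expect_true(n_of(3, 9) >= n_of(3, 6))

  same <- power_spec(classes = tibble::tibble(
    class = c("a", "b"), mean = c(5, 5), lower = c(4, 4), upper = c(6, 6)))
  expect_error(sample_size(same), "no detectable difference")
  expect_error(power_spec(alpha = 1.2), "alpha")
})

test_that("default power spec reports the three class comparisons", {
  res <- sample_size(power_spec())
  expect_equal(nrow(res$comparisons), 3)
  expect_true(all(res$comparisons$n_per_group >= 1))
  expect_equal(res$n_final, max(res$comparisons$n_total))
})

test_that("baseline table reproduces the published p-values from its counts", {
  # demographics constructed to match the published baseline margins exactly
  demo <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:33),
    group = rep(1:2, c(18, 15)),
    sex = c(rep("male", 7), rep("female", 11),
            rep("male", 10), rep("female", 5)),
    age = c(seq(12, 17.9, length.out = 18), seq(12.1, 17.8, length.out = 15)),
    instructed_dpi = c(rep(TRUE, 8), rep(FALSE, 10),
                       rep(TRUE, 9), rep(FALSE, 6)),
    instructed_mdi = c(rep(TRUE, 5), rep(FALSE, 13),
                       rep(TRUE, 6), rep(FALSE, 9)),
    instructed_smi = c(TRUE, rep(FALSE, 17), TRUE, rep(FALSE, 14)),
    region = c(rep("North", 15), rep("South and Islands", 3),
               rep("North", 10), rep("Center", 3),
               rep("South and Islands", 2)),
    education = c(rep("Lower secondary", 15), rep("Upper secondary", 3),
                  rep("Lower secondary", 11), rep("Upper secondary", 4)))
  tbl <- baseline_table(demo)
  p_of <- function(v) tbl$p_value[tbl$variable == v & !is.na(tbl$p_value)][1]
  expect_equal(round(p_of("male"), 3), 0.107)
  expect_equal(round(p_of("instructed_dpi"), 3), 0.295)
  expect_equal(round(p_of("instructed_mdi"), 3), 0.355)
  expect_equal(round(p_of("instructed_smi"), 2), 0.71)
  expect_equal(round(p_of("region"), 3), 0.199)
  expect_equal(round(p_of("education"), 3), 0.391)
  expect_true("age" %in% tbl$variable)
  expect_match(tbl$total[tbl$variable == "male"], "17 \\(51.5%\\)")
})
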