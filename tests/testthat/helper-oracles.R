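# Independent oracles the implementation is checked against. These are
# deliberately written from first principles (enumeration / closed forms)
# and share no code with the package internals.

# Lower-tail Fisher p by direct enumeration of all tables with the
# observed margins, using log-binomial coefficients only.
oracle_fisher_lower <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  log_p <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(m + n2, k)
  sum(exp(log_p[support <= a]))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# assignments of the combined midranks to the first sample.
oracle_wilcoxon_exact <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  w <- sum(r[seq_len(n1)])
  sums <- combn(r, n1, sum)
  p_le <- mean(sums <= w + 1e-9)
  p_ge <- mean(sums >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Independent re-summation of S-GUS totals: the default subscore table
# typed out directly, applied row by row with base R only.
oracle_points_table <- function() {
  tab <- list()
  for (i in 1:3)  tab[[i]] <- c(yes = 2, no = 0)
  for (i in 4:9)  tab[[i]] <- c(yes = 3, no = 0)
  tab[[10]] <- c(none = 10, mild = 6.6, moderate = 3.3, severe = 0)
  tab[[11]] <- c(none = 12.8, mild = 8.5, moderate = 4.3, severe = 0)
  tab[[12]] <- c(yes = 3.2, no = 0)
  tab
}

oracle_score_responses <- function(responses) {
  tab <- oracle_points_table()
  keys <- unique(responses[, c("patient_id", "device_id")])
  out <- data.frame(patient_id = keys$patient_id,
                    device_id = keys$device_id,
                    sgus_total = NA_real_)
  for (i in seq_len(nrow(keys))) {
    sub <- responses[responses$patient_id == keys$patient_id[i] &
                     responses$device_id == keys$device_id[i], ]
    out$sgus_total[i] <- sum(vapply(seq_len(nrow(sub)), function(j) {
      tab[[sub$item_id[j]]][[sub$level[j]]]
    }, numeric(1)))
  }
  out[order(out$patient_id, out$device_id), ]
}

# A complete response set at the given level for every item, for one
# patient-device record.
responses_at <- function(patient = "P1", device = "Ellipta",
                         binary = "yes", graded = "none",
                         agreement = "yes") {
  tibble::tibble(
    patient_id = patient, device_id = device, item_id = 1:12,
    level = c(rep(binary, 9), graded, graded, agreement))
}

# Monte-Carlo standard error of a posterior mean by batch means.
mcse_batch <- function(x, n_batch = 40) {
  n <- length(x)
  size <- n %/% n_batch
  means <- vapply(seq_len(n_batch), function(b) {
    mean(x[seq.int((b - 1) * size + 1, b * size)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_batch)
}

# Small fully crossed two-device cohort with a known device shift.
two_device_cohort <- function(n_patients = 8, shift = 5, noise_sd = 1,
                              seed = 11) {
  set.seed(seed)
  base <- rnorm(n_patients, 20, 2)
  tibble::tibble(
    patient_id = rep(sprintf("P%d", seq_len(n_patients)), each = 2),
    device_id = rep(c("A", "B"), n_patients),
    sgus_total = as.vector(rbind(base, base + shift)) +
      rnorm(2 * n_patients, 0, noise_sd))
}
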