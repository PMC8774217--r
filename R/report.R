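#' Run the full indirect-comparison analysis and write the report
#'
#' End-to-end pipeline: evidence-network construction and connectivity
#' check, the hierarchical model fit, posterior summaries, SUCRA ranking,
#' usability classification, heterogeneity decomposition, and (when
#' demographics are supplied) the baseline table. All outputs are written
#' to `out_dir` as plain text: `table1.csv`, `table2.csv` (the
#' publication-style comparison matrix, devices ordered by descending
#' SUCRA), `device_estimates.csv`, `comparisons.csv`, `sucra.csv`,
#' `rank_probabilities.csv`, `cumulative_ranking.csv`,
#' `classification.csv`, `heterogeneity.json` and `run_log.json` (seed
#' and settings echo, sufficient to reproduce the run).
#'
#' @param scores Data frame `patient_id`, `device_id`, `sgus_total`.
#' @param demographics Optional demographics table (see
#'   [baseline_table()]).
#' @param out_dir Output directory (created if needed).
#' @param reference,iterations,burnin,thin,seed,level Passed to
#'   [fit_ic_model()].
#' @param threshold Usability classification cut point (points).
#' @return Invisibly, a list with every computed object (`network`,
#'   `fit`, `summary`, `ranking`, `sucra`, `classification`,
#'   `heterogeneity`, `baseline`).
#' @export
run_analysis <- function(scores, demographics = NULL, out_dir,
                         reference = NULL,
                         iterations = 100000L, burnin = 50000L,
                         thin = 1L, seed = 1L, level = 0.90,
                         threshold = 15) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  network <- build_network(scores)
  fit <- fit_ic_model(scores, reference = reference,
                      iterations = iterations, burnin = burnin,
                      thin = thin, seed = seed, level = level)
  summary <- summarize_posterior(fit)
  ranking <- rank_probabilities(fit)
  sucra_tbl <- sucra(ranking)
  classification <- classify_usability(summary, threshold)
  het <- heterogeneity(fit, level)

  readr::write_csv(network, file.path(out_dir, "evidence_network.csv"))
  readr::write_csv(summary$devices,
                   file.path(out_dir, "device_estimates.csv"))
  readr::write_csv(summary$comparisons, file.path(out_dir, "comparisons.csv"))
  readr::write_csv(format_comparison_table(summary, sucra_tbl),
                   file.path(out_dir, "table2.csv"))
  readr::write_csv(sucra_tbl, file.path(out_dir, "sucra.csv"))
  readr::write_csv(ranking, file.path(out_dir, "rank_probabilities.csv"))
  readr::write_csv(cumulative_ranking(ranking),
                   file.path(out_dir, "cumulative_ranking.csv"))
  readr::write_csv(classification, file.path(out_dir, "classification.csv"))
  jsonlite::write_json(as.list(het), file.path(out_dir, "heterogeneity.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  baseline <- NULL
  if (!is.null(demographics)) {
    baseline <- baseline_table(demographics)
    readr::write_csv(baseline, file.path(out_dir, "table1.csv"))
  }

  jsonlite::write_json(
    list(seed = seed, reference = fit$reference, iterations = iterations,
         burnin = burnin, thin = thin, level = level,
         threshold = threshold, n_obs = nrow(scores),
         devices = fit$devices),
    file.path(out_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(network = network, fit = fit, summary = summary,
                 ranking = ranking, sucra = sucra_tbl,
                 classification = classification, heterogeneity = het,
                 baseline = baseline))
}
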