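#' Recovery of a planted cascade by a summary network
#'
#' Compares a synthesized summary network with the generator's ground
#' truth: recall is the fraction of true cascade edges present (with the
#' correct direction) in the summary; precision is the fraction of summary
#' edges that are true cascade edges; sign errors count signed summary
#' edges whose label contradicts the planted edge sign.
#'
#' @param summary A `summary_network`.
#' @param truth A `ground_truth`.
#' @return List with `recall`, `precision`, `sign_errors`, `n_true_edges`,
#'   `n_summary_edges`.
#' @export
evaluate_recovery <- function(summary, truth) {
  ce <- truth$cascade_edges
  true_key <- paste(ce$from, ce$to)
  sum_key <- paste(summary$from, summary$to)
  recall <- if (length(true_key) == 0) NA_real_
            else mean(true_key %in% sum_key)
  precision <- if (length(sum_key) == 0) NA_real_
               else mean(sum_key %in% true_key)
  signed <- summary[summary$sign != "unknown", , drop = FALSE]
  sgn_key <- paste(signed$from, signed$to)
  hit <- match(sgn_key, true_key)
  n_err <- sum(!is.na(hit) &
                 ((signed$sign == "activation") != (ce$sign[hit] > 0)))
  list(recall = recall, precision = precision, sign_errors = n_err,
       n_true_edges = nrow(ce), n_summary_edges = nrow(summary))
}

#' Parse deposited summary-network and kinase-network files and count edges
#'
#' Convenience check for externally deposited network files in the
#' summary-network and kinase-network TSV dialects: parses them and reports
#' the directed edge count, the signed edge count, and the kinase-kinase
#' edge count.
#'
#' @param summary_path Path to a summary-network TSV (see
#'   [read_summary_tsv()]).
#' @param kinase_path Path to a kinase-network TSV (see
#'   [read_kinase_network_tsv()]).
#' @return List with `n_directed`, `n_signed`, `n_kinase_edges` (NA for a
#'   path not supplied).
#' @export
check_deposited_files <- function(summary_path = NULL, kinase_path = NULL) {
  n_directed <- n_signed <- n_kinase <- NA_integer_
  if (!is.null(summary_path)) {
    s <- read_summary_tsv(summary_path)
    n_directed <- nrow(s)
    n_signed <- sum(s$sign != "unknown")
  }
  if (!is.null(kinase_path)) {
    k <- read_kinase_network_tsv(kinase_path)
    n_kinase <- nrow(k$edges)
  }
  list(n_directed = n_directed, n_signed = n_signed,
       n_kinase_edges = n_kinase)
}

stage_seed <- function(seed, stage) {
  # per-stage seed scheme: base * 100 + stage index, documented and fixed
  as.integer(seed) * 100L + as.integer(stage)
}

#' Run the full reconstruction and validation pipeline on synthetic data
#'
#' Executes, in order: synthetic-data generation (interactome, planted
#' cascade, time series, inhibition matrix, permeability screen, functional
#' model fixture), preprocessing (significance scores, activity profiles,
#' prizes), prize-based subnetwork extraction, temporal pathway synthesis,
#' kinase-network comparison, validation of both arms, planted-cascade
#' recovery scoring and (optionally) the two randomization null ensembles.
#' Per-stage seeds derive from `cfg$seed` via a fixed scheme
#' (`seed * 100 + stage index`), so identical configurations give identical
#' results. With `outdir` set, every intermediate artifact is written in
#' its native format with a header naming the stage, parameters and seed.
#'
#' @param cfg A [sim_config()].
#' @param pcsf A [pcsf_params()].
#' @param vcfg A [validation_config()].
#' @param max_path_len Maximum path length for [synthesize()].
#' @param null_n Iterations per null ensemble (0 skips the ensembles).
#' @param outdir Optional output directory for all artifacts.
#' @return A list report with all intermediate objects, the two validation
#'   scores, the recovery metrics and (when requested) null-ensemble
#'   summaries.
#' @export
run_pipeline <- function(cfg = sim_config(), pcsf = pcsf_params(),
                         vcfg = validation_config(), max_path_len = 8,
                         null_n = 0L, outdir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))

  # stage 1: simulate
  net <- generate_interactome(cfg)
  truth <- plant_cascade(net, cfg)
  dataset <- generate_timeseries(truth, net, cfg)
  inhib <- generate_inhibition_matrix(truth, net, cfg)
  screen <- generate_permeability_screen(truth, inhib, cfg)
  trek <- generate_treking_fixture(truth, net, cfg)

  # stage 2: preprocess
  prep <- preprocess_dataset(dataset)

  # stage 3: extract
  sub <- extract_subnetwork(net, prep$prizes, net$source, pcsf,
                            seed = stage_seed(cfg$seed, 3L))

  # stage 4: synthesize
  pm <- ks_partial_model(net)
  syn <- synthesize(sub, pm, prep$profiles, source = net$source,
                    max_path_len = max_path_len)

  kinases <- net$nodes$id[net$nodes$is_kinase]

  # stage 5: compare kinase networks
  tps_kin <- kinase_subnetwork(syn$summary, kinases)
  trek_kin <- kinase_subnetwork(treking_network(trek), kinases)
  comparison <- overlap_stats(tps_kin, trek_kin)

  # stage 6: validate both arms
  net_kin <- intersect(unique(c(syn$summary$from, syn$summary$to)), kinases)
  tps_val <- score_network_inhibition(net_kin, inhib, screen, vcfg)
  trek_val <- score_treking_model(trek, dataset, vcfg)

  recovery <- evaluate_recovery(syn$summary, truth)

  report <- list(
    config = cfg, interactome = net, truth = truth, dataset = dataset,
    inhibition = inhib, screen = screen,
    preprocessing = prep, subnetwork = sub, partial_model = pm,
    summary = syn$summary, windows = syn$windows, treking = trek,
    comparison = comparison, tps_validation = tps_val,
    treking_validation = trek_val, recovery = recovery
  )

  # stage 7: null ensembles
  if (null_n > 0) {
    tps_null <- random_tps_ensemble(
      sub, pm, dataset, prep$scores, kinases, inhib, screen,
      n = null_n, base_seed = stage_seed(cfg$seed, 7L), vcfg = vcfg,
      max_path_len = max_path_len
    )
    trek_null <- random_treking_ensemble(
      treking_null_config(n_kir_kinases = length(trek$kinases),
                          n_clusters = cfg$n_clusters),
      trek, dataset, n = null_n, base_seed = stage_seed(cfg$seed, 8L),
      vcfg = vcfg
    )
    report$tps_null <- summarize_null(tps_null, tps_val$accuracy)
    report$treking_null <- summarize_null(trek_null, trek_val$accuracy)
    report$tps_null_ensemble <- tps_null
    report$treking_null_ensemble <- trek_null
  }

  if (!is.null(outdir)) write_pipeline_outputs(report, outdir)
  report
}

write_pipeline_outputs <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  hdr <- function(stage, extra = NULL) {
    c(sprintf("phosnet stage=%s seed=%d", stage, cfg$seed), extra)
  }
  write_interactome_sif(report$interactome,
                        file.path(outdir, "interactome.sif.tsv"),
                        header = hdr("simulate"))
  write_timeseries_tsv(report$dataset, file.path(outdir, "timeseries.tsv"),
                       header = hdr("simulate",
                                    sprintf("noise_cv=%g", cfg$noise_cv)))
  write_scores_tsv(report$preprocessing$scores,
                   file.path(outdir, "firstscores.tsv"),
                   type = "firstscores", header = hdr("preprocess"))
  write_scores_tsv(report$preprocessing$scores,
                   file.path(outdir, "prevscores.tsv"),
                   type = "prevscores", header = hdr("preprocess"))
  write_subnetwork_tsv(report$subnetwork, file.path(outdir, "subnetwork.tsv"),
                       header = hdr("extract"))
  write_partial_model_tsv(report$partial_model,
                          file.path(outdir, "partial_model.tsv"),
                          header = hdr("extract"))
  write_summary_tsv(report$summary, file.path(outdir, "summary_network.tsv"),
                    header = hdr("synthesize"))
  write_kinase_network_tsv(kinase_subnetwork(
    report$summary, report$interactome$nodes$id[report$interactome$nodes$is_kinase]
  ), file.path(outdir, "kinase_network.tsv"), header = hdr("compare"))
  write_inhibition_tsv(report$inhibition,
                       file.path(outdir, "inhibition_matrix.tsv"),
                       header = hdr("simulate"))
  write_screen_tsv(report$screen, file.path(outdir, "permeability_screen.tsv"),
                   header = hdr("simulate"))
  write_treking_json(report$treking, file.path(outdir, "treking_model.json"))
  jsonlite::write_json(
    list(comparison = report$comparison,
         tps_validation = report$tps_validation[c("n_predicted", "n_agree",
                                                  "accuracy", "confusion")],
         treking_validation = report$treking_validation[c("n_predicted",
                                                          "n_agree",
                                                          "accuracy",
                                                          "confusion")],
         recovery = report$recovery,
         tps_null = report$tps_null, treking_null = report$treking_null),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(outdir)
}
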